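# internal wrapper over the C++ 8-connected labeling
label_components8 <- function(mask) {
  label_components8_cpp(mask != 0)
}

#' Simulation protocol configuration
#'
#' The default protocol: 15 ms total at a time step of 1e-8 s, comprising
#' 2 ms of quiescent equilibration followed by a 2 ms voltage clamp of one
#' domain edge at 1 mV (absolute membrane voltage) and free propagation for
#' the remainder. The linear solver runs to 1e-12 relative/absolute
#' tolerance. Recording every 1 us resolves upstroke velocities of
#' 200-300 V/s.
#'
#' @param dt time step in seconds.
#' @param total_time_ms total simulated time (includes equilibration and
#'   stimulus windows).
#' @param equilibration_ms quiescent time before the stimulus.
#' @param stimulus_duration_ms length of the edge voltage clamp.
#' @param stimulus_value_mV clamped membrane voltage.
#' @param stimulus_edge `"left"`, `"right"`, `"top"` or `"bottom"`.
#' @param rel_tol,abs_tol iterative linear-solver tolerances.
#' @param record_every_ms recording interval for field snapshots.
#' @param record_phie also record the extracellular potential (needed for
#'   conservation diagnostics; roughly doubles memory).
#' @param exp_gates use the exponential gate update in the ionic model
#'   (stable at coarse time steps; forward Euler is the default scheme).
#' @param cell_type myocyte variant for all active elements.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1e-8, total_time_ms = 15,
                              equilibration_ms = 2, stimulus_duration_ms = 2,
                              stimulus_value_mV = 1, stimulus_edge = "left",
                              rel_tol = 1e-12, abs_tol = 1e-12,
                              record_every_ms = 1e-3, record_phie = FALSE,
                              exp_gates = FALSE, cell_type = "epi") {
  stimulus_edge <- match.arg(stimulus_edge, c("left", "right", "top", "bottom"))
  stopifnot(
    dt > 0, total_time_ms > 0, rel_tol > 0, abs_tol > 0,
    equilibration_ms + stimulus_duration_ms <= total_time_ms
  )
  record_stride <- max(1L, round(record_every_ms / (dt * 1e3)))
  structure(
    list(
      dt = dt, total_time_ms = total_time_ms,
      equilibration_ms = equilibration_ms,
      stimulus_duration_ms = stimulus_duration_ms,
      stimulus_value_mV = stimulus_value_mV,
      stimulus_edge = stimulus_edge,
      rel_tol = rel_tol, abs_tol = abs_tol,
      record_stride = as.integer(record_stride),
      record_phie = record_phie,
      exp_gates = exp_gates,
      cell_type = cell_type
    ),
    class = "simulation_config"
  )
}

#' Assemble discrete bidomain operators
#'
#' Builds five-point finite-volume operators on the element grid with face
#' conductivities equal to the harmonic mean of the adjacent element
#' conductivities along the face normal (so fully fibrotic elements act as
#' intracellular insulators), no-flux exterior faces, and a gauge-fixed
#' elliptic operator (reference element pinned to zero extracellular
#' potential). Elements with no conductive coupling at all are pinned too.
#'
#' @param mesh a `bidomain_mesh`.
#' @return List with `L_myo` (myocyte-domain divergence operator, A/m^3 per
#'   volt), `L_sum` (raw elliptic operator, rows sum to zero), `A_ell`
#'   (pinned symmetric positive-definite system matrix `-L_sum` with gauge
#'   rows), `ref_index`, `n_el`.
#' @export
assemble_operators <- function(mesh) {
  stopifnot(inherits(mesh, "bidomain_mesh"))
  ny <- mesh$ny; nx <- mesh$nx
  n <- ny * nx
  if (!any(mesh$active)) stop("mesh has no active elements")
  h <- mesh$element_edge_um * 1e-6
  idx <- function(r, c) (c - 1L) * ny + r

  harm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  build <- function(sig_l, sig_t) {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    # x-direction faces use longitudinal conductivity
    if (nx > 1) {
      a <- sig_l[, -nx, drop = FALSE]; b <- sig_l[, -1, drop = FALSE]
      f <- harm(a, b) / h^2
      r <- rep(seq_len(ny), nx - 1)
      c1 <- rep(seq_len(nx - 1), each = ny)
      i1 <- idx(r, c1); i2 <- idx(r, c1 + 1L)
      ii <- c(ii, i1, i2, i1, i2)
      jj <- c(jj, i2, i1, i1, i2)
      xx <- c(xx, f, f, -f, -f)
    }
    # y-direction faces use transverse conductivity
    if (ny > 1) {
      a <- sig_t[-ny, , drop = FALSE]; b <- sig_t[-1, , drop = FALSE]
      f <- harm(a, b) / h^2
      r <- rep(seq_len(ny - 1), nx)
      c1 <- rep(seq_len(nx), each = ny - 1)
      i1 <- idx(r, c1); i2 <- idx(r + 1L, c1)
      ii <- c(ii, i1, i2, i1, i2)
      jj <- c(jj, i2, i1, i1, i2)
      xx <- c(xx, f, f, -f, -f)
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  }

  L_myo <- build(mesh$sigma_myo_l, mesh$sigma_myo_t)
  L_sum <- build(mesh$sigma_myo_l + mesh$sigma_e_l,
                 mesh$sigma_myo_t + mesh$sigma_e_t)

  A <- -L_sum
  ref <- which(mesh$active)[1]
  pinned <- unique(c(ref, which(Matrix::diag(A) <= 0)))
  A[pinned, ] <- 0
  A[, pinned] <- 0
  Matrix::diag(A)[pinned] <- 1
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")

  list(
    L_myo = methods::as(L_myo, "CsparseMatrix"),
    L_sum = methods::as(L_sum, "CsparseMatrix"),
    A_ell = A,
    ref_index = ref,
    pinned = pinned,
    n_el = n
  )
}

# element indices (column-major) of a stimulus edge, active elements only
stim_edge_indices <- function(mesh, edge) {
  ny <- mesh$ny; nx <- mesh$nx
  sel <- switch(edge,
    left = cbind(seq_len(ny), 1L),
    right = cbind(seq_len(ny), nx),
    top = cbind(1L, seq_len(nx)),
    bottom = cbind(ny, seq_len(nx))
  )
  lin <- (sel[, 2] - 1L) * ny + sel[, 1]
  lin[mesh$active[sel]]
}

#' Run one bidomain simulation
#'
#' Operator-split explicit integration of the elliptic/parabolic bidomain
#' system on the mesh: per step an ionic-model update, an iterative elliptic
#' solve for the extracellular potential, and a forward-Euler parabolic
#' update of the membrane voltage, with the stimulus edge's membrane voltage
#' clamped during the stimulus window.
#'
#' @param mesh a `bidomain_mesh`.
#' @param config a [simulation_config()].
#' @param operators optionally, precomputed [assemble_operators()] output.
#' @return Object of class `field_recording`: `times_ms`, `Vm_mV`
#'   (elements x frames, `NA` for passive elements), optional `phie_mV`,
#'   per-element `max_upstroke_V_per_s` and `t_max_upstroke_ms` (relative to
#'   stimulus onset, tracked at full step resolution within the -60..0 mV
#'   window), mesh geometry, and the config.
#' @export
simulate_bidomain <- function(mesh, config = simulation_config(), operators = NULL) {
  stopifnot(inherits(mesh, "bidomain_mesh"), inherits(config, "simulation_config"))
  if (is.null(operators)) operators <- assemble_operators(mesh)
  stim_idx <- stim_edge_indices(mesh, config$stimulus_edge)
  if (length(stim_idx) == 0) stop("stimulus edge has no active elements")
  beta_cm <- as.numeric(mesh$beta_myo) * mesh$params$Cm_per_myocyte
  beta_cm[beta_cm <= 0] <- 1  # passive elements: never used by the update
  A <- operators$A_ell
  L <- operators$L_myo
  res <- bidomain_simulate_cpp(
    n_el = operators$n_el,
    active_idx = which(as.logical(mesh$active)) - 1L,
    beta_cm = beta_cm,
    Ap = A@p, Ai = A@i, Ax = A@x,
    Lp = L@p, Li = L@i, Lx = L@x,
    cell_type = cell_type_code(config$cell_type),
    dt_s = config$dt,
    total_ms = config$total_time_ms,
    equil_ms = config$equilibration_ms,
    stim_dur_ms = config$stimulus_duration_ms,
    stim_mV = config$stimulus_value_mV,
    stim_idx = stim_idx - 1L,
    pinned_idx = operators$pinned - 1L,
    rel_tol = config$rel_tol, abs_tol = config$abs_tol,
    record_stride = config$record_stride,
    record_phie = config$record_phie,
    exp_gates = config$exp_gates,
    reversal_refresh = max(1L, as.integer(round(1e-6 / config$dt)))
  )
  structure(
    list(
      times_ms = res$times_ms,
      Vm_mV = res$Vm_mV,
      phie_mV = res$phie_mV,
      max_upstroke_V_per_s = res$max_upstroke_V_per_s,
      t_max_upstroke_ms = res$t_max_upstroke_ms,
      stim_onset_ms = res$stim_onset_ms,
      cg_iterations = res$cg_iterations,
      ny = mesh$ny, nx = mesh$nx,
      element_edge_um = mesh$element_edge_um,
      active = mesh$active,
      stimulus_edge = config$stimulus_edge,
      config = config
    ),
    class = "field_recording"
  )
}

#' @export
print.field_recording <- function(x, ...) {
  cat(sprintf(
    "field_recording: %d x %d elements, %d frames over %.1f ms, stimulus %s\n",
    x$ny, x$nx, length(x$times_ms), max(x$times_ms), x$stimulus_edge
  ))
  invisible(x)
}

#' Run the four-edge stimulus protocol
#'
#' Runs the simulation with the stimulus on each edge of the domain. With
#' the myocyte long axis along x, the left/right stimuli (normal to the long
#' axis) probe longitudinal conduction and the top/bottom stimuli transverse
#' conduction. For cross-section images only the transverse pair is run.
#'
#' @param mesh a `bidomain_mesh`.
#' @param config base [simulation_config()]; its `stimulus_edge` is ignored.
#' @param directions optionally restrict to a subset of
#'   `c("left", "right", "top", "bottom")`.
#' @return Named list of `field_recording`s.
#' @export
run_protocol <- function(mesh, config = simulation_config(), directions = NULL) {
  if (is.null(directions)) {
    directions <- if (identical(mesh$myocyte_axis, "cross-section")) {
      c("top", "bottom")
    } else {
      c("left", "right", "top", "bottom")
    }
  }
  ops <- assemble_operators(mesh)
  out <- lapply(directions, function(e) {
    cfg <- config
    cfg$stimulus_edge <- e
    simulate_bidomain(mesh, cfg, operators = ops)
  })
  names(out) <- directions
  out
}
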