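#' Conductivity and membrane parameter set for the bidomain mesh
#'
#' Base (100% volume fraction) conductivities, anisotropy ratios and membrane
#' constants used to build per-element conductivity tensors. Two presets are
#' provided for the myocyte-domain base conductivity: `"sim"`
#' (`sigma_myo_long_100 = 0.1` S/m, the value enumerated for the conduction
#' simulations) and `"high"` (`0.5` S/m, the alternative stated with the
#' fraction-scaling relation); both appear in the source description of the
#' model and the choice materially shifts conduction velocity.
#'
#' @param preset `"sim"` or `"high"`.
#' @param sigma_myo_long_100,sigma_e_long_100 longitudinal conductivities
#'   (S/m) at 100% myocyte / extracellular fraction.
#' @param anis_myo,anis_e longitudinal:transverse anisotropy ratios (10, 2).
#' @param membrane_R membrane resistance (Ohm m^2), used for space constants.
#' @param beta_sv myocyte surface-to-volume ratio (1/m).
#' @param V_myo_single_um3 volume of one myocyte (um^3).
#' @param Cm_per_myocyte capacitance of one myocyte (F). The default derives
#'   from `beta_sv * V_myo_single * 0.01 F/m^2` (~82 pF), i.e. the membrane
#'   area of one myocyte times a specific capacitance of 1 uF/cm^2.
#' @return List of class `conductivity_params`.
#' @export
conductivity_params <- function(preset = c("sim", "high"),
                                sigma_myo_long_100 = NULL,
                                sigma_e_long_100 = 1,
                                anis_myo = 10, anis_e = 2,
                                membrane_R = 0.2,
                                beta_sv = 2e5,
                                V_myo_single_um3 = 41073,
                                Cm_per_myocyte = NULL) {
  preset <- match.arg(preset)
  if (is.null(sigma_myo_long_100)) {
    sigma_myo_long_100 <- switch(preset, sim = 0.1, high = 0.5)
  }
  if (is.null(Cm_per_myocyte)) {
    Cm_per_myocyte <- beta_sv * (V_myo_single_um3 * 1e-18) * 0.01
  }
  stopifnot(
    sigma_myo_long_100 > 0, sigma_e_long_100 > 0,
    anis_myo >= 1, anis_e >= 1,
    membrane_R > 0, beta_sv > 0, V_myo_single_um3 > 0, Cm_per_myocyte > 0
  )
  structure(
    list(
      preset = preset,
      sigma_myo_long_100 = sigma_myo_long_100,
      sigma_e_long_100 = sigma_e_long_100,
      anis_myo = anis_myo, anis_e = anis_e,
      membrane_R = membrane_R,
      beta_sv = beta_sv,
      V_myo_single_um3 = V_myo_single_um3,
      Cm_per_myocyte = Cm_per_myocyte
    ),
    class = "conductivity_params"
  )
}

#' Downsample image masks to per-element volume fractions
#'
#' Averages each binary mask over the physical footprint of every mesh
#' element (2,500 um^2 for the default 50-um edge), anchored at the image
#' origin with incomplete edge elements dropped. The image is assumed
#' pre-rotated so the myocyte long axis runs along x.
#'
#' @param image a [tissue_image()].
#' @param element_edge_um element edge length in micrometres.
#' @return List with matrices `V_e`, `V_f`, `V_mf` (element row x element
#'   column), `element_edge_um`, and the source `pixel_size_nm`.
#' @export
downsample_fractions <- function(image, element_edge_um = 50) {
  stopifnot(inherits(image, "tissue_image"))
  by <- tile_boundaries(nrow(image$es), image$pixel_size_nm, element_edge_um)
  bx <- tile_boundaries(ncol(image$es), image$pixel_size_nm, element_edge_um)
  ny <- length(by) - 1L; nx <- length(bx) - 1L
  avg <- function(mask) {
    out <- matrix(NA_real_, ny, nx)
    for (i in seq_len(ny)) {
      for (j in seq_len(nx)) {
        out[i, j] <- mean(mask[(by[i] + 1L):by[i + 1L], (bx[j] + 1L):bx[j + 1L]])
      }
    }
    out
  }
  list(
    V_e = avg(image$es), V_f = avg(image$fib), V_mf = avg(image$myofib),
    element_edge_um = element_edge_um,
    pixel_size_nm = image$pixel_size_nm,
    myocyte_axis = image$myocyte_axis
  )
}

#' Build a bidomain mesh from per-element volume fractions
#'
#' Establishes per-element myocyte fractions `V_myo = 1 - V_e - V_f - V_mf`,
#' diagonal conductivity tensors scaled linearly with the domain fractions
#' (`sigma_myo = V_myo * sigma_myo_100`, `sigma_e = V_e * sigma_e_100`, with
#' transverse entries divided by the anisotropy ratios), and myocyte density
#' `beta_myo = V_myo / V_myo_single`. Fibroblast and myofibroblast fractions
#' carry zero conductivity in both domains. Elements whose myocyte fraction
#' falls below `passive_threshold` are flagged passive: they carry no
#' membrane model and zero myocyte-domain conductivity but remain part of
#' the extracellular system.
#'
#' @param fractions output of [downsample_fractions()], or a list with
#'   matrices `V_e`, `V_f`, `V_mf` and `element_edge_um`.
#' @param params a [conductivity_params()].
#' @param passive_threshold myocyte fraction below which an element is
#'   treated as passive.
#' @return Object of class `bidomain_mesh` with element-grid matrices
#'   (`V_e`, `V_f`, `V_mf`, `V_myo`, `sigma_myo_l`, `sigma_myo_t`,
#'   `sigma_e_l`, `sigma_e_t`, `beta_myo`, `active`), counts `ny`, `nx`,
#'   `element_edge_um` and `params`.
#' @export
build_mesh <- function(fractions, params = conductivity_params(),
                       passive_threshold = 1e-6) {
  Ve <- fractions$V_e; Vf <- fractions$V_f; Vmf <- fractions$V_mf
  stopifnot(is.matrix(Ve), all(dim(Ve) == dim(Vf)), all(dim(Ve) == dim(Vmf)))
  Vmyo <- 1 - Ve - Vf - Vmf
  bad <- which(Vmyo < -1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "element (%d, %d) has negative myocyte fraction %.4f (V_e + V_f + V_mf > 1)",
      bad[1, 1], bad[1, 2], Vmyo[bad[1, 1], bad[1, 2]]
    ))
  }
  Vmyo[Vmyo < 0] <- 0
  active <- Vmyo > passive_threshold
  s_myo <- Vmyo * params$sigma_myo_long_100
  s_myo[!active] <- 0
  structure(
    list(
      ny = nrow(Ve), nx = ncol(Ve),
      element_edge_um = fractions$element_edge_um,
      V_e = Ve, V_f = Vf, V_mf = Vmf, V_myo = Vmyo,
      sigma_myo_l = s_myo,
      sigma_myo_t = s_myo / params$anis_myo,
      sigma_e_l = Ve * params$sigma_e_long_100,
      sigma_e_t = Ve * params$sigma_e_long_100 / params$anis_e,
      beta_myo = Vmyo / (params$V_myo_single_um3 * 1e-18),
      active = active,
      myocyte_axis = if (is.null(fractions$myocyte_axis)) "x-aligned" else fractions$myocyte_axis,
      params = params
    ),
    class = "bidomain_mesh"
  )
}

#' @export
print.bidomain_mesh <- function(x, ...) {
  cat(sprintf(
    "bidomain_mesh: %d x %d elements of %g um (%.2f x %.2f mm), %d passive\n",
    x$ny, x$nx, x$element_edge_um,
    x$nx * x$element_edge_um / 1000, x$ny * x$element_edge_um / 1000,
    sum(!x$active)
  ))
  cat(sprintf("  mean V_myo = %.3f, sigma preset '%s'\n",
              mean(x$V_myo), x$params$preset))
  invisible(x)
}

#' Build a homogeneous mesh from uniform volume fractions
#'
#' Convenience constructor for benchmark and calibration meshes: every
#' element carries the same composition.
#'
#' @param V_e,V_f,V_mf uniform fractions.
#' @param ny,nx element counts.
#' @param element_edge_um element edge (um).
#' @param params a [conductivity_params()].
#' @return A `bidomain_mesh`.
#' @export
homogeneous_mesh <- function(V_e, V_f = 0, V_mf = 0, ny = 20, nx = 20,
                             element_edge_um = 50,
                             params = conductivity_params()) {
  build_mesh(
    list(
      V_e = matrix(V_e, ny, nx), V_f = matrix(V_f, ny, nx),
      V_mf = matrix(V_mf, ny, nx), element_edge_um = element_edge_um
    ),
    params = params
  )
}

#' Extend a mesh with homogeneous flanks along x
#'
#' Embeds the mesh in a longer domain whose flanking elements carry the mean
#' volume fractions of the original mesh, centering the original along x (a
#' 1-mm mesh extended to 5 mm occupies x in [2, 3] mm). Used to quantify
#' boundary effects on conduction-velocity estimates.
#'
#' @param mesh a `bidomain_mesh`.
#' @param total_length_x_mm requested total domain length along x.
#' @return A `bidomain_mesh` with attribute `"embedded_cols"`, the column
#'   indices of the original mesh inside the extended one.
#' @export
extend_homogeneous <- function(mesh, total_length_x_mm = 5) {
  stopifnot(inherits(mesh, "bidomain_mesh"))
  nx_total <- round(total_length_x_mm * 1000 / mesh$element_edge_um)
  pad <- nx_total - mesh$nx
  if (pad <= 0) stop("total length must exceed the current mesh length")
  pad_l <- floor(pad / 2)
  pad_r <- pad - pad_l
  extend <- function(m) {
    cbind(
      matrix(mean(m), mesh$ny, pad_l), m, matrix(mean(m), mesh$ny, pad_r)
    )
  }
  out <- build_mesh(
    list(
      V_e = extend(mesh$V_e), V_f = extend(mesh$V_f), V_mf = extend(mesh$V_mf),
      element_edge_um = mesh$element_edge_um, myocyte_axis = mesh$myocyte_axis
    ),
    params = mesh$params
  )
  attr(out, "embedded_cols") <- pad_l + seq_len(mesh$nx)
  out
}
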