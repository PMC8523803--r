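test_that("discrete operators conserve current and insulate zero-conductivity columns", {
  mesh <- donor_mean_mesh()
  ops <- assemble_operators(mesh)
  # conservation: every row of the raw operators sums to zero
  expect_lt(max(abs(Matrix::rowSums(ops$L_sum))) /
              max(abs(ops$L_sum@x)), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(ops$L_myo))) /
              max(abs(ops$L_myo@x)), 1e-12)

  # discrete Laplacian identity: zero action on a linear-in-x field away
  # from the no-flux boundary columns
  x_field <- matrix(rep(seq_len(mesh$nx), each = mesh$ny), mesh$ny, mesh$nx)
  act <- matrix(as.numeric(ops$L_myo %*% as.numeric(x_field)), mesh$ny, mesh$nx)
  interior <- act[, 2:(mesh$nx - 1)]
  expect_lt(max(abs(interior)) / max(abs(act)), 1e-10)

  # a fully fibrotic column has zero harmonic-mean intracellular coupling
  fr <- list(V_e = matrix(0.2, 6, 6), V_f = matrix(0, 6, 6),
             V_mf = matrix(0, 6, 6), element_edge_um = 50)
  fr$V_e[, 3] <- 1  # V_myo = 0 there
  barrier <- build_mesh(fr)
  bops <- assemble_operators(barrier)
  Lm <- matrix(0, 36, 36)
  Lm[] <- as.matrix(bops$L_myo)
  idx <- function(r, c) (c - 1) * 6 + r
  expect_equal(Lm[idx(2, 2), idx(2, 3)], 0)
  expect_equal(Lm[idx(2, 4), idx(2, 3)], 0)

  expect_error(assemble_operators(homogeneous_mesh(V_e = 1, ny = 3, nx = 3)),
               "no active elements")
})

test_that("a left-edge stimulus produces a planar longitudinal wave", {
  rec <- cached_recording("donor_left", function() {
    simulate_bidomain(donor_mean_mesh(), coarse_config(stimulus_edge = "left"))
  })
  am <- activation_map(rec)
  expect_equal(am$n_blocked, 0L)
  # same activation time across y within 1%
  act <- am$activation_ms
  spread <- apply(act[, 2:19], 2, function(cl) diff(range(cl)) / mean(cl))
  expect_lt(max(spread), 0.01)
  # activation time increases affinely with x
  prof <- colMeans(act)[3:18]
  fit <- linreg(3:18, prof)
  expect_gt(fit$R2, 0.999)
  # 1D cable oracle: per-column activation-time steps equal the fitted
  # slope within a few percent away from the boundaries
  # slight acceleration toward the far no-flux boundary is expected
  steps <- diff(colMeans(act))[4:15]
  expect_lt(max(abs(steps - fit$A)) / fit$A, 0.08)
  # interior upstroke velocities sit in the physiological 150-300 V/s band
  ups <- am$upstroke_V_per_s[, 5:15]
  expect_true(all(ups > 150 & ups < 300))
})

test_that("conduction is blocked by a full-width compact fibrotic band", {
  fr <- list(V_e = matrix(0.201, 20, 20), V_f = matrix(0.01, 20, 20),
             V_mf = matrix(0.01, 20, 20), element_edge_um = 50)
  fr$V_e[, 10:11] <- 1; fr$V_f[, 10:11] <- 0; fr$V_mf[, 10:11] <- 0
  mesh <- build_mesh(fr)
  rec <- simulate_bidomain(mesh, coarse_config(stimulus_edge = "left"))
  am <- activation_map(rec)
  expect_true(all(am$non_conductive[, 10:20]))
  expect_true(all(!am$non_conductive[, 1:9]))
  expect_gte(am$n_blocked, 1L)
})

test_that("mirror-symmetric stimuli give mirror-equal activation maps", {
  left <- cached_recording("donor_left", function() {
    simulate_bidomain(donor_mean_mesh(), coarse_config(stimulus_edge = "left"))
  })
  right <- cached_recording("donor_right", function() {
    simulate_bidomain(donor_mean_mesh(), coarse_config(stimulus_edge = "right"))
  })
  a_l <- activation_map(left)$activation_ms
  a_r <- activation_map(right)$activation_ms
  mirrored <- a_r[, rev(seq_len(ncol(a_r)))]
  expect_lt(max(abs(a_l - mirrored)) / max(a_l), 0.01)
})

test_that("the resting tissue stays at rest without a stimulus", {
  mesh <- donor_mean_mesh()
  cfg <- coarse_config(stimulus_duration_ms = 0, record_every_ms = 0.1)
  rec <- simulate_bidomain(mesh, cfg)
  v0 <- rec$Vm_mV[1, 1]
  expect_lt(max(abs(rec$Vm_mV - v0), na.rm = TRUE), 0.5)
})

test_that("membrane current balances extracellular divergence at every frame", {
  mesh <- donor_mean_mesh()
  cfg <- coarse_config(total_time_ms = 6, record_every_ms = 0.5,
                       record_phie = TRUE)
  rec <- simulate_bidomain(mesh, cfg)
  ops <- assemble_operators(mesh)
  for (f in seq_along(rec$times_ms)) {
    vm <- rec$Vm_mV[, f] * 1e-3
    pe <- rec$phie_mV[, f] * 1e-3
    resid <- as.numeric(ops$L_sum %*% pe + ops$L_myo %*% vm)
    # scale: largest stencil coefficient times the field magnitude
    scale <- max(abs(ops$L_myo@x)) * max(abs(vm))
    expect_lt(max(abs(resid[-ops$pinned])) / scale, 1e-9)
  }
})

test_that("longitudinal activation completes earlier than transverse", {
  left <- cached_recording("donor_left", function() {
    simulate_bidomain(donor_mean_mesh(), coarse_config(stimulus_edge = "left"))
  })
  top <- cached_recording("donor_top", function() {
    simulate_bidomain(donor_mean_mesh(), coarse_config(stimulus_edge = "top"))
  })
  t_long <- max(activation_map(left)$activation_ms, na.rm = TRUE)
  t_trans <- max(activation_map(top)$activation_ms, na.rm = TRUE)
  expect_lt(t_long, t_trans)
})

test_that("run_protocol returns the four stimulus directions and flags blocks", {
  mesh <- donor_mean_mesh(ny = 10, nx = 10)
  cfg <- coarse_config(total_time_ms = 8)
  recs <- run_protocol(mesh, cfg)
  expect_named(recs, c("left", "right", "top", "bottom"))

  # all-passive right half: longitudinal run reports a non-conductive region
  fr <- list(V_e = matrix(0.201, 10, 10), V_f = matrix(0.01, 10, 10),
             V_mf = matrix(0.01, 10, 10), element_edge_um = 50)
  fr$V_e[, 6:10] <- 1; fr$V_f[, 6:10] <- 0; fr$V_mf[, 6:10] <- 0
  half <- build_mesh(fr)
  rec <- simulate_bidomain(half, coarse_config(total_time_ms = 8))
  expect_gte(activation_map(rec)$n_blocked, 1L)

  # cross-section images: only the transverse pair is simulated
  xsec <- donor_mean_mesh(ny = 10, nx = 10)
  xsec$myocyte_axis <- "cross-section"
  recs2 <- run_protocol(xsec, cfg)
  expect_named(recs2, c("top", "bottom"))
})
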