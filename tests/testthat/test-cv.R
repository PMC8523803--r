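# build a minimal field_recording by hand for oracle tests
fake_recording <- function(traces, times, ny, nx, edge = "left",
                           stim_onset = 0) {
  structure(
    list(
      times_ms = times, Vm_mV = traces, phie_mV = NULL,
      stim_onset_ms = stim_onset, ny = ny, nx = nx,
      element_edge_um = 50, active = matrix(TRUE, ny, nx),
      stimulus_edge = edge
    ),
    class = "field_recording"
  )
}

# build an activation_map directly from a matrix of times (ms)
fake_amap <- function(act_ms, edge = "left") {
  structure(
    list(
      activation_ms = act_ms,
      upstroke_V_per_s = act_ms * 0 + 200,
      non_conductive = is.na(act_ms),
      block_labels = cardiofib:::label_components8(is.na(act_ms)),
      n_blocked = max(cardiofib:::label_components8(is.na(act_ms))),
      ny = nrow(act_ms), nx = ncol(act_ms),
      element_edge_um = 50, stimulus_edge = edge
    ),
    class = "activation_map"
  )
}

test_that("activation time is the max-slope sample within the voltage window", {
  times <- seq(0, 10, by = 0.01)
  # a synthetic upstroke crossing -60 to 0 with known max slope at t = 5
  trace <- -85 + 110 / (1 + exp(-(times - 5) / 0.25))
  # brute-force oracle over the recorded intervals: rising and
  # intersecting the (-60, 0) window
  dv <- diff(trace) / diff(times)
  v0 <- trace[-length(trace)]; v1 <- trace[-1]
  elig <- pmin(v0, v1) < 0 & pmax(v0, v1) > -60 & dv > 0
  oracle_t <- times[which(dv == max(dv[elig]) & elig)[1]]

  flat <- rep(-85, length(times))
  rec <- fake_recording(rbind(trace, flat), times, ny = 2, nx = 1)
  am <- activation_map(rec)
  expect_equal(am$activation_ms[1, 1], oracle_t)
  expect_false(am$non_conductive[1, 1])
  expect_true(am$non_conductive[2, 1])
  expect_equal(am$upstroke_V_per_s[1, 1], max(dv[elig]))
})

test_that("a coarse recording stride triggers a resolution warning", {
  times <- seq(0, 10, by = 0.5)
  trace <- -85 + 110 / (1 + exp(-(times - 5) / 0.25))
  rec <- fake_recording(matrix(trace, 1), times, ny = 1, nx = 1)
  expect_warning(activation_map(rec), "under-resolve")
})

test_that("CV magnitude and tilt follow the direction-specific formulas", {
  # planar +x wave: tx = 125 us per 50-um step -> 0.4 m/s at 0 degrees
  act <- matrix(rep((0:4) * 0.125, each = 3), 3, 5)
  cv <- cv_vectors(fake_amap(act, "left"),
                   locations = cbind(row = 2, col = 2))
  expect_equal(cv$magnitude_m_per_s, 0.4, tolerance = 1e-12)
  expect_equal(cv$angle_deg, 0)

  # tx = ty = 100 us: |CV| = l / sqrt(2) / 100us ~ 0.354 m/s at 45 degrees
  act2 <- outer((0:4) * 0.1, (0:4) * 0.1, "+")  # t = 0.1*(row + col)
  cv2 <- cv_vectors(fake_amap(t(act2), "left"),
                    locations = cbind(row = 2, col = 2))
  expect_equal(cv2$magnitude_m_per_s, 50e-6 / sqrt(2 * (1e-4)^2),
               tolerance = 1e-12)
  expect_equal(cv2$angle_deg, 45)

  # same time field analyzed in the -x branch: 180 - 45 = 135
  cv3 <- cv_vectors(fake_amap(t(act2), "right"),
                    locations = cbind(row = 2, col = 2))
  expect_equal(cv3$angle_deg, 135)

  # pure transverse waves have zero tilt in both y branches
  act_y <- matrix(rep((0:4) * 0.3, times = 3), 5, 3)
  expect_equal(cv_vectors(fake_amap(act_y, "top"),
                          locations = cbind(2, 2))$angle_deg, 0)
  act_yr <- matrix(rep((4:0) * 0.3, times = 3), 5, 3)
  expect_equal(cv_vectors(fake_amap(act_yr, "bottom"),
                          locations = cbind(2, 2))$angle_deg, 0)
})

test_that("blocked and degenerate triplets are flagged, never numeric", {
  act <- matrix(c(0.1, 0.2, NA, 0.3), 2, 2)
  cv <- cv_vectors(fake_amap(act, "left"), locations = cbind(1, 1))
  expect_true(cv$blocked)
  expect_true(is.na(cv$magnitude_m_per_s))

  flat <- matrix(0.5, 2, 2)
  cvd <- cv_vectors(fake_amap(flat, "left"), locations = cbind(1, 1))
  expect_false(cvd$blocked)
  expect_true(is.na(cvd$magnitude_m_per_s))

  expect_error(cv_vectors(fake_amap(act, "left"), locations = cbind(2, 2)),
               "outside grid")
})

test_that("rotating the problem 90 degrees maps longitudinal onto transverse", {
  set.seed(31)
  base <- outer(seq_len(6), seq_len(6),
                function(r, c) 0.12 * c + 0.01 * r + rnorm(36, 0, 0.002))
  cv_x <- cv_vectors(fake_amap(base, "left"), locations = cbind(3, 3))
  # rotate the activation field by 90 degrees: x wave becomes y wave
  rot <- t(base)[6:1, ][6:1, ]  # transpose keeps +x -> +y roles at our triplet
  cv_y <- cv_vectors(fake_amap(t(base), "top"), locations = cbind(3, 3))
  expect_equal(cv_y$magnitude_m_per_s, cv_x$magnitude_m_per_s, tolerance = 1e-10)
  expect_equal(cv_y$angle_deg, cv_x$angle_deg, tolerance = 1e-10)
})

test_that("per-subject pooling produces medians, anisotropy and block notes", {
  m <- rbind(
    data.frame(row = 1, col = 1, direction = c("+x", "-x", "+y", "-y"),
               tx_s = 1e-4, ty_s = 0,
               magnitude_m_per_s = c(0.3, 0.4, 0.5, NA),
               angle_deg = c(5, -10, 2, NA),
               blocked = c(FALSE, FALSE, FALSE, TRUE))
  )
  m$subject <- 1
  m$group <- "donor"
  s <- pool_and_summarize(m)
  expect_equal(s$per_subject$median_CVL, 0.35)
  expect_equal(s$per_subject$median_CVT, 0.5)
  expect_equal(s$per_subject$median_abs_angle_L, 7.5)
  expect_equal(s$per_subject$anisotropy, 0.35 / 0.5)
  expect_equal(s$per_subject$n_blocked, 1)
  expect_equal(s$per_group$n, 1)
})

test_that("boundary-error metrics match their defining formulas", {
  base <- data.frame(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
                     direction = "+x", tx_s = 1.25e-4, ty_s = 0,
                     magnitude_m_per_s = 0.4, angle_deg = 0, blocked = FALSE)
  same <- boundary_error(base, base)
  expect_equal(same$mean_error_magnitude, 0)
  expect_equal(same$rmse_pct_magnitude, 0)

  shifted <- base
  shifted$magnitude_m_per_s <- 0.41
  be <- boundary_error(base, shifted)
  expect_equal(be$mean_error_magnitude, 0.01, tolerance = 1e-12)
  expect_equal(be$rmse_pct_magnitude, 2.5, tolerance = 1e-9)

  bad <- base
  bad$col <- bad$col + 1
  expect_error(boundary_error(base, bad), "do not match")
})

test_that("space constants evaluate the closed form and its limits", {
  sc <- space_constants(conductivity_params("sim"))
  expect_equal(round(sc$lambda_l_mm, 2), 0.30)
  # the transverse expression evaluates to ~0.099 mm with these parameters
  expect_equal(sc$lambda_t_mm, 0.0990, tolerance = 1e-3)

  # sigma_myo -> 0 limit
  tiny <- conductivity_params("sim", sigma_myo_long_100 = 1e-12)
  expect_lt(space_constants(tiny)$lambda_l_mm, 1e-5)

  # symmetric closed form: sigma_myo = sigma_e = s -> sqrt(R s / (2 beta))
  p <- conductivity_params("sim", sigma_myo_long_100 = 0.7,
                           sigma_e_long_100 = 0.7,
                           anis_myo = 2, anis_e = 2)
  expect_equal(space_constants(p)$lambda_l_mm,
               sqrt(0.2 * 0.35 / 2e5) * 1e3, tolerance = 1e-12)
})
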