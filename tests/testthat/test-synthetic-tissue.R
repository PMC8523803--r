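test_that("generation is deterministic and masks are disjoint", {
  spec <- small_spec("NIC", seed = 11)
  a <- generate_tissue(spec)
  b <- generate_tissue(spec)
  expect_identical(a$es, b$es)
  expect_identical(a$fib, b$fib)
  expect_identical(a$myofib, b$myofib)
  expect_false(any(a$fib & a$myofib))
  expect_false(any(a$es & (a$fib | a$myofib)))
})

test_that("saturated compact spec gives an all-ones non-myocyte mask", {
  spec <- small_spec("IC",
    target_Vnm = 1, target_sigma_intra = 0,
    pattern_weights = c(compact = 1), target_Vf_plus_Vmf = 0
  )
  img <- generate_tissue(spec)
  expect_true(all(img$es))
  expect_equal(compute_fractions(img)$V_nm, 1.0)
})

test_that("measured V_nm and sigma_intra track the spec targets", {
  # donor example: target 22.09% must land in [20, 24]%
  img <- generate_tissue(small_spec("donor", target_Vnm = 0.2209, seed = 1))
  fr <- compute_fractions(img)
  expect_gt(fr$V_nm, 0.20)
  expect_lt(fr$V_nm, 0.24)

  # 100 seeded specs across groups: |measured - target| <= 2 points,
  # and sigma_intra within 3 points where a target was set
  set.seed(42)
  for (k in 1:100) {
    g <- sample(c("donor", "NIC", "IC"), 1)
    tv <- runif(1, 0.15, 0.6)
    ts <- runif(1, 4, 0.8 * 100 * sqrt(tv * (1 - tv)))
    spec <- small_spec(g, target_Vnm = tv, target_sigma_intra = ts, seed = k)
    img <- generate_tissue(spec)
    hp <- heterogeneity_profile(img)
    expect_lt(abs(compute_fractions(img)$V_nm - tv), 0.02)
    expect_lt(abs(hp$sigma_intra - ts), 3)
  }
})

test_that("calibration solves the tile mixture and flags infeasible targets", {
  # IC-like target reachable with patchy/compact mass
  cal <- calibrate_generator(small_spec("IC",
    target_Vnm = 0.47, target_sigma_intra = 27.1
  ))
  expect_true(cal$converged)
  expect_lt(abs(cal$achieved_Vnm - 47), 2)
  expect_lt(abs(cal$achieved_sigma_intra - 27.1), 2)

  # homogeneous limit: tiny sigma with pure interstitial pattern
  img <- generate_tissue(small_spec("donor",
    target_Vnm = 0.25, target_sigma_intra = 0.5,
    pattern_weights = c(interstitial = 1), seed = 3
  ))
  expect_lt(heterogeneity_profile(img)$sigma_intra, 3)

  # sigma far above the Bernoulli bound cannot be reached
  expect_warning(
    calibrate_generator(small_spec("donor",
      target_Vnm = 0.1, target_sigma_intra = 80,
      pattern_weights = c(interstitial = 0.5, compact = 0.5)
    )),
    "closest achieved"
  )
})

test_that("checker-like tile targets reproduce the brute-force tile SD", {
  # direct oracle: a known half-empty/half-full tile layout has
  # sd(c(0,1,...)) * 100 heterogeneity; build it as an explicit mask
  px_nm <- 2000
  n <- 250  # 500 um, 10x10 tiles of 25 px
  tile <- 25
  mask <- matrix(FALSE, n, n)
  for (i in 0:9) {
    for (j in 0:9) {
      if ((i + j) %% 2 == 0) {
        mask[(i * tile + 1):((i + 1) * tile), (j * tile + 1):((j + 1) * tile)] <- TRUE
      }
    }
  }
  img <- tissue_image(mask, mask & FALSE, mask & FALSE, pixel_size_nm = px_nm)
  hp <- heterogeneity_profile(img)
  oracle <- 100 * sd(rep(c(0, 1), each = 50))
  expect_equal(hp$sigma_intra, oracle, tolerance = 1e-12)
  expect_equal(hp$mean_Vnm, 0.5, tolerance = 1e-12)
})

test_that("patchy/compact weight raises heterogeneity monotonically", {
  w_hi <- seq(0, 0.8, by = 0.1)
  sig <- vapply(seq_along(w_hi), function(k) {
    w <- w_hi[k]
    spec <- small_spec("IC",
      target_Vnm = 0.4, target_sigma_intra = NULL,
      pattern_weights = c(interstitial = 1 - w, patchy = w / 2, compact = w / 2),
      seed = 100 + k
    )
    heterogeneity_profile(generate_tissue(spec))$sigma_intra
  }, numeric(1))
  expect_gt(cor(w_hi, sig, method = "spearman"), 0.9)
})

test_that("cohort generation matches group statistics and handles edge cases", {
  empty <- generate_cohort(0, 0, 0, seed = 1)
  expect_length(empty, 0)

  coh <- generate_cohort(5, 8, 8, seed = 7, image_edge_um = 500,
                         pixel_size_nm = 2000)
  groups <- attr(coh, "groups")
  expect_length(coh, 21)
  expect_equal(sum(groups == "donor"), 5)
  q <- quantify_cohort(coh)
  expect_gt(mean(q$V_nm[q$group == "IC"]), mean(q$V_nm[q$group == "NIC"]))
  # donor heterogeneity should sit near the 7.47% group mean
  expect_lt(abs(mean(q$sigma_intra[q$group == "donor"]) - 7.47), 3)
  # fibroblast + myofibroblast mass around 2-2.5%
  expect_true(all(q$V_f + q$V_mf > 0.005 & q$V_f + q$V_mf < 0.05))
})

test_that("images round-trip through PNG + sidecar", {
  img <- generate_tissue(small_spec("donor", seed = 5))
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "subj1")
  write_tissue_image(img, prefix)
  back <- read_tissue_image(prefix)
  expect_identical(back$es, img$es)
  expect_identical(back$fib, img$fib)
  expect_equal(back$pixel_size_nm, img$pixel_size_nm)
  expect_equal(back$myocyte_axis, img$myocyte_axis)
})
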