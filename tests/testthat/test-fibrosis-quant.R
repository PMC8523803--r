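make_image <- function(es, fib = NULL, myofib = NULL, px_nm = 2000) {
  z <- matrix(FALSE, nrow(es), ncol(es))
  tissue_image(es, if (is.null(fib)) z else fib,
               if (is.null(myofib)) z else myofib, pixel_size_nm = px_nm)
}

test_that("composition fractions equal brute-force pixel counts", {
  # trivial saturated and half-filled cases
  ones <- matrix(TRUE, 40, 40)
  img <- make_image(ones)
  fr <- compute_fractions(img)
  expect_equal(fr$V_e, 1.0)
  expect_equal(fr$V_nm, 1.0)

  half <- matrix(FALSE, 40, 40)
  half[, 1:20] <- TRUE
  expect_equal(compute_fractions(make_image(half))$V_e, 0.5)

  # random masks vs independent counting, and the composition identity
  set.seed(9)
  for (k in 1:5) {
    es <- matrix(runif(900) < 0.3, 30, 30)
    fib <- matrix(runif(900) < 0.05, 30, 30) & !es
    mf <- matrix(runif(900) < 0.05, 30, 30) & !es & !fib
    img <- tissue_image(es, fib, mf, pixel_size_nm = 2000)
    fr <- compute_fractions(img)
    expect_identical(fr$V_e, sum(es) / 900)
    expect_identical(fr$V_f, sum(fib) / 900)
    expect_identical(fr$V_mf, sum(mf) / 900)
    expect_identical(fr$V_nm, fr$V_e + fr$V_f + fr$V_mf)
  }
})

test_that("roi handling: subsetting, empty and out-of-bounds rois", {
  es <- matrix(FALSE, 30, 30)
  es[1:10, 1:10] <- TRUE
  img <- make_image(es)
  fr <- compute_fractions(img, roi = list(rows = c(1, 10), cols = c(1, 10)))
  expect_equal(fr$V_e, 1.0)
  expect_error(compute_fractions(img, roi = list(rows = c(5, 2), cols = c(1, 3))),
               "bounds")
  expect_error(compute_fractions(img, roi = list(rows = c(1, 40), cols = c(1, 3))),
               "bounds")
})

test_that("fibrosis measure is the offset from the donor mean", {
  expect_equal(compute_fibrosis(0.3968, 0.2209), 0.1759)
  expect_equal(compute_fibrosis(0.37, 0.37), 0)
  expect_equal(compute_fibrosis(0.10, 0.2209), -0.1209)
})

test_that("a 1 mm image at acquisition resolution yields 400 tiles", {
  img <- generate_tissue(tissue_spec("donor", rng_seed = 2))
  hp <- heterogeneity_profile(img)
  expect_equal(hp$n_tiles, 400L)
  expect_equal(dim(hp$tile_Vnm), c(20L, 20L))
  expect_equal(mean(hp$tile_Vnm), hp$mean_Vnm)
  expect_equal(sum(hp$histogram$probability), 1)
})

test_that("heterogeneity is zero for uniform masks and matches the sample SD", {
  img <- make_image(matrix(TRUE, 250, 250))
  expect_equal(heterogeneity_profile(img)$sigma_intra, 0)

  # 50-um checkerboard of empty/full tiles: sample SD of half zeros, half ones
  n <- 250; tile <- 25
  mask <- matrix(FALSE, n, n)
  for (i in 0:9) for (j in 0:9) {
    if ((i + j) %% 2 == 0) {
      mask[(i * tile + 1):((i + 1) * tile), (j * tile + 1):((j + 1) * tile)] <- TRUE
    }
  }
  hp <- heterogeneity_profile(make_image(mask))
  expect_equal(hp$sigma_intra, 100 * sd(rep(c(0, 1), each = 50)), tolerance = 1e-12)

  expect_error(heterogeneity_profile(make_image(matrix(TRUE, 10, 10))),
               "smaller than one tile")
})

test_that("sigma_intra is invariant to mirroring and tile order", {
  img <- generate_tissue(small_spec("NIC", seed = 21))
  hp <- heterogeneity_profile(img)
  mirrored <- tissue_image(img$es[, rev(seq_len(ncol(img$es)))],
                           img$fib[, rev(seq_len(ncol(img$fib)))],
                           img$myofib[, rev(seq_len(ncol(img$myofib)))],
                           pixel_size_nm = img$pixel_size_nm)
  hp_m <- heterogeneity_profile(mirrored)
  expect_equal(hp_m$sigma_intra, hp$sigma_intra, tolerance = 1e-12)
  expect_equal(sort(as.numeric(hp_m$tile_Vnm)), sort(as.numeric(hp$tile_Vnm)),
               tolerance = 1e-12)
})

test_that("patch geometry matches the closed-form moment ellipse", {
  # 100 x 20 um solid rectangle at 1 um pixels
  es <- matrix(FALSE, 60, 140)
  es[21:40, 21:120] <- TRUE
  pg <- patch_geometry(es, pixel_size_nm = 1000)
  expect_equal(pg$n_patches, 1L)
  expect_equal(pg$largest_area_um2, 2000)
  # continuous rectangle: major = 4*sqrt(w^2/12) = 2w/sqrt(3)
  expect_equal(pg$mean_major_axis_um, 200 / sqrt(3), tolerance = 1e-3)
  expect_equal(pg$mean_minor_axis_um, 40 / sqrt(3), tolerance = 1e-3)
  expect_equal(pg$mean_axis_ratio, 5, tolerance = 1e-3)

  # sub-threshold blob: 10 x 10 um = 100 um^2 < 150 um^2
  small <- matrix(FALSE, 30, 30)
  small[10:19, 10:19] <- TRUE
  pg0 <- patch_geometry(small, pixel_size_nm = 1000)
  expect_equal(pg0$n_patches, 0L)
  expect_true(is.na(pg0$largest_area_um2))

  # disc: axis ratio 1, standard eccentricity 0
  d <- 41
  xy <- expand.grid(r = 1:d, c = 1:d)
  disc <- matrix((xy$r - 21)^2 + (xy$c - 21)^2 <= 15^2, d, d)
  pgd <- patch_geometry(disc, pixel_size_nm = 1000)
  expect_equal(pgd$mean_axis_ratio, 1, tolerance = 1e-2)
  expect_lt(pgd$mean_eccentricity, 0.15)
})

test_that("patch features are translation invariant and 8-connected", {
  base <- matrix(FALSE, 80, 80)
  base[10:25, 10:40] <- TRUE
  shift <- matrix(FALSE, 80, 80)
  shift[40:55, 30:60] <- TRUE
  p1 <- patch_geometry(base, pixel_size_nm = 1000)
  p2 <- patch_geometry(shift, pixel_size_nm = 1000)
  expect_equal(p1$largest_area_um2, p2$largest_area_um2)
  expect_equal(p1$mean_major_axis_um, p2$mean_major_axis_um, tolerance = 1e-12)

  # diagonal strand stays one component under 8-connectivity
  diag_mask <- matrix(FALSE, 40, 40)
  for (k in 1:30) diag_mask[k, k] <- TRUE
  lab <- cardiofib:::label_components8(diag_mask)
  expect_equal(max(lab), 1L)
})

test_that("moment axes agree with an independent image-analysis implementation", {
  skip_if_not_installed("EBImage")
  # well-separated solid patches so 4- and 8-connectivity agree
  es <- matrix(FALSE, 120, 120)
  es[10:29, 10:59] <- TRUE    # 20 x 50 rectangle
  es[50:79, 20:39] <- TRUE    # 30 x 20 rectangle
  es[90:110, 60:110] <- TRUE  # 21 x 51 rectangle
  pg <- patch_geometry(es, pixel_size_nm = 1000, min_area_um2 = 150)
  lab <- EBImage::bwlabel(EBImage::Image(es * 1))
  mom <- EBImage::computeFeatures.moment(lab)
  expect_equal(pg$n_patches, nrow(mom))
  expect_equal(sort(pg$patches$major_axis_um),
               sort(as.numeric(mom[, "m.majoraxis"])), tolerance = 0.02)
  expect_equal(sort(pg$patches$eccentricity),
               sort(as.numeric(mom[, "m.eccentricity"])), tolerance = 0.02)
})
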