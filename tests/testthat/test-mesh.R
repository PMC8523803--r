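test_that("downsampling equals brute-force footprint averaging", {
  set.seed(6)
  es <- matrix(runif(250 * 250) < 0.3, 250, 250)
  img <- tissue_image(es, es & FALSE, es & FALSE, pixel_size_nm = 2000)
  fr <- downsample_fractions(img)  # 50-um elements = 25 px
  expect_equal(dim(fr$V_e), c(10L, 10L))
  for (k in 1:5) {
    i <- sample(10, 1); j <- sample(10, 1)
    block <- es[((i - 1) * 25 + 1):(i * 25), ((j - 1) * 25 + 1):(j * 25)]
    expect_identical(fr$V_e[i, j], mean(block))
  }
  # whole-image V_nm preserved exactly (complete tiling)
  expect_equal(mean(fr$V_e), mean(es), tolerance = 1e-12)

  ones <- tissue_image(matrix(TRUE, 100, 100), matrix(FALSE, 100, 100),
                       matrix(FALSE, 100, 100), pixel_size_nm = 2000)
  expect_true(all(downsample_fractions(ones)$V_e == 1))

  expect_error(downsample_fractions(
    tissue_image(matrix(TRUE, 10, 10), matrix(FALSE, 10, 10),
                 matrix(FALSE, 10, 10), pixel_size_nm = 2000)
  ), "smaller than one tile")
})

test_that("a 1 mm image gives a 20 x 20 element mesh", {
  img <- generate_tissue(tissue_spec("donor", rng_seed = 3))
  fr <- downsample_fractions(img)
  expect_equal(dim(fr$V_e), c(20L, 20L))
  mesh <- build_mesh(fr)
  expect_equal(mesh$ny * mesh$nx, 400L)
})

test_that("mesh construction evaluates the fraction-scaled conductivities", {
  p5 <- conductivity_params("high")  # sigma_myo_long_100 = 0.5
  mesh <- homogeneous_mesh(V_e = 0.2, ny = 2, nx = 2, params = p5)
  # V_myo = 0.8: sigma_myo = diag(0.4, 0.04); sigma_e = diag(0.2, 0.1)
  expect_equal(mesh$V_myo[1, 1], 0.8)
  expect_equal(mesh$sigma_myo_l[1, 1], 0.4)
  expect_equal(mesh$sigma_myo_t[1, 1], 0.04)
  expect_equal(mesh$sigma_e_l[1, 1], 0.2)
  expect_equal(mesh$sigma_e_t[1, 1], 0.1)

  # beta_myo at V_myo = 1: reciprocal of the single-myocyte volume
  full <- homogeneous_mesh(V_e = 0, ny = 1, nx = 2)
  expect_equal(full$beta_myo[1, 1], 1 / (41073e-18), tolerance = 1e-9)
  expect_equal(full$beta_myo[1, 1], 2.435e13, tolerance = 1e-3)

  # all-ES element: passive, no myocyte conductivity, no membrane
  es_el <- homogeneous_mesh(V_e = 1, ny = 1, nx = 2)
  expect_equal(es_el$V_myo[1, 1], 0)
  expect_equal(es_el$sigma_myo_l[1, 1], 0)
  expect_equal(es_el$beta_myo[1, 1], 0)
  expect_false(any(es_el$active))

  expect_error(
    build_mesh(list(V_e = matrix(0.8, 2, 2), V_f = matrix(0.3, 2, 2),
                    V_mf = matrix(0, 2, 2), element_edge_um = 50)),
    "negative myocyte fraction"
  )
})

test_that("composition identity and linearity hold per element", {
  set.seed(12)
  Ve <- matrix(runif(36, 0.1, 0.5), 6, 6)
  Vf <- matrix(runif(36, 0, 0.02), 6, 6)
  Vmf <- matrix(runif(36, 0, 0.02), 6, 6)
  fr <- list(V_e = Ve, V_f = Vf, V_mf = Vmf, element_edge_um = 50)
  mesh <- build_mesh(fr)
  expect_equal(mesh$V_myo + mesh$V_e + mesh$V_f + mesh$V_mf,
               matrix(1, 6, 6), tolerance = 1e-14)
  expect_true(all(mesh$sigma_myo_l >= 0 & mesh$sigma_e_l >= 0))

  # scaling base conductivities scales tensors identically
  p1 <- conductivity_params("sim")
  p3 <- conductivity_params("sim", sigma_myo_long_100 = 0.3, sigma_e_long_100 = 3)
  m1 <- build_mesh(fr, p1)
  m3 <- build_mesh(fr, p3)
  expect_equal(m3$sigma_myo_l, 3 * m1$sigma_myo_l, tolerance = 1e-12)
  expect_equal(m3$sigma_e_t, 3 * m1$sigma_e_t, tolerance = 1e-12)
})

test_that("homogeneous extension centers the mesh and uses flank means", {
  img <- generate_tissue(small_spec("donor", seed = 8))
  mesh <- build_mesh(downsample_fractions(img))
  ext <- extend_homogeneous(mesh, total_length_x_mm = 2.5)  # 500 um -> 2.5 mm
  expect_equal(ext$nx, 50L)
  cols <- attr(ext, "embedded_cols")
  expect_equal(length(cols), mesh$nx)
  expect_equal(ext$V_e[, cols], mesh$V_e)
  flank <- setdiff(seq_len(ext$nx), cols)
  expect_equal(unique(as.numeric(ext$V_e[, flank])), mean(mesh$V_e),
               tolerance = 1e-12)

  # homogeneous input: extension statistics indistinguishable from input
  hom <- homogeneous_mesh(V_e = 0.25, ny = 4, nx = 10)
  he <- extend_homogeneous(hom, total_length_x_mm = 1)
  expect_equal(unique(as.numeric(he$V_e)), 0.25)

  expect_error(extend_homogeneous(mesh, total_length_x_mm = 0.4),
               "exceed")
})
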