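test_that("homogeneous phantom carries the requested moduli everywhere", {
  ph <- build_property_phantom(regions = list(
    brain = list(gd = 5000, gl = 2000)))
  inside <- ph$labels == region_labels()[["brain"]]
  expect_true(all(ph$gd[inside] == 5000))
  expect_true(all(ph$gl[inside] == 2000))
  expect_identical(dim(ph$gd), c(64L, 64L, 9L))
  expect_equal(ph$spacing, c(0.3, 0.3, 0.3))
})

test_that("regions voxelize with exact labels and priority", {
  ph <- build_property_phantom(regions = list(
    brain = list(gd = 5000),
    corpus_callosum = list(gd = 4440, shape = "band",
                           center_mm = c(9.45, 6, 1.2), curvature = 0.04,
                           half_thickness_mm = 0.45, half_length_mm = 6,
                           half_depth_mm = 10)))
  lv <- region_labels()
  expect_setequal(unique(as.vector(ph$labels)),
                  lv[c("background", "brain", "corpus_callosum")])
  expect_true(all(ph$gd[ph$labels == lv[["corpus_callosum"]]] == 4440))
  expect_true(all(ph$gd[ph$labels == lv[["brain"]]] == 5000))
})

test_that("an ellipsoid calibrated to a target volume matches it within one voxel", {
  ph <- build_property_phantom(regions = list(
    brain = list(gd = 5000),
    tumor_core = list(gd = 3600, shape = "ellipsoid",
                      center_mm = c(11, 11, 1.2), radii_mm = c(1.2, 1, 0.9),
                      volume_mm3 = 16.88)))
  nvox <- sum(ph$labels == region_labels()[["tumor_core"]])
  vox <- prod(ph$spacing)
  expect_lt(abs(nvox * vox - 16.88), vox + 1e-12)
})

test_that("negative storage modulus is rejected", {
  expect_error(build_property_phantom(regions = list(
    brain = list(gd = -1))), "positive")
})

test_that("phantom tensors are symmetric positive semi-definite", {
  ph <- build_property_phantom(regions = list(brain = list(
    eigenvalues = c(1.7, 0.2, 0.2) * 1e-3, axis = c(1, 1, 0) / sqrt(2))))
  i <- which(ph$labels == 1, arr.ind = TRUE)[1, ]
  comp <- ph$tensors[i[1], i[2], i[3], ]
  D <- matrix(c(comp[1], comp[4], comp[5],
                comp[4], comp[2], comp[6],
                comp[5], comp[6], comp[3]), 3, 3)
  expect_equal(D, t(D))
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-15))
  expect_equal(sort(ev), sort(c(1.7, 0.2, 0.2) * 1e-3), tolerance = 1e-10)
})

test_that("echo train synthesis follows the exact mono-exponential decay", {
  ph <- build_property_phantom(grid_shape = c(4, 4, 3),
                               regions = list(brain = list(t2 = 40)))
  tr <- synthesize_echo_train(ph, te_list = c(20, 40, 60), s0 = 1000,
                              noise_sd = 0)
  inside <- ph$labels == 1
  expect_equal(tr$signal[, , , 2][inside],
               rep(1000 / exp(1), sum(inside)), tolerance = 1e-12)
  ## log-linearity across the default 30 echoes
  tr30 <- synthesize_echo_train(ph, s0 = 1000, noise_sd = 0)
  i <- which(inside, arr.ind = TRUE)[1, ]
  lsig <- log(tr30$signal[i[1], i[2], i[3], ])
  slopes <- diff(lsig) / diff(tr30$te)
  expect_equal(slopes, rep(-1 / 40, length(slopes)), tolerance = 1e-10)
  ## background (zero T2) flagged and silent
  expect_true(all(tr$signal[, , , 1][!inside] == 0))
  expect_true(all(tr$zero_t2[!inside]))
})

test_that("magnitude noise has the Rayleigh mean in signal-free voxels", {
  ## Monte-Carlo of the two-channel magnitude model: mean of |noise| is
  ## sigma * sqrt(pi / 2)
  ph <- build_property_phantom(grid_shape = c(64, 64, 9),
                               regions = list(brain = list(t2 = 40)))
  tr <- synthesize_echo_train(ph, te_list = c(500, 600, 700, 800, 900,
                                              1000, 1100, 1200),
                              s0 = 1000, noise_sd = 10, seed = 7)
  bg <- ph$labels == 0
  vals <- matrix(tr$signal, ncol = 8)[as.vector(bg), ]
  expect_gt(length(vals), 1e5)
  expect_equal(mean(vals), 10 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("dwi synthesis matches the tensor forward model and round-trips", {
  ph <- build_property_phantom(grid_shape = c(6, 6, 3), regions = list(
    brain = list(eigenvalues = c(0.6, 0.6, 0.6) * 1e-3)))
  dwi <- synthesize_dwi(ph, noise_sd = 0)
  inside <- ph$labels == 1
  ## isotropic: S/S0 = exp(-b * MD) for every direction
  for (k in c(2, 12, 31))
    expect_equal(dwi$signal[, , , k][inside] / 1000,
                 rep(exp(-1500 * 0.6e-3), sum(inside)), tolerance = 1e-12)
  ## anisotropic along the gradient axis
  ph2 <- build_property_phantom(grid_shape = c(6, 6, 3), regions = list(
    brain = list(eigenvalues = c(1.7, 0.2, 0.2) * 1e-3, axis = c(1, 0, 0))))
  dwi2 <- synthesize_dwi(ph2, directions = rbind(c(1, 0, 0), c(0, 1, 0),
                                                 c(0, 0, 1), c(1, 1, 0) / sqrt(2),
                                                 c(1, 0, 1) / sqrt(2),
                                                 c(0, 1, 1) / sqrt(2)),
                         noise_sd = 0)
  expect_equal(dwi2$signal[2, 2, 2, 2] / 1000, exp(-1500 * 1.7e-3),
               tolerance = 1e-12)
  expect_error(synthesize_dwi(ph, bvalue = -5), "non-negative")
  expect_error(synthesize_dwi(ph, directions = matrix(c(2, 0, 0), 1, 3)),
               "unit-norm")
})

test_that("generators are bitwise deterministic under a fixed seed", {
  ph <- build_property_phantom(grid_shape = c(8, 8, 3))
  t1 <- synthesize_echo_train(ph, noise_sd = 5, seed = 11)
  t2 <- synthesize_echo_train(ph, noise_sd = 5, seed = 11)
  expect_identical(t1$signal, t2$signal)
  d1 <- synthesize_dwi(ph, noise_sd = 5, seed = 11)
  d2 <- synthesize_dwi(ph, noise_sd = 5, seed = 11)
  expect_identical(d1$signal, d2$signal)
  c1 <- build_longitudinal_cohort(seed = 3)
  c2 <- build_longitudinal_cohort(seed = 3)
  expect_identical(c1$truth, c2$truth)
})

test_that("seeded generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(1)
  set.seed(99)
  invisible(synthesize_echo_train(build_property_phantom(
    grid_shape = c(4, 4, 3)), noise_sd = 1, seed = 5))
  b <- rnorm(1)
  expect_identical(a, b)
})
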