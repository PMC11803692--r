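test_that("plane wave has the closed-form shear wavelength and decay", {
  ph <- homogeneous_phantom(5000, 0)
  fld <- plane_wave_field(ph, propagation = c(1, 0, 0),
                          polarization = c(0, 1, 0))
  ## c = sqrt(G / rho) -> lambda = c / f = 2.4845 mm at 5 kPa, 900 Hz
  lambda_mm <- 2 * pi / Re(fld$wavenumber) * 1e3
  expect_equal(lambda_mm, sqrt(5000 / 1000) / 900 * 1e3, tolerance = 1e-12)
  expect_equal(lambda_mm, 2.4845, tolerance = 1e-4)
  ## lossless: no attenuation along propagation
  amp <- Mod(fld$u[, 1, 1, 2])
  expect_equal(max(amp) - min(amp), 0, tolerance = 1e-18)

  ## viscoelastic: monotone decay at rate -Im(k)
  phv <- homogeneous_phantom(5000, 2000)
  fv <- plane_wave_field(phv, propagation = c(1, 0, 0),
                         polarization = c(0, 1, 0))
  ampv <- Mod(fv$u[, 1, 1, 2])
  expect_true(all(diff(ampv) < 0))
  decay <- diff(log(ampv)) / (0.3e-3)
  expect_equal(decay, rep(Im(fv$wavenumber), length(decay)),
               tolerance = 1e-9)
  ## decay branch: Im(k) <= 0 under the e^{i w t} convention
  expect_lte(Im(fv$wavenumber), 0)
})

test_that("plane wave rejects non-shear and heterogeneous setups", {
  ph <- homogeneous_phantom()
  expect_error(plane_wave_field(ph, propagation = c(1, 0, 0),
                                polarization = c(1, 0, 0)), "orthogonal")
  ph2 <- build_property_phantom(regions = list(
    brain = list(gd = 5000),
    tumor_core = list(gd = 8000, shape = "ellipsoid",
                      center_mm = c(9.45, 9.45, 1.2),
                      radii_mm = c(2, 2, 1))))
  expect_error(plane_wave_field(ph2), "not homogeneous")
})

test_that("heterogeneous solver matches the plane-wave oracle when anchored", {
  ## lossy homogeneous medium resolved at ~35 voxels per wavelength;
  ## analytic values anchor both x faces, symmetry (Neumann) sides
  ph <- build_property_phantom(grid_shape = c(32, 24, 12), regions = list(
    brain = list(gd = 80000, gl = 32000, shape = "ellipsoid",
                 center_mm = c(4.65, 3.45, 1.65), radii_mm = c(99, 99, 99))))
  pw <- plane_wave_field(ph, propagation = c(1, 0, 0),
                         polarization = c(0, 1, 0), amplitude = 30e-6)
  far <- matrix(pw$u[32, , , 2], 24, 12)
  sol <- solve_heterogeneous_helmholtz(
    ph, source_face = "x-", source_amplitude = 30e-6,
    polarization = c(0, 1, 0), extra_dirichlet = list("x+" = far),
    side_bc = "neumann")
  expect_lt(sol$residual, 1e-8)
  rel <- abs(Mod(sol$u[, , , 2]) / Mod(pw$u[, , , 2]) - 1)
  expect_lt(max(rel), 0.02)
})

test_that("solver is linear in the source amplitude", {
  ph <- build_property_phantom(grid_shape = c(20, 20, 9), regions = list(
    brain = list(gd = 5000, gl = 2000, shape = "ellipsoid",
                 center_mm = c(2.85, 2.85, 1.2), radii_mm = c(99, 99, 99))))
  s1 <- solve_heterogeneous_helmholtz(ph, source_amplitude = 30e-6)
  s2 <- solve_heterogeneous_helmholtz(ph, source_amplitude = 60e-6)
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-12)
})

test_that("a stiff inclusion carries a longer local wavelength", {
  ph <- build_property_phantom(grid_shape = c(48, 48, 9), regions = list(
    brain = list(gd = 4000, gl = 800, shape = "ellipsoid",
                 center_mm = c(7.05, 7.05, 1.2), radii_mm = c(99, 99, 99)),
    tumor_core = list(gd = 8000, gl = 1600, shape = "ellipsoid",
                      center_mm = c(7.05, 7.05, 1.2),
                      radii_mm = c(3, 3, 1.6))))
  sol <- solve_heterogeneous_helmholtz(ph, source_face = "x-",
                                       polarization = c(0, 1, 0))
  ## local wavenumber from the unwrapped phase slope along x rows
  row_k <- function(y) {
    phase <- Arg(sol$u[, y, 5, 2])
    steps <- diff(phase)
    steps <- steps - 2 * pi * round(steps / (2 * pi))
    abs(steps) / 0.3          # rad / mm
  }
  inc_rows <- which(apply(ph$labels[, , 5] == 3, 2, any))
  ymid <- inc_rows[ceiling(length(inc_rows) / 2)]
  inc_cols <- which(ph$labels[, ymid, 5] == 3)
  k_inside <- mean(row_k(ymid)[inc_cols[-length(inc_cols)]])
  ## background sampled upstream of the inclusion on the same row
  bg_cols <- setdiff(8:(min(inc_cols) - 2), inc_cols)
  k_bg <- mean(row_k(ymid)[bg_cols])
  expect_lt(k_inside, k_bg)                     # longer wavelength inside
  expect_equal(k_inside / k_bg, sqrt(4000 / 8000), tolerance = 0.25)
})

test_that("compressional component is curl-free and additive", {
  ph <- homogeneous_phantom(5000, 0)
  fld0 <- plane_wave_field(ph)
  fld0$u[] <- 0i
  comp <- add_compressional_component(fld0, amplitude = 30e-6,
                                      direction = c(2, 1, 2) / 3)
  q <- compute_curl(comp)
  scale <- 30e-6 / 0.3e-3
  expect_lt(max(Mod(q$q)[rep(q$validity, 3)]), 1e-3 * scale)
  ## amplitude zero is a bitwise identity
  fld <- plane_wave_field(ph)
  expect_identical(add_compressional_component(fld, 0), fld)
})

test_that("phase encoding samples the harmonic at quarter cycles", {
  ph <- homogeneous_phantom(5000, 0, grid_shape = c(4, 4, 3))
  fld <- plane_wave_field(ph)
  a <- 1e-5
  fld$u[] <- 0i
  fld$u[, , , 2] <- a + 0i                 # purely real displacement
  acq <- encode_wave_phases(fld, scale = 1e5, wrap = FALSE)
  samples <- acq$phase_images[1, 1, 1, 2, ]
  expect_equal(samples, 1e5 * a * c(1, 0, -1, 0), tolerance = 1e-12)
})

test_that("noiseless unwrapped encoding round-trips through the 4-point DFT", {
  fld <- plane_wave_field(homogeneous_phantom(5000, 2000))
  acq <- encode_wave_phases(fld, wrap = FALSE)
  rec <- extract_first_harmonic(acq)
  err <- max(Mod(rec$u / acq$scale - fld$u)) / max(Mod(fld$u))
  expect_lt(err, 1e-12)
})

test_that("wrapping is a no-op when phases stay in range", {
  fld <- plane_wave_field(homogeneous_phantom(5000, 0))
  sc <- 3 / max(Mod(fld$u))
  a1 <- encode_wave_phases(fld, scale = sc * 0.9, wrap = TRUE)
  a2 <- encode_wave_phases(fld, scale = sc * 0.9, wrap = FALSE)
  expect_lt(max(abs(a1$phase_images)), pi)
  expect_equal(a1$phase_images, a2$phase_images, tolerance = 1e-15)
})
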