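test_that("slice unwrapping restores smooth ramps up to a 2*pi constant", {
  ## steep ramp 0 -> 6 rad across a slice, wrapped
  ramp <- matrix(rep(seq(0, 6, length.out = 32), each = 32), 32, 32)
  stack <- array(ramp, c(32, 32, 1))
  wrapped <- elastoquant:::wrap_phase(stack)
  un <- unwrap_phase_stack(wrapped)
  resid <- (un - stack) / (2 * pi)
  expect_equal(resid, round(resid), tolerance = 1e-9)   # multiples of 2 pi
  expect_equal(max(un) - min(un), 6, tolerance = 1e-9)  # shape restored
  ## in-range smooth input is untouched
  small <- elastoquant:::wrap_phase(stack / 3)
  expect_equal(unwrap_phase_stack(small), small, tolerance = 1e-12)
})

test_that("noisy wrapped plane waves unwrap with rare errors", {
  ph <- homogeneous_phantom(5000, 0)
  fld <- plane_wave_field(ph)
  truth <- encode_wave_phases(fld, wrap = FALSE)
  noisy <- encode_wave_phases(fld, noise_sd_rad = 0.1, wrap = TRUE,
                              seed = 21)
  un <- unwrap_phase_stack(noisy)
  ## compare per slice up to its global 2*pi offset
  nfail <- 0; ntot <- 0
  for (d in 1:3) for (nn in 1:4) for (z in 1:9) {
    err <- un$phase_images[, , z, d, nn] - truth$phase_images[, , z, d, nn]
    err <- err - 2 * pi * round(median(err) / (2 * pi))
    nfail <- nfail + sum(abs(err) > pi / 2)
    ntot <- ntot + length(err)
  }
  expect_lt(nfail / ntot, 0.01)
})

test_that("slice alignment removes injected 2*pi offsets exactly", {
  base <- array(rep(seq(-1, 1, length.out = 16), 16 * 5), c(16, 16, 5))
  shifted <- base
  offs <- c(0, 2, 4, -2, 6) * pi
  for (z in 1:5) shifted[, , z] <- base[, , z] + offs[z]
  aligned <- align_slice_offsets(shifted)
  expect_equal(aligned, base, tolerance = 1e-12)
  ## an already-consistent stack is unchanged
  expect_equal(align_slice_offsets(base), base, tolerance = 1e-15)
})

test_that("through-slice wavenumber survives unwrap and alignment", {
  ph <- homogeneous_phantom(5000, 0)
  fld <- plane_wave_field(ph)           # oblique: k_z = k / sqrt(3)
  acq <- encode_wave_phases(fld, wrap = TRUE)
  un <- align_slice_offsets(unwrap_phase_stack(acq))
  vol <- un$phase_images[, , , 2, 1]
  dz <- apply(vol, c(1, 2), function(p) mean(diff(p))) / 0.3   # rad/mm
  k_true <- Re(plane_wave_field(ph)$wavenumber) / sqrt(3) / 1e3
  expect_equal(median(abs(dz)), k_true, tolerance = 0.05)
})

test_that("the 4-point DFT returns exact first-harmonic amplitude and phase", {
  expect_equal(extract_first_harmonic(c(1, 0, -1, 0)), 1 + 0i,
               tolerance = 1e-15)
  expect_equal(extract_first_harmonic(c(5, 5, 5, 5)), 0 + 0i,
               tolerance = 1e-15)
  th <- 2 * pi * (0:3) / 4
  h <- extract_first_harmonic(3 * cos(th + pi / 3))
  expect_equal(Mod(h), 3, tolerance = 1e-12)
  expect_equal(Arg(h), pi / 3, tolerance = 1e-12)
  expect_error(extract_first_harmonic(c(1, 0, -1)), "4 wave-phase")
})

test_that("curl annihilates gradients and matches the analytic plane-wave curl", {
  ph <- homogeneous_phantom(5000, 0)
  ## gradient field -> curl below discretization tolerance
  fld <- plane_wave_field(ph); fld$u[] <- 0i
  grad <- add_compressional_component(fld, amplitude = 1e-5,
                                      direction = c(1, 2, 2) / 3)
  qg <- compute_curl(grad)
  expect_lt(max(Mod(qg$q)[rep(qg$validity, 3)]), 1e-3 * 1e-5 / 0.3e-3)

  ## axis-aligned shear wave: q_z = -i k u_y; 20 voxels per wavelength so
  ## the second-order stencil's sinc error (~(kh)^2/6) sits under 2%
  ph <- homogeneous_phantom(29160, 0)
  pw <- plane_wave_field(ph, propagation = c(1, 0, 0),
                         polarization = c(0, 1, 0))
  q <- compute_curl(pw)
  k <- pw$wavenumber
  qz_expected <- -1i * k * pw$u[, , , 2]
  v <- q$validity
  rel <- Mod(q$q[, , , 3] - qz_expected) / Mod(qz_expected)
  expect_lt(median(rel[v]), 0.02)
  ## other curl components vanish for this geometry
  expect_lt(max(Mod(q$q[, , , 1])[v]), 1e-6 * max(Mod(qz_expected)))

  ## gradient contamination leaves the shear curl untouched within 2%
  mixed <- add_compressional_component(pw, amplitude = 30e-6,
                                       direction = c(1, 2, 2) / 3)
  qm <- compute_curl(mixed)
  rel_m <- Mod(qm$q[, , , 3] - q$q[, , , 3]) / Mod(qz_expected)
  expect_lt(max(rel_m[v]), 0.02)

  ## fewer than 3 slices cannot support z-derivatives
  thin <- plane_wave_field(homogeneous_phantom(grid_shape = c(8, 8, 2)))
  expect_error(compute_curl(thin), "3 slices")
})

test_that("Helmholtz inversion recovers homogeneous truth from clean waves", {
  el <- reconstruct_elastogram(oblique_acquisition(5000, 0))
  v <- el$validity
  expect_lt(abs(median(el$gstar[v]) / 5000 - 1), 0.05)
  expect_lt(median(el$y[v]), 0.05)

  elv <- reconstruct_elastogram(oblique_acquisition(5000, 2000))
  vv <- elv$validity
  expect_lt(abs(median(elv$gstar[vv]) / sqrt(5000^2 + 2000^2) - 1), 0.05)
  expect_lt(abs(median(elv$y[vv]) - (2 / pi) * atan(2000 / 5000)), 0.05)
})

test_that("recovered G* scales as rho * omega^2 for a fixed curl field", {
  fld <- plane_wave_field(homogeneous_phantom(5000, 2000))
  q <- compute_curl(fld)
  e1 <- invert_helmholtz(q, frequency = 900)
  e2 <- invert_helmholtz(q, frequency = 1800)
  v <- e1$validity & e2$validity
  expect_equal(e2$gd_raw[v], 4 * e1$gd_raw[v], tolerance = 1e-12)
  expect_equal(e2$gl_raw[v], 4 * e1$gl_raw[v], tolerance = 1e-12)
})

test_that("elastogram is invariant to the phase-to-displacement scale", {
  fld <- plane_wave_field(homogeneous_phantom(5000, 2000))
  a1 <- encode_wave_phases(fld, scale = 2.0 / max(Mod(fld$u)), wrap = FALSE)
  a2 <- encode_wave_phases(fld, scale = 0.5 / max(Mod(fld$u)), wrap = FALSE)
  e1 <- reconstruct_elastogram(a1)
  e2 <- reconstruct_elastogram(a2)
  v <- e1$validity & e2$validity
  expect_equal(e1$gstar[v], e2$gstar[v], tolerance = 1e-9)
})

test_that("reconstruction error shrinks as voxels per wavelength grow", {
  ## stiffness sets the wavelength on the fixed grid: 4, 6, 8, 12 vox/lambda
  vpl <- c(4, 6, 8, 12)
  gd <- 1000 * (900 * vpl * 0.3e-3)^2
  err <- vapply(gd, function(g) {
    el <- reconstruct_elastogram(oblique_acquisition(g, 0))
    abs(median(el$gstar[el$validity]) / g - 1)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[length(err)], 0.02)
})

test_that("compose_elastogram obeys the analytic identities and limits", {
  cmp <- compose_elastogram(3000, 4000)
  expect_equal(cmp$g_magnitude, 5000)
  expect_equal(cmp$y, (2 / pi) * atan2(4000, 3000))
  expect_equal(compose_elastogram(5000, 0)$y, 0)           # purely elastic
  expect_equal(compose_elastogram(0, 5000)$y, 1)           # purely viscous
  expect_equal(compose_elastogram(2000, 2000)$y, 0.5)
  expect_true(is.na(compose_elastogram(0, 0)$y))
  ## vectorized identities on random moduli
  set.seed(8)
  gdv <- runif(500, 0, 1e4); glv <- runif(500, 0, 1e4)
  cm <- compose_elastogram(gdv, glv)
  expect_equal(cm$g_magnitude, sqrt(gdv^2 + glv^2), tolerance = 1e-12)
  expect_true(all(cm$y >= 0 & cm$y <= 1))
  expect_true(all(pmax(gdv, glv) <= cm$g_magnitude + 1e-9))
  expect_true(all(cm$g_magnitude <= gdv + glv + 1e-9))
})

test_that("elastogram identities hold on every valid voxel of a reconstruction", {
  for (mod in list(c(5000, 0), c(5000, 2000), c(3000, 1500))) {
    el <- reconstruct_elastogram(oblique_acquisition(mod[1], mod[2]))
    v <- el$validity
    expect_equal(el$gstar[v], sqrt(el$gd[v]^2 + el$gl[v]^2),
                 tolerance = 1e-10)
    expect_true(all(el$y[v] >= 0 & el$y[v] <= 1))
    expect_true(all(el$gstar[v] >= pmax(el$gd[v], el$gl[v]) - 1e-9))
    expect_true(all(el$gstar[v] <= el$gd[v] + el$gl[v] + 1e-9))
  }
})
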