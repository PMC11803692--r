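## ---------------------------------------------------------------------------
## Time-harmonic shear-wave forward simulation and phase encoding
##
## Convention: physical displacement u(t) = Re{ U * exp(i w t) }, wavenumber
## k = w * sqrt(rho / G*) on the branch with Im(k) <= 0 so that
## exp(-i k (r . n)) decays along the propagation direction n in a lossy
## medium (Im(G*) > 0).
## ---------------------------------------------------------------------------

## complex shear modulus and wavenumber of a homogeneous phantom
homogeneous_modulus <- function(phantom) {
  inside <- phantom$labels != 0
  gd <- unique(phantom$gd[inside])
  gl <- unique(phantom$gl[inside])
  if (length(gd) != 1 || length(gl) != 1)
    stop("phantom is not homogeneous; use solve_heterogeneous_helmholtz()")
  complex(real = gd, imaginary = gl)
}

shear_wavenumber <- function(gstar, density, frequency) {
  w <- 2 * pi * frequency
  k <- w * sqrt(density / gstar)      # principal branch: Re > 0, Im <= 0
  if (Im(k) > 0) k <- -k
  k                                    # rad/m
}

#' Analytic plane shear-wave field in a homogeneous phantom
#'
#' Evaluates `U(r) = A * p * exp(-i k (r . n))` with complex wavenumber
#' `k = w sqrt(rho / G*)` chosen on the decaying branch. This closed form
#' is the validation oracle for the finite-difference solver and for the
#' reconstruction chain.
#'
#' @param phantom homogeneous `property_phantom` (constant moduli inside
#'   the labeled domain).
#' @param propagation unit propagation direction `n`.
#' @param polarization unit displacement direction `p`, orthogonal to `n`
#'   (shear wave).
#' @param amplitude displacement amplitude, meters.
#' @param frequency vibration frequency, Hz.
#' @return class `wave_field`: complex displacement array `u` with
#'   dimensions `c(grid, 3)`, plus `frequency`, `spacing` (mm), `density`.
#' @export
plane_wave_field <- function(phantom, propagation = c(1, 1, 1) / sqrt(3),
                             polarization = c(1, -1, 0) / sqrt(2),
                             amplitude = 30e-6, frequency = 900) {
  stopifnot(is_unit(propagation, 1e-6), is_unit(polarization, 1e-6))
  if (abs(sum(propagation * polarization)) > 1e-8)
    stop("polarization must be orthogonal to propagation for a shear wave")
  gstar <- homogeneous_modulus(phantom)
  k <- shear_wavenumber(gstar, phantom$density, frequency)
  proj_m <- projection_array(phantom$grid_shape, phantom$spacing,
                             propagation) * 1e-3     # mm -> m
  ph <- exp(-1i * k * proj_m)
  u <- array(0i, c(phantom$grid_shape, 3))
  for (c3 in 1:3) u[, , , c3] <- amplitude * polarization[c3] * ph
  structure(list(u = u, frequency = frequency, spacing = phantom$spacing,
                 density = phantom$density, wavenumber = k),
            class = "wave_field")
}

#' Finite-difference solve of the heterogeneous scalar Helmholtz equation
#'
#' Solves `div(G* grad u) + rho w^2 u = 0` per displacement component on
#' the voxel grid (second-order flux-conservative differences, face moduli
#' by arithmetic averaging), with the displacement prescribed on one grid
#' face and absorbing layers — a ramp of added loss modulus over
#' `absorbing_width` voxels backed by zero-displacement boundaries — on the
#' remaining faces. This scalar per-component treatment deliberately
#' matches the local-homogeneity physics assumed by the inversion it is
#' used to test; it does not model mode conversion at interfaces.
#'
#' @param phantom a `property_phantom` with positive storage modulus in
#'   the simulated domain.
#' @param source_face face carrying the prescribed displacement, one of
#'   `"x-"`, `"x+"`, `"y-"`, `"y+"`, `"z-"`, `"z+"`.
#' @param source_amplitude complex amplitude (meters) prescribed uniformly
#'   on the source face, or a matrix matching the face.
#' @param polarization unit displacement direction of the source.
#' @param frequency vibration frequency, Hz.
#' @param absorbing_width width of the absorbing ramp, voxels.
#' @param absorbing_strength peak added loss modulus as a multiple of the
#'   local storage modulus.
#' @param extra_dirichlet optional named list (face name -> complex
#'   values, scalar or face-shaped) of additional prescribed faces, e.g.
#'   analytic values anchoring the far face in a validation run.
#' @param side_bc treatment of the remaining (non-prescribed) faces:
#'   `"absorbing"` (default; loss ramp backed by zero displacement) or
#'   `"neumann"` (zero normal derivative — a symmetry boundary, exact for
#'   fields with no variation towards that face).
#' @return a `wave_field` (with `absorbing` mask marking the layers).
#' @export
solve_heterogeneous_helmholtz <- function(phantom, source_face = "x-",
                                          source_amplitude = 30e-6,
                                          polarization = c(0, 1, 0),
                                          frequency = 900,
                                          absorbing_width = 6,
                                          absorbing_strength = 2.5,
                                          extra_dirichlet = NULL,
                                          side_bc = c("absorbing",
                                                      "neumann")) {
  side_bc <- match.arg(side_bc)
  dm <- phantom$grid_shape
  if (any(phantom$gd <= 0))
    stop("storage modulus must be positive everywhere in the domain")
  stopifnot(is_unit(polarization, 1e-6))
  h <- phantom$spacing * 1e-3                      # m
  w <- 2 * pi * frequency
  rho <- phantom$density

  face_names <- c("x-", "x+", "y-", "y+", "z-", "z+")
  dir_faces <- c(source_face, names(extra_dirichlet))
  if (!all(dir_faces %in% face_names))
    stop("unknown face name among: ", paste(dir_faces, collapse = ", "))

  gstar <- phantom$gd + 1i * phantom$gl
  ## absorbing ramp: quadratic growth of added loss towards every
  ## non-prescribed face (skipped entirely under Neumann side conditions)
  absorb <- array(0, dm)
  if (side_bc == "absorbing") {
    for (ax in 1:3) {
      n <- dm[ax]
      d_lo <- array(rep(pmax(absorbing_width + 1 - seq_len(n), 0),
                        each = prod(dm[seq_len(ax - 1)])), dm)
      d_hi <- array(rep(pmax(seq_len(n) - (n - absorbing_width), 0),
                        each = prod(dm[seq_len(ax - 1)])), dm)
      lo_name <- paste0(c("x", "y", "z")[ax], "-")
      hi_name <- paste0(c("x", "y", "z")[ax], "+")
      if (lo_name %in% dir_faces) d_lo[] <- 0
      if (hi_name %in% dir_faces) d_hi[] <- 0
      absorb <- pmax(absorb, pmax(d_lo, d_hi) / absorbing_width)
    }
  }
  gsolve <- gstar + 1i * absorbing_strength * phantom$gd * absorb^2

  n <- prod(dm)
  idx <- array(seq_len(n), dm)
  face_voxels <- function(face) {
    v <- switch(face,
                "x-" = idx[1, , ], "x+" = idx[dm[1], , ],
                "y-" = idx[, 1, ], "y+" = idx[, dm[2], ],
                "z-" = idx[, , 1], "z+" = idx[, , dm[3]])
    as.vector(v)
  }
  face_values <- function(face, val) {
    sel <- face_voxels(face)
    v <- if (length(val) == 1) rep(val + 0i, length(sel)) else as.vector(val) + 0i
    if (length(v) != length(sel))
      stop("prescribed values do not match face ", face)
    list(sel = sel, val = v)
  }
  pres <- list(face_values(source_face, source_amplitude))
  for (f in names(extra_dirichlet))
    pres <- c(pres, list(face_values(f, extra_dirichlet[[f]])))
  src_sel <- unlist(lapply(pres, `[[`, "sel"))
  u_src <- unlist(lapply(pres, `[[`, "val"))
  dup <- duplicated(src_sel)        # face edges shared between two faces
  src_sel <- src_sel[!dup]
  u_src <- u_src[!dup]

  unknown <- setdiff(seq_len(n), src_sel)
  m <- length(unknown)
  arr_ind_all <- arrayInd(seq_len(n), dm)
  ## slice-fastest ordering (z, then x, then y) keeps the matrix bandwidth
  ## at nz * nx, where a direct banded factorization is cheap
  band_key <- (arr_ind_all[, 3] - 1) + dm[3] * (arr_ind_all[, 1] - 1) +
    dm[3] * dm[1] * (arr_ind_all[, 2] - 1)
  ord <- order(band_key[unknown])
  unknown <- unknown[ord]
  map <- integer(n)
  map[unknown] <- seq_len(m)

  arr_ind <- arr_ind_all[unknown, , drop = FALSE]
  gs_u <- gsolve[unknown]
  diag_v <- rep(rho * w^2 + 0i, m)
  rhs <- complex(m)
  nb_rows <- vector("list", 6)
  nb_cols <- vector("list", 6)
  nb_vals <- vector("list", 6)
  is_src <- logical(n); is_src[src_sel] <- TRUE
  t <- 0
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      t <- t + 1
      nb_ind <- arr_ind
      nb_ind[, ax] <- nb_ind[, ax] + sgn
      inside <- nb_ind[, ax] >= 1 & nb_ind[, ax] <= dm[ax]
      nb_lin <- rep(NA_integer_, m)
      nb_lin[inside] <- idx[nb_ind[inside, , drop = FALSE]]
      gface <- complex(m)
      gface[inside] <- (gs_u[inside] + gsolve[nb_lin[inside]]) / 2
      ## outside the grid: zero-Dirichlet ghost under absorbing sides (use
      ## the voxel's own modulus), mirror ghost (no flux) under Neumann
      gface[!inside] <- if (side_bc == "absorbing") gs_u[!inside] else 0
      coef <- gface / h[ax]^2
      diag_v <- diag_v - coef
      nb_src <- inside & is_src[ifelse(is.na(nb_lin), 1L, nb_lin)]
      sel <- which(inside & !nb_src)
      nb_rows[[t]] <- sel
      nb_cols[[t]] <- map[nb_lin[sel]]
      nb_vals[[t]] <- coef[sel]
      sel2 <- which(nb_src)
      if (length(sel2))
        rhs[sel2] <- rhs[sel2] -
          coef[sel2] * u_src[match(nb_lin[sel2], src_sel)]
    }
  }
  ti <- c(unlist(nb_rows), seq_len(m))
  tj <- c(unlist(nb_cols), seq_len(m))
  tv <- c(unlist(nb_vals, use.names = FALSE), diag_v)
  kl <- max(abs(ti - tj))
  ku <- kl
  ab <- matrix(0i, 2 * kl + ku + 1, m)
  ab[cbind(kl + ku + 1 + ti - tj, tj)] <- tv
  ures <- .zgbsv_solve(ab, kl, ku, rhs)

  ## residual of the assembled system, checked by re-applying the operator
  ax_apply <- complex(m)
  for (t in seq_len(6)) ax_apply[nb_rows[[t]]] <- ax_apply[nb_rows[[t]]] +
    nb_vals[[t]] * ures[nb_cols[[t]]]
  ax_apply <- ax_apply + diag_v * ures
  resid <- sqrt(sum(Mod(ax_apply - rhs)^2)) /
    max(sqrt(sum(Mod(rhs)^2)), 1e-300)
  if (resid > 1e-8)
    stop("discrete Helmholtz residual too large (", fmt_num(resid),
         "); system ill-conditioned")

  ufull <- complex(n)
  ufull[unknown] <- ures
  ufull[src_sel] <- u_src
  u <- array(0i, c(dm, 3))
  for (c3 in 1:3) if (polarization[c3] != 0)
    u[, , , c3] <- array(polarization[c3] * ufull, dm)
  structure(list(u = u, frequency = frequency, spacing = phantom$spacing,
                 density = rho, absorbing = absorb > 0, residual = resid),
            class = "wave_field")
}

#' Add a curl-free compressional contamination to a wave field
#'
#' Adds `U_c = A * (-i m) exp(-i k_c (r . m))`, the gradient of a
#' long-wavelength scalar potential (so exactly curl-free in the
#' continuum), emulating the compressional wave component that the curl
#' operator in the reconstruction must annihilate.
#'
#' @param field a `wave_field`.
#' @param amplitude peak displacement of the added component, meters.
#' @param wavelength_mm compressional wavelength, much longer than the
#'   shear wavelength (default 50 mm).
#' @param direction unit propagation direction of the compressional wave.
#' @return the contaminated `wave_field`.
#' @export
add_compressional_component <- function(field, amplitude,
                                        wavelength_mm = 50,
                                        direction = c(1, 0, 0)) {
  if (amplitude == 0) return(field)
  stopifnot(is_unit(direction, 1e-6))
  dm <- dim(field$u)[1:3]
  kc <- 2 * pi / (wavelength_mm * 1e-3)        # rad/m
  proj_m <- projection_array(dm, field$spacing, direction) * 1e-3
  pot <- exp(-1i * kc * proj_m)
  for (c3 in 1:3) if (direction[c3] != 0)
    field$u[, , , c3] <- field$u[, , , c3] +
      amplitude * (-1i) * direction[c3] * pot
  field
}

#' Encode a wave field as a wrapped multi-phase acquisition
#'
#' For each encoding direction `d` and wave phase `theta_n = 2 pi n / 4`
#' (n = 0..3), the MR phase image is
#' `phi = scale * Re{U_d exp(i theta_n)} + noise`, optionally wrapped to
#' `(-pi, pi]`. On noiseless, unwrapped output,
#' [extract_first_harmonic()] recovers `scale * U_d` exactly.
#'
#' @param field a `wave_field`.
#' @param scale radians of MR phase per meter of displacement; `NULL`
#'   picks the scale giving a maximum phase amplitude of 2.5 rad (so
#'   wrapping occurs and the unwrapper is exercised).
#' @param noise_sd_rad Gaussian phase noise SD, radians.
#' @param wrap logical, wrap phases to `(-pi, pi]`.
#' @param seed integer seed for the noise.
#' @return class `wave_acquisition`: `phase_images` with dimensions
#'   `c(grid, 3 directions, 4 wave phases)`, `phase_offsets`, `scale`,
#'   `frequency`, `spacing`, `wrap_applied`.
#' @export
encode_wave_phases <- function(field, scale = NULL, noise_sd_rad = 0,
                               wrap = TRUE, seed = 1) {
  offs <- 2 * pi * (0:3) / 4
  umax <- max(Mod(field$u))
  if (is.null(scale)) scale <- 2.5 / umax
  if (scale <= 0) stop("scale must be positive")
  dm <- dim(field$u)[1:3]
  ph <- array(0, c(dm, 3, 4))
  for (d in 1:3) for (nn in 1:4)
    ph[, , , d, nn] <- scale * Re(field$u[, , , d] * exp(1i * offs[nn]))
  if (noise_sd_rad > 0) {
    ph <- with_seed(seed, ph + rnorm(length(ph), sd = noise_sd_rad))
    dim(ph) <- c(dm, 3, 4)
  }
  if (wrap) ph <- wrap_phase(ph)
  structure(list(phase_images = ph, phase_offsets = offs, scale = scale,
                 frequency = field$frequency, spacing = field$spacing,
                 wrap_applied = wrap),
            class = "wave_acquisition")
}
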