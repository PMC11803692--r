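## ---------------------------------------------------------------------------
## Elastogram reconstruction: unwrap -> align slices -> temporal first
## harmonic -> curl -> local Helmholtz inversion -> |G*| and Y
## ---------------------------------------------------------------------------

#' Unwrap a stack of wrapped phase images slice by slice
#'
#' Each 2-D slice of each encoding direction / wave phase image is
#' unwrapped independently with a quality-guided region-growing algorithm
#' (compiled): growth starts at the most reliable pixel (smallest local
#' wrapped-gradient energy) and each pixel is unwrapped relative to an
#' already-unwrapped neighbour. Output minus input is an integer multiple
#' of 2 pi per voxel; smooth fields are restored up to one global 2 pi
#' constant per slice. Through-slice consistency is restored afterwards by
#' [align_slice_offsets()].
#'
#' @param acq a `wave_acquisition`, or a plain 3-D phase array.
#' @return object of the same kind with unwrapped phases.
#' @export
unwrap_phase_stack <- function(acq) {
  unwrap3d <- function(vol) {
    for (z in seq_len(dim(vol)[3]))
      vol[, , z] <- .cpp_unwrap2d(vol[, , z])
    vol
  }
  if (is.array(acq) && length(dim(acq)) == 3) return(unwrap3d(acq))
  stopifnot(inherits(acq, "wave_acquisition"))
  ph <- acq$phase_images
  for (d in seq_len(dim(ph)[4])) for (nn in seq_len(dim(ph)[5]))
    ph[, , , d, nn] <- unwrap3d(ph[, , , d, nn])
  acq$phase_images <- ph
  acq$wrap_applied <- FALSE
  acq
}

#' Align per-slice 2 pi offsets of an unwrapped stack
#'
#' Per-slice unwrapping leaves each slice with an arbitrary integer
#' multiple of 2 pi. Taking slice 1 as reference, an offset `k * 2 pi` is
#' added to each subsequent slice so that the median phase difference to
#' the previous slice falls in `(-pi, pi]`. A median jump of exactly pi is
#' ambiguous; the smaller offset is chosen and a warning logged.
#'
#' @param stack 3-D unwrapped phase array, or a `wave_acquisition` (each
#'   direction / wave phase volume aligned independently).
#' @return the offset-consistent object.
#' @export
align_slice_offsets <- function(stack) {
  align3d <- function(vol) {
    nz <- dim(vol)[3]
    for (z in seq(2, length.out = nz - 1)) {
      d <- median(vol[, , z] - vol[, , z - 1])
      k <- floor(d / (2 * pi) + 0.5)      # ties at +pi resolve downward
      if (abs(abs(d - k * 2 * pi) - pi) < 1e-12)
        warning("inter-slice phase jump of exactly pi at slice ", z,
                "; choosing smaller offset")
      if (k != 0) vol[, , z:nz] <- vol[, , z:nz, drop = FALSE] - k * 2 * pi
    }
    vol
  }
  if (is.array(stack) && length(dim(stack)) == 3) return(align3d(stack))
  stopifnot(inherits(stack, "wave_acquisition"))
  ph <- stack$phase_images
  for (d in seq_len(dim(ph)[4])) for (nn in seq_len(dim(ph)[5]))
    ph[, , , d, nn] <- align3d(ph[, , , d, nn])
  stack$phase_images <- ph
  stack
}

#' Extract the temporal first harmonic from 4 wave phases
#'
#' Discrete Fourier transform over the four sampled wave phases
#' `theta_n = 2 pi n / 4`: `H = (2/4) sum_n s_n exp(-i theta_n)`. For
#' samples `s_n = A cos(theta_n + phi)` this returns `A exp(i phi)`
#' exactly (and rejects any DC component), so on a noiseless unwrapped
#' acquisition it inverts [encode_wave_phases()] to `scale * U_d`.
#'
#' @param acq an unwrapped, aligned `wave_acquisition`; or a numeric array
#'   whose last axis holds exactly 4 wave-phase samples.
#' @return a `wave_field` with complex displacement-scaled phases (units
#'   rad; divide by `scale` for meters), or the complex array for array
#'   input.
#' @export
extract_first_harmonic <- function(acq) {
  harm <- function(a) {
    d <- dim(a)
    if (d[length(d)] != 4) stop("exactly 4 wave-phase samples are required")
    w <- exp(-1i * 2 * pi * (0:3) / 4)
    out <- matrix(a, ncol = 4) %*% w * (2 / 4)
    array(out, d[-length(d)])
  }
  if (!inherits(acq, "wave_acquisition")) {
    if (is.vector(acq)) {
      if (length(acq) != 4) stop("exactly 4 wave-phase samples are required")
      return(sum(acq * exp(-1i * 2 * pi * (0:3) / 4)) / 2)
    }
    return(harm(acq))
  }
  ph <- acq$phase_images
  dm <- dim(ph)[1:3]
  u <- array(0i, c(dm, 3))
  for (d in 1:3) u[, , , d] <- harm(ph[, , , d, ])
  structure(list(u = u, frequency = acq$frequency, spacing = acq$spacing,
                 density = NULL, scale = acq$scale),
            class = "wave_field")
}

#' Curl of a displacement field by central differences
#'
#' Applies the curl operator to the (complex) displacement field with the
#' physical voxel spacing, annihilating any curl-free (compressional)
#' component up to discretization error. The validity mask excludes the
#' one-voxel rim where the central stencil is incomplete.
#'
#' @param field a `wave_field` (requires at least 3 slices).
#' @return class `curl_field`: complex array `q` of dimensions
#'   `c(grid, 3)` (units of U per meter), `validity` mask, `frequency`,
#'   `spacing`.
#' @export
compute_curl <- function(field) {
  u <- field$u
  dm <- dim(u)[1:3]
  if (dm[3] < 3) stop("at least 3 slices are needed for z-derivatives")
  h <- field$spacing * 1e-3                      # m
  dcomp <- function(cidx, ax) central_diff(u[, , , cidx], ax, h[ax])
  q <- array(0i, c(dm, 3))
  q[, , , 1] <- dcomp(3, 2) - dcomp(2, 3)
  q[, , , 2] <- dcomp(1, 3) - dcomp(3, 1)
  q[, , , 3] <- dcomp(2, 1) - dcomp(1, 2)
  structure(list(q = q, validity = interior_mask(dm, 1),
                 frequency = field$frequency, spacing = field$spacing),
            class = "curl_field")
}

## small separable 3-D Gaussian smoother (sigma in voxels), for optional
## pre-differentiation smoothing of the curl components
gauss_smooth3d <- function(a, sigma) {
  if (is.null(sigma) || sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(x, ax) {
    out <- array(0, dim(x)) * x[1]               # keep complex type
    for (j in seq_along(k)) {
      sh <- shift_axis(x, ax, j - r - 1L)
      out <- out + k[j] * sh
    }
    out
  }
  for (ax in 1:3) a <- sm1(a, ax)
  a
}

#' Local Helmholtz inversion of a curl field
#'
#' Under local homogeneity every curl component obeys
#' `G* lap(q_c) = -rho w^2 q_c`. The complex modulus is estimated per
#' voxel by least squares over the three components:
#' `G* = -rho w^2 * sum_c q_c conj(lap q_c) / sum_c |lap q_c|^2`
#' (equal weights; per-component median available via
#' `combine = "median"`). The storage and loss moduli are the real and
#' imaginary parts, clipped at zero for map reporting with the unclipped
#' estimates kept in `gd_raw` / `gl_raw`. Validity excludes two voxels of
#' rim (curl + Laplacian stencils) and voxels whose summed Laplacian
#' magnitude falls below `min_lap_frac` times the median (no wave
#' curvature to invert).
#'
#' @param curl a `curl_field`.
#' @param frequency vibration frequency, Hz.
#' @param density tissue density, kg/m^3.
#' @param smooth_sigma optional Gaussian sigma (voxels) applied to the
#'   curl components before differentiation; `NULL` (default) disables.
#' @param combine `"lsq"` (default) or `"median"` per-component
#'   combination.
#' @param min_lap_frac exclusion threshold as a fraction of the median
#'   Laplacian magnitude.
#' @return an `elastogram` (see [compose_elastogram()]): arrays `gd`,
#'   `gl`, `gstar`, `y`, `gd_raw`, `gl_raw`, `validity`, `clipped`.
#' @export
invert_helmholtz <- function(curl, frequency = curl$frequency,
                             density = 1000, smooth_sigma = NULL,
                             combine = c("lsq", "median"),
                             min_lap_frac = 0.05) {
  combine <- match.arg(combine)
  dm <- dim(curl$q)[1:3]
  h <- curl$spacing * 1e-3
  w <- 2 * pi * frequency
  num <- array(0i, dm); den <- array(0, dm); lap_mag <- array(0, dm)
  gper <- vector("list", 3)
  for (cc in 1:3) {
    qc <- gauss_smooth3d(curl$q[, , , cc], smooth_sigma)
    lap <- second_diff(qc, 1, h[1]) + second_diff(qc, 2, h[2]) +
      second_diff(qc, 3, h[3])
    num <- num + qc * Conj(lap)
    den <- den + Mod(lap)^2
    lap_mag <- lap_mag + Mod(lap)
    if (combine == "median")
      gper[[cc]] <- -density * w^2 * qc * Conj(lap) / (Mod(lap)^2)
  }
  validity <- curl$validity & interior_mask(dm, 2)
  if (!any(validity)) stop("no valid voxels after stencil erosion; ",
                           "wavelength likely under-resolved")
  med <- median(lap_mag[validity])
  validity <- validity & lap_mag > min_lap_frac * med & den > 0
  if (!any(validity)) stop("all voxels excluded by the Laplacian magnitude ",
                           "filter; wavelength likely under-resolved")
  g <- if (combine == "lsq") {
    -density * w^2 * num / pmax(den, 1e-300)
  } else {
    gr <- array(apply(vapply(gper, Re, array(0, dm)), 1:3, median), dm)
    gi <- array(apply(vapply(gper, Im, array(0, dm)), 1:3, median), dm)
    gr + 1i * gi
  }
  gd_raw <- Re(g); gl_raw <- Im(g)
  gd <- pmax(gd_raw, 0); gl <- pmax(gl_raw, 0)
  clipped <- (gd_raw < 0 | gl_raw < 0) & validity
  comp <- compose_elastogram(gd, gl)
  structure(list(gd = gd, gl = gl, gstar = comp$g_magnitude, y = comp$y,
                 gd_raw = gd_raw, gl_raw = gl_raw, validity = validity,
                 clipped = clipped, frequency = frequency,
                 density = density, spacing = curl$spacing),
            class = "elastogram")
}

#' Compose |G*| and the phase angle Y from the moduli
#'
#' `|G*| = sqrt(gd^2 + gl^2)` and `Y = (2/pi) atan2(gl, gd)`: a purely
#' elastic material has Y = 0, a purely viscous one Y = 1. atan2 makes the
#' `gd = 0` limit exact; `gd = gl = 0` leaves Y undefined (NA).
#'
#' @param gd storage modulus, Pa (scalar or array).
#' @param gl loss modulus, Pa.
#' @return list with `g_magnitude` (Pa) and `y` (dimensionless).
#' @export
compose_elastogram <- function(gd, gl) {
  stopifnot(all(is.finite(gd)), all(is.finite(gl)))
  gm <- sqrt(gd^2 + gl^2)
  y <- (2 / pi) * atan2(gl, gd)
  y[gd == 0 & gl == 0] <- NA_real_
  list(g_magnitude = gm, y = y)
}

#' Reconstruct an elastogram from a wrapped multi-phase acquisition
#'
#' Runs the full reconstruction chain: per-slice phase unwrapping,
#' inter-slice 2 pi alignment, temporal first-harmonic extraction per
#' encoding direction, curl decomposition and local Helmholtz inversion.
#' The chain is invariant to the phase-to-displacement scale (the
#' inversion is a ratio of derivatives), so the elastogram is in absolute
#' Pa given frequency and density.
#'
#' @param acq a `wave_acquisition`.
#' @param density tissue density, kg/m^3.
#' @param smooth_sigma,combine,min_lap_frac passed to
#'   [invert_helmholtz()].
#' @return an `elastogram`.
#' @export
reconstruct_elastogram <- function(acq, density = 1000, smooth_sigma = NULL,
                                   combine = "lsq", min_lap_frac = 0.05) {
  stopifnot(inherits(acq, "wave_acquisition"))
  a <- if (isTRUE(acq$wrap_applied)) unwrap_phase_stack(acq) else acq
  a <- align_slice_offsets(a)
  field <- extract_first_harmonic(a)
  field$u <- field$u / acq$scale       # rad -> meters (scale cancels anyway)
  curl <- compute_curl(field)
  invert_helmholtz(curl, frequency = acq$frequency, density = density,
                   smooth_sigma = smooth_sigma, combine = combine,
                   min_lap_frac = min_lap_frac)
}

#' @export
print.elastogram <- function(x, ...) {
  v <- x$validity
  cat("Elastogram:", paste(dim(x$gd), collapse = " x "), "voxels;",
      sum(v), "valid\n")
  if (any(v)) {
    cat(sprintf("  median |G*| %.0f Pa, median Y %.3f; %d voxels clipped\n",
                median(x$gstar[v]), median(x$y[v]), sum(x$clipped)))
  }
  invisible(x)
}

#' @export
summary.elastogram <- function(object, ...) {
  v <- object$validity
  out <- list(
    n_valid = sum(v), n_clipped = sum(object$clipped),
    gstar = stats::quantile(object$gstar[v], c(0.25, 0.5, 0.75)),
    y = stats::quantile(object$y[v], c(0.25, 0.5, 0.75)))
  class(out) <- "summary.elastogram"
  out
}

#' @export
print.summary.elastogram <- function(x, ...) {
  cat("Valid voxels:", x$n_valid, " clipped:", x$n_clipped, "\n")
  cat("|G*| quartiles (Pa):", paste(fmt_num(x$gstar), collapse = " / "), "\n")
  cat("Y    quartiles:     ", paste(fmt_num(x$y), collapse = " / "), "\n")
  invisible(x)
}
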