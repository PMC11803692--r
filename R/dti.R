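## ---------------------------------------------------------------------------
## Diffusion tensor fitting and scalar maps (ADC as mean diffusivity, FA)
## ---------------------------------------------------------------------------

## closed-form eigenvalues of symmetric 3x3 tensors given as an n x 6
## matrix (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz); trigonometric method, vectorized
symtensor_eigenvalues <- function(m6) {
  dxx <- m6[, 1]; dyy <- m6[, 2]; dzz <- m6[, 3]
  dxy <- m6[, 4]; dxz <- m6[, 5]; dyz <- m6[, 6]
  q <- (dxx + dyy + dzz) / 3
  p1 <- dxy^2 + dxz^2 + dyz^2
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > 0
  if (any(nz)) {
    bxx <- (dxx - q) / p; byy <- (dyy - q) / p; bzz <- (dzz - q) / p
    bxy <- dxy / p; bxz <- dxz / p; byz <- dyz / p
    detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q + 2 * p * cos(phi)
    e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
    e2 <- 3 * q - e1 - e3
    l1[nz] <- e1[nz]; l2[nz] <- e2[nz]; l3[nz] <- e3[nz]
  }
  cbind(l1, l2, l3)
}

#' Scalar invariants of a diffusion tensor: ADC and FA
#'
#' ADC is defined as the mean diffusivity `(Dxx + Dyy + Dzz) / 3`
#' (trace/3), the standard tensor reduction. FA is
#' `sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`
#' from the eigenvalues; negative eigenvalues are clamped to zero for the
#' FA computation and flagged. An all-zero tensor leaves FA undefined.
#'
#' @param tensor numeric vector of 6 unique components (Dxx, Dyy, Dzz,
#'   Dxy, Dxz, Dyz), or an n x 6 matrix.
#' @return for one tensor a list `(adc, fa, clipped)`; for a matrix a
#'   data.frame with those columns.
#' @export
tensor_scalars <- function(tensor) {
  m6 <- if (is.matrix(tensor)) tensor else matrix(tensor, nrow = 1)
  stopifnot(ncol(m6) == 6)
  adc <- unname((m6[, 1] + m6[, 2] + m6[, 3]) / 3)
  ev <- unname(symtensor_eigenvalues(m6))
  clipped <- rowSums(ev < 0) > 0
  ev <- pmax(ev, 0)
  mn <- rowMeans(ev)
  num <- (ev[, 1] - mn)^2 + (ev[, 2] - mn)^2 + (ev[, 3] - mn)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- ifelse(den > 0, sqrt(3 / 2) * sqrt(num / den), NA_real_)
  fa <- unname(pmin(fa, 1))
  if (!is.matrix(tensor)) list(adc = adc[1], fa = fa[1], clipped = clipped[1])
  else data.frame(adc = adc, fa = fa, clipped = clipped)
}

#' Fit the diffusion tensor from a DWI set
#'
#' Per voxel, solves `ln(S_g / S_0) = -b g' D g` for the six unique
#' tensor components by unweighted linear least squares over all
#' diffusion-weighted volumes, then derives ADC (mean diffusivity) and FA.
#' Requires at least 6 non-collinear directions plus one b = 0 reference;
#' voxels with non-positive signals are invalidated.
#'
#' @param dwi a `dwi_set` (see [synthesize_dwi()]).
#' @return class `tensor_map`: `tensor` (4-D array, 6 components), `adc`,
#'   `fa`, `validity`, `clipped` and the design `condition_number`.
#' @export
fit_diffusion_tensor <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_set"))
  b <- dwi$bvalues
  g <- dwi$directions
  wi <- which(b > 0)
  if (length(wi) < 6) stop("at least 6 diffusion-weighted volumes required")
  if (sum(b == 0) != 1) stop("exactly one b = 0 reference volume required")
  i0 <- which(b == 0)
  X <- cbind(g[wi, 1]^2, g[wi, 2]^2, g[wi, 3]^2,
             2 * g[wi, 1] * g[wi, 2], 2 * g[wi, 1] * g[wi, 3],
             2 * g[wi, 2] * g[wi, 3]) * b[wi]
  if (qr(X)$rank < 6) stop("rank-deficient direction set")
  cn <- kappa(X, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8) stop("rank-deficient direction set")
  pinv <- solve(crossprod(X), t(X))
  dm <- dim(dwi$signal)[1:3]
  nv <- prod(dm)
  s <- matrix(dwi$signal, nrow = nv)
  s0 <- s[, i0]
  sw <- s[, wi, drop = FALSE]
  validity <- s0 > 0 & rowSums(sw <= 0) == 0
  ratio <- ifelse(validity, 1, NA) * sw / s0
  yy <- -log(ratio)
  yy[!validity, ] <- 0
  tens <- yy %*% t(pinv)
  sc <- tensor_scalars(tens)
  ## an all-zero tensor leaves FA undefined: masked out of validity
  validity <- validity & !is.na(sc$fa)
  tens[!validity, ] <- NA
  adc <- ifelse(validity, sc$adc, NA)
  fa <- ifelse(validity, sc$fa, NA)
  structure(list(tensor = array(tens, c(dm, 6)), adc = array(adc, dm),
                 fa = array(fa, dm), validity = array(validity, dm),
                 clipped = array(sc$clipped & validity, dm),
                 condition_number = cn, bvalue = max(b)),
            class = "tensor_map")
}

#' @export
print.tensor_map <- function(x, ...) {
  v <- x$validity
  cat("Tensor map:", paste(dim(x$adc), collapse = " x "), "voxels;",
      sum(v), "valid; design condition number", fmt_num(x$condition_number),
      "\n")
  if (any(v))
    cat(sprintf("  median ADC %.1f x 1e-6 mm^2/s, median FA %.3f\n",
                median(x$adc[v]) * 1e6, median(x$fa[v])))
  invisible(x)
}
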