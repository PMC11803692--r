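#' @useDynLib elastoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm rpois runif sd setNames t.test var
#' @importFrom utils read.csv write.csv
NULL

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global random-number state so that seeded
#' generators do not perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific sub-seed from a root seed
#'
#' All pipeline randomness flows from one root seed via named substreams so
#' that a stage is reproducible even when other stages change.
#'
#' @param seed root integer seed.
#' @param stream character stream name.
#' @return an integer below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1013904223
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483629)
}

## circular shift of a 3-D (or higher) array along one axis, edge padded by wrap;
## used only through diff helpers below which mask the wrapped rim.
shift_axis <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  n <- d[axis]
  idx[[axis]] <- ((seq_len(n) - 1 - by) %% n) + 1
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

## central first difference along an axis, physical spacing h; rim voxels invalid
central_diff <- function(a, axis, h) {
  (shift_axis(a, axis, -1) - shift_axis(a, axis, 1)) / (2 * h)
}

## second central difference along an axis
second_diff <- function(a, axis, h) {
  (shift_axis(a, axis, -1) - 2 * a + shift_axis(a, axis, 1)) / (h * h)
}

## logical mask of voxels with all neighbours within `k` voxels inside the grid
interior_mask <- function(dm, k) {
  m <- array(TRUE, dm)
  for (ax in 1:3) {
    n <- dm[ax]
    if (n <= 2 * k) stop("grid too small for interior erosion of ", k)
    idx <- c(seq_len(k), n - seq_len(k) + 1)
    if (ax == 1) m[idx, , ] <- FALSE
    if (ax == 2) m[, idx, ] <- FALSE
    if (ax == 3) m[, , idx] <- FALSE
  }
  m
}

## wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  w <- -((-x + pi) %% (2 * pi) - pi)
  w
}

## voxel centre coordinates (mm) along each axis, first voxel centred at 0
grid_coords <- function(grid_shape, spacing) {
  lapply(1:3, function(ax) (seq_len(grid_shape[ax]) - 1) * spacing[ax])
}

## outer-sum of per-axis coordinate projections: returns array of n . r
projection_array <- function(grid_shape, spacing, direction) {
  co <- grid_coords(grid_shape, spacing)
  px <- co[[1]] * direction[1]
  py <- co[[2]] * direction[2]
  pz <- co[[3]] * direction[3]
  outer(outer(px, py, `+`), pz, `+`)
}

is_unit <- function(v, tol = 1e-9) abs(sqrt(sum(v^2)) - 1) <= tol

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
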