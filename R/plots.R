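#' Display an elastogram slice as a colour-coded parametric map
#'
#' @param x an `elastogram`.
#' @param what map to show: `"gstar"`, `"gd"`, `"gl"` or `"y"`.
#' @param slice slice index (default: central slice).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.elastogram <- function(x, what = c("gstar", "gd", "gl", "y"),
                            slice = NULL, ...) {
  what <- match.arg(what)
  dm <- dim(x$gd)
  if (is.null(slice)) slice <- ceiling(dm[3] / 2)
  m <- x[[what]][, , slice]
  m[!x$validity[, , slice]] <- NA
  graphics::image(seq_len(dm[1]) * x$spacing[1],
                  seq_len(dm[2]) * x$spacing[2], m,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("%s, slice %d", what, slice),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Display a synthetic histology image
#'
#' @param x a `histo_image`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.histo_image <- function(x, ...) {
  px <- x$pixels / 255
  graphics::plot.new()
  graphics::plot.window(c(0, ncol(px)), c(0, nrow(px)), asp = 1)
  graphics::rasterImage(px, 0, 0, ncol(px), nrow(px))
  graphics::title(sprintf("%.2f%% stained, %d nuclei",
                          100 * x$truth_stained_fraction,
                          x$truth_cell_count))
  invisible(x)
}
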