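## ---------------------------------------------------------------------------
## Synthetic histology images and their quantification: sample-guided RGB
## thresholding (stained-area fraction) and nucleus density per 100 um^2
## ---------------------------------------------------------------------------

#' Default staining palettes
#'
#' The stained palette emulates an Alcian-blue-like hue; the background a
#' pale eosin-like tissue tone. Channel SDs are small relative to the mean
#' separation so that the classes are separable by per-channel
#' thresholding.
#'
#' @return list with `stained` and `background`, each `mean` and `sd`
#'   (8-bit intensity units per RGB channel).
#' @export
default_histo_palettes <- function() {
  list(stained = list(mean = c(70, 130, 185), sd = c(6, 6, 6)),
       background = list(mean = c(235, 220, 228), sd = c(5, 5, 5)))
}

#' Synthesize an RGB histology image with known truth
#'
#' Pixels are drawn from a background palette, a `stained_fraction` of
#' them (chosen uniformly at random) from the stained palette. Per-pixel
#' colour variation is dominated by a shared stain-concentration factor
#' across the three channels (plus a small independent channel
#' component); the shared factor is a truncated Gaussian (standardized,
#' support 1.91 SD), reflecting that a stain class is a bounded colour
#' cluster — dye concentration cannot be negative or unbounded — which is
#' what makes a mean +/- 2 SD in-range rule a reliable detector of the
#' class. Nuclei are placed as
#' disjoint dark disks with Poisson-distributed count at the requested
#' density; placement is rejected if the disks cannot fit. The realized
#' stained mask and nucleus centres are recorded as ground truth.
#'
#' @param width,height image size, pixels.
#' @param pixel_size_um physical pixel size, micrometers.
#' @param stained_fraction target fraction of stained pixels in [0, 1].
#' @param cell_density_per_100um2 nucleus density, count per 100 um^2
#'   (0 disables nuclei).
#' @param palettes as [default_histo_palettes()]; the stained and
#'   background means must be separated by more than 6 channel SDs.
#' @param nucleus_radius_um nucleus disk radius.
#' @param min_gap_um minimum gap between nucleus rims (keeps connected
#'   components disjoint).
#' @param shared_variance fraction of palette variance carried by the
#'   shared intensity factor.
#' @param seed integer seed.
#' @return class `histo_image`: `pixels` (height x width x 3, 0-255),
#'   `pixel_size_um`, `truth_stained_mask`, `truth_stained_fraction`,
#'   `truth_cell_centers`, `truth_cell_count`, `truth_cell_density`.
#' @export
synthesize_histology <- function(width = 400, height = 400,
                                 pixel_size_um = 0.1,
                                 stained_fraction = 0.1,
                                 cell_density_per_100um2 = 0,
                                 palettes = default_histo_palettes(),
                                 nucleus_radius_um = 0.3,
                                 min_gap_um = 0.2,
                                 shared_variance = 1,
                                 seed = 1) {
  stopifnot(stained_fraction >= 0, stained_fraction <= 1,
            cell_density_per_100um2 >= 0, shared_variance >= 0,
            shared_variance <= 1)
  sep <- abs(palettes$stained$mean - palettes$background$mean) /
    pmax(palettes$stained$sd, palettes$background$sd)
  if (max(sep) <= 6)
    stop("palettes not separable: need mean difference > 6 SD in a channel")
  npix <- width * height
  with_seed(seed, {
    stained <- rep(FALSE, npix)
    n_st <- round(stained_fraction * npix)
    if (n_st > 0) stained[sample.int(npix, n_st)] <- TRUE
    ## truncated standard Gaussian (unit variance, bounded support): both
    ## the shared concentration factor and the small per-channel residual
    ## are bounded, so a stain class is a compact colour cluster
    rtruncnorm1 <- function(n, a = 1.2) {
      tsd <- sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
      stats::qnorm(runif(n, stats::pnorm(-a), stats::pnorm(a))) / tsd
    }
    draw <- function(pal, n) {
      t_shared <- rtruncnorm1(n)
      sapply(1:3, function(cc) {
        e <- sqrt(shared_variance) * t_shared +
          sqrt(1 - shared_variance) * rtruncnorm1(n)
        pal$mean[cc] + pal$sd[cc] * e
      })
    }
    px <- draw(palettes$background, npix)
    if (n_st > 0) px[stained, ] <- draw(palettes$stained, n_st)

    ## nucleus placement: Poisson count, random sequential adsorption of
    ## disjoint disks with a minimum rim gap
    area_um2 <- npix * pixel_size_um^2
    centers <- NULL
    if (cell_density_per_100um2 > 0) {
      lambda <- cell_density_per_100um2 * area_um2 / 100
      n_cells <- rpois(1, lambda)
      r_px <- nucleus_radius_um / pixel_size_um
      excl_px <- (2 * nucleus_radius_um + min_gap_um) / pixel_size_um
      pack <- n_cells * pi * (excl_px / 2)^2 / npix
      if (pack > 0.45)
        stop("infeasible nucleus density: disjoint disks cannot fit ",
             "(packing fraction ", fmt_num(pack), ")")
      centers <- matrix(NA_real_, n_cells, 2)
      ## bucket grid for neighbour queries
      cell <- excl_px
      nbx <- max(1L, ceiling(width / cell))
      nby <- max(1L, ceiling(height / cell))
      buckets <- vector("list", nbx * nby)
      placed <- 0
      attempts <- 0
      max_attempts <- max(20000, n_cells * 200)
      while (placed < n_cells && attempts < max_attempts) {
        attempts <- attempts + 1
        cx <- runif(1, r_px + 1, width - r_px)
        cy <- runif(1, r_px + 1, height - r_px)
        bx <- pmin(pmax(ceiling(cx / cell), 1L), nbx)
        by <- pmin(pmax(ceiling(cy / cell), 1L), nby)
        ok <- TRUE
        for (ix in max(1, bx - 1):min(nbx, bx + 1)) {
          for (iy in max(1, by - 1):min(nby, by + 1)) {
            for (p in buckets[[(iy - 1) * nbx + ix]]) {
              if ((cx - centers[p, 1])^2 + (cy - centers[p, 2])^2 < excl_px^2) {
                ok <- FALSE; break
              }
            }
            if (!ok) break
          }
          if (!ok) break
        }
        if (ok) {
          placed <- placed + 1
          centers[placed, ] <- c(cx, cy)
          bi <- (by - 1) * nbx + bx
          buckets[[bi]] <- c(buckets[[bi]], placed)
        }
      }
      if (placed < n_cells)
        stop("infeasible nucleus density: placement saturated at ",
             placed, " of ", n_cells, " nuclei")
      ## rasterize dark disks
      nucleus_col <- c(45, 35, 70)
      for (p in seq_len(n_cells)) {
        cx <- centers[p, 1]; cy <- centers[p, 2]
        x0 <- max(1, floor(cx - r_px)); x1 <- min(width, ceiling(cx + r_px))
        y0 <- max(1, floor(cy - r_px)); y1 <- min(height, ceiling(cy + r_px))
        gx <- x0:x1; gy <- y0:y1
        dd <- outer(gy - cy, gx - cx, function(a, b) a^2 + b^2) <= r_px^2
        lin <- as.vector(outer(gy, (gx - 1) * height, `+`))[as.vector(dd)]
        for (cc in 1:3)
          px[lin, cc] <- nucleus_col[cc] + rnorm(length(lin), sd = 2)
      }
    }
    px <- round(pmin(pmax(px, 0), 255))
    pixels <- array(0, c(height, width, 3))
    for (cc in 1:3) pixels[, , cc] <- matrix(px[, cc], height, width)
    st_mask <- matrix(stained, height, width)
    ## nucleus pixels overwrite the stain: drop them from the truth mask
    if (!is.null(centers) && nrow(centers) > 0) {
      dark <- (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3 < 100
      st_mask <- st_mask & !dark
    }
    n_cells_final <- if (is.null(centers)) 0L else nrow(centers)
    structure(list(
      pixels = pixels, pixel_size_um = pixel_size_um,
      truth_stained_mask = st_mask,
      truth_stained_fraction = mean(st_mask),
      truth_cell_centers = centers,
      truth_cell_count = n_cells_final,
      truth_cell_density = n_cells_final * 100 /
        (npix * pixel_size_um^2)),
      class = "histo_image")
  })
}

#' @export
print.histo_image <- function(x, ...) {
  cat(sprintf("Histology image %d x %d px (%.2f um/px): %.2f%% stained, %d nuclei (%.1f per 100 um^2)\n",
              dim(x$pixels)[2], dim(x$pixels)[1], x$pixel_size_um,
              100 * x$truth_stained_fraction, x$truth_cell_count,
              x$truth_cell_density))
  invisible(x)
}

#' Coordinates of stained sample pixels
#'
#' Picks `n` pixel locations from the recorded stained mask of a
#' synthetic image, emulating the manual sampling of stain-conforming
#' pixels that seeds the threshold derivation.
#'
#' @param image a `histo_image`.
#' @param n number of sample pixels (default 20).
#' @param seed integer seed.
#' @return n x 2 matrix of (row, col) coordinates.
#' @export
sample_stained_coords <- function(image, n = 20, seed = 1) {
  idx <- which(image$truth_stained_mask)
  if (length(idx) < n) stop("fewer than ", n, " stained pixels available")
  sel <- with_seed(seed, sample(idx, n))
  cbind(row = ((sel - 1) %% nrow(image$truth_stained_mask)) + 1,
        col = ((sel - 1) %/% nrow(image$truth_stained_mask)) + 1)
}

#' Derive a per-channel colour threshold from sampled pixels
#'
#' For each RGB channel the in-range interval is the sample mean plus or
#' minus two sample standard deviations (n - 1 denominator), clipped to
#' [0, 255] — the sample-guided rule used to isolate a stain hue.
#'
#' @param image a `histo_image` or a height x width x 3 array.
#' @param sample_coords n x 2 matrix of (row, col) pixel coordinates
#'   (default: 20 stained-mask samples for a `histo_image`).
#' @param n_sd half-width in SDs (default 2).
#' @return class `color_threshold`: 3 x 2 matrix (`low`, `high` per
#'   channel) with attribute `n_samples`.
#' @export
derive_color_threshold <- function(image, sample_coords = NULL, n_sd = 2) {
  px <- if (inherits(image, "histo_image")) image$pixels else image
  if (is.null(sample_coords)) {
    if (!inherits(image, "histo_image"))
      stop("sample_coords required for a plain array")
    sample_coords <- sample_stained_coords(image)
  }
  sample_coords <- as.matrix(sample_coords)
  if (nrow(sample_coords) < 2) stop("at least 2 sample pixels are required")
  if (any(sample_coords[, 1] < 1 | sample_coords[, 1] > dim(px)[1] |
            sample_coords[, 2] < 1 | sample_coords[, 2] > dim(px)[2]))
    stop("sample coordinates outside the image")
  bounds <- t(sapply(1:3, function(cc) {
    v <- px[cbind(sample_coords, cc)]
    c(low = max(0, mean(v) - n_sd * sd(v)),
      high = min(255, mean(v) + n_sd * sd(v)))
  }))
  rownames(bounds) <- c("R", "G", "B")
  structure(bounds, n_samples = nrow(sample_coords),
            class = "color_threshold")
}

#' Stained-area fraction within a region of interest
#'
#' A pixel counts as stained iff all three channels lie within their
#' threshold bounds (conjunctive rule). Reports the stained percentage of
#' the ROI.
#'
#' @param image a `histo_image` or RGB array.
#' @param threshold a `color_threshold`.
#' @param roi_mask logical height x width mask; default whole image.
#' @return class `region_quantification`: `area_fraction_pct`,
#'   `n_stained`, `n_pixels`, `roi_area_um2` (NA for plain arrays without
#'   pixel size).
#' @export
stained_area_fraction <- function(image, threshold, roi_mask = NULL) {
  px <- if (inherits(image, "histo_image")) image$pixels else image
  psz <- if (inherits(image, "histo_image")) image$pixel_size_um else NA_real_
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dim(px)[1], dim(px)[2])
  if (!any(roi_mask)) stop("empty ROI")
  inr <- matrix(TRUE, dim(px)[1], dim(px)[2])
  for (cc in 1:3)
    inr <- inr & px[, , cc] >= threshold[cc, 1] & px[, , cc] <= threshold[cc, 2]
  n_st <- sum(inr & roi_mask)
  n_tot <- sum(roi_mask)
  structure(list(area_fraction_pct = 100 * n_st / n_tot, n_stained = n_st,
                 n_pixels = n_tot, roi_area_um2 = n_tot * psz^2),
            class = "region_quantification")
}

#' Nucleus count and density per 100 um^2
#'
#' Segments nuclei by intensity thresholding (mean RGB below
#' `intensity_threshold`), labels connected components and filters them by
#' area; the density is `count * 100 / ROI area (um^2)`.
#'
#' @param image a `histo_image`.
#' @param roi_mask logical mask; default whole image.
#' @param intensity_threshold mean-RGB threshold below which a pixel is
#'   nuclear.
#' @param min_area_um2,max_area_um2 component area bounds.
#' @return class `region_quantification`: `cell_count`, `cell_density`
#'   (per 100 um^2), `roi_area_um2`.
#' @export
cell_density <- function(image, roi_mask = NULL, intensity_threshold = 120,
                         min_area_um2 = 0.05, max_area_um2 = 5) {
  stopifnot(inherits(image, "histo_image"))
  px <- image$pixels
  psz <- image$pixel_size_um
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, dim(px)[1], dim(px)[2])
  dark <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3 < intensity_threshold
  dark <- dark & roi_mask
  lab <- EBImage::bwlabel(dark)
  n_comp <- max(lab)
  count <- 0L
  if (n_comp > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n_comp) * psz^2
    count <- sum(areas >= min_area_um2 & areas <= max_area_um2)
  }
  if (count == 0 && n_comp == 0 && any(roi_mask))
    warning("no nucleus components detected; density 0")
  roi_area <- sum(roi_mask) * psz^2
  structure(list(cell_count = count, cell_density = count * 100 / roi_area,
                 roi_area_um2 = roi_area),
            class = "region_quantification")
}

#' @export
print.region_quantification <- function(x, ...) {
  if (!is.null(x$area_fraction_pct))
    cat(sprintf("Stained area: %.2f%% of %d ROI pixels\n",
                x$area_fraction_pct, x$n_pixels))
  if (!is.null(x$cell_count))
    cat(sprintf("Nuclei: %d in %.1f um^2 ROI (%.2f per 100 um^2)\n",
                x$cell_count, x$roi_area_um2, x$cell_density))
  invisible(x)
}
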