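## Shared fixture builders; everything is generated in code under fixed
## seeds so the suite is hermetic.

homogeneous_phantom <- function(gd = 5000, gl = 0,
                                grid_shape = c(64, 64, 9)) {
  build_property_phantom(grid_shape = grid_shape,
                         regions = list(brain = list(gd = gd, gl = gl)))
}

## wrapped, noiseless acquisition of an oblique plane wave; oblique
## incidence exercises all three curl components and every axis of the
## finite-difference stencils
oblique_acquisition <- function(gd = 5000, gl = 0, noise_sd_rad = 0,
                                seed = 1, wrap = TRUE) {
  ph <- homogeneous_phantom(gd, gl)
  fld <- plane_wave_field(ph)
  encode_wave_phases(fld, noise_sd_rad = noise_sd_rad, wrap = wrap,
                     seed = seed)
}

## tiny cohort table with hand-set values for statistics unit tests
toy_table <- function(values_by_week, group = "g", region = "r",
                      metric = "m") {
  rows <- list()
  for (w in names(values_by_week)) {
    v <- values_by_week[[w]]
    rows[[length(rows) + 1L]] <- data.frame(
      subject = paste0("s", seq_along(v)), group = group,
      week = as.integer(w), region = region, metric = metric, value = v)
  }
  do.call(rbind, rows)
}
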