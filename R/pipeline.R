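## ---------------------------------------------------------------------------
## Seeded end-to-end pipeline: cohort -> synthesis -> reconstruction ->
## ROI table -> statistics -> report
## ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' Fully serializable configuration for [run_pipeline()]. The cohort
#' defaults use the full study arms; `subjects_per_group` can shrink them
#' for quick demonstration runs. The imaging grid for the per-subject
#' wave simulation defaults to 32 x 32 x 9 voxels at the acquisition's
#' 0.3 mm resolution (a reduced field of view, keeping the shear
#' wavelength equally well resolved) so that a cohort run stays at desk
#' scale; all estimator options are exposed.
#'
#' @param seed root seed; all stages derive named substream seeds from it.
#' @param subjects_per_group optional named vector overriding group sizes.
#' @param mre_grid grid for the per-subject wave simulation.
#' @param frequency_hz vibration frequency.
#' @param phase_noise_sd_rad acquisition phase noise.
#' @param echo_noise_sd,dwi_noise_sd magnitude noise of the relaxometry /
#'   diffusion synthesis (signal units, s0 = 1000).
#' @param t2_filter_multiplier,t2_filter_mode noise filter settings.
#' @param smooth_sigma,combine,min_lap_frac inversion settings.
#' @param density_kg_m3 tissue density.
#' @param var_equal pooled (TRUE) vs Welch unpaired tests.
#' @param alpha significance level for the report (default 0.05).
#' @return class `pipeline_config` (a named list).
#' @export
default_pipeline_config <- function(seed = 1,
                                    subjects_per_group = c(
                                      treatment_control = 3L,
                                      radiotherapy = 3L, sham = 3L),
                                    mre_grid = c(32L, 32L, 9L),
                                    frequency_hz = 900,
                                    phase_noise_sd_rad = 0.05,
                                    echo_noise_sd = 10,
                                    dwi_noise_sd = 0,
                                    t2_filter_multiplier = 4,
                                    t2_filter_mode = "sample",
                                    smooth_sigma = 0.8,
                                    combine = "lsq",
                                    min_lap_frac = 0.05,
                                    density_kg_m3 = 1000,
                                    var_equal = TRUE,
                                    alpha = 0.05) {
  cfg <- list(seed = seed, subjects_per_group = subjects_per_group,
              mre_grid = as.integer(mre_grid), frequency_hz = frequency_hz,
              phase_noise_sd_rad = phase_noise_sd_rad,
              echo_noise_sd = echo_noise_sd, dwi_noise_sd = dwi_noise_sd,
              t2_filter_multiplier = t2_filter_multiplier,
              t2_filter_mode = t2_filter_mode,
              smooth_sigma = smooth_sigma, combine = combine,
              min_lap_frac = min_lap_frac, density_kg_m3 = density_kg_m3,
              var_equal = var_equal, alpha = alpha)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(...) message("[elastoquant] ", ...)

## voxels whose in-plane 4-neighbourhood (and the voxel itself) share one
## label; z is excluded so thin stacks keep their central slices
label_interior <- function(labels) {
  dm <- dim(labels)
  ok <- array(TRUE, dm)
  for (ax in 1:2) for (sgn in c(-1, 1)) {
    nb <- shift_axis(labels, ax, sgn)
    ok <- ok & nb == labels
  }
  ## rim of the grid cannot be checked against out-of-grid neighbours
  ok[c(1, dm[1]), , ] <- FALSE
  ok[, c(1, dm[2]), ] <- FALSE
  ok
}

## measure one subject-week: synthesize acquisitions from the subject's
## phantom, run all estimators, extract ROI means
measure_subject_week <- function(cohort, subject, week, group, cfg) {
  ## spacing is kept at the acquisition's 0.3 mm so the shear wavelength
  ## stays well resolved; a smaller grid shrinks the field of view instead
  ph <- build_subject_phantom(cohort, subject, week,
                              grid_shape = cfg$mre_grid,
                              spacing = c(0.3, 0.3, 0.3))
  sseed <- substream_seed(cfg$seed, paste0(subject, "_w", week))
  maps <- list()
  validity <- list()

  ## --- MRE: heterogeneous wave simulation + full reconstruction.
  ## The wave must propagate through the whole grid, so voxels outside the
  ## brain are given the brain moduli for the mechanical solve only.
  ## The source drives the thin slice direction (short propagation path,
  ## so the lossy tissue does not bury the far field under phase noise);
  ## Neumann sides admit standing waves, which still satisfy the
  ## Helmholtz equation and invert correctly — wave nodes are dropped by
  ## the inversion's Laplacian-magnitude filter.
  phw <- ph
  bg <- phw$labels == 0
  phw$gd[bg] <- phw$regions$brain$gd
  phw$gl[bg] <- phw$regions$brain$gl
  fld <- solve_heterogeneous_helmholtz(phw, source_face = "z-",
                                       polarization = c(0, 1, 0),
                                       frequency = cfg$frequency_hz,
                                       side_bc = "neumann")
  acq <- encode_wave_phases(fld, noise_sd_rad = cfg$phase_noise_sd_rad,
                            wrap = TRUE, seed = substream_seed(sseed, "mre"))
  el <- reconstruct_elastogram(acq, density = cfg$density_kg_m3,
                               smooth_sigma = cfg$smooth_sigma,
                               combine = cfg$combine,
                               min_lap_frac = cfg$min_lap_frac)
  ## local-homogeneity inversion is unreliable at region interfaces, so
  ## the elastogram ROI means use rim-eroded masks (in-plane 6-neighbour
  ## same-label voxels), as manual ROIs drawn inside a structure would
  interior <- label_interior(ph$labels)
  maps$gstar_kpa <- el$gstar / 1000
  maps$y <- el$y
  validity$gstar_kpa <- el$validity & interior
  validity$y <- el$validity & interior

  ## --- T2 relaxometry with noise-floor filter
  tr <- synthesize_echo_train(ph, noise_sd = cfg$echo_noise_sd,
                              seed = substream_seed(sseed, "t2"))
  nsd <- if (cfg$echo_noise_sd > 0)
    estimate_noise_level(tr, background_mask = ph$labels == 0) else 0
  t2m <- fit_t2_map(tr, noise_sd = nsd,
                    threshold_multiplier = cfg$t2_filter_multiplier,
                    mode = cfg$t2_filter_mode)
  maps$t2_ms <- t2m$t2
  validity$t2_ms <- t2m$validity

  ## --- DTI
  dwi <- synthesize_dwi(ph, noise_sd = cfg$dwi_noise_sd,
                        seed = substream_seed(sseed, "dwi"))
  tm <- fit_diffusion_tensor(dwi)
  maps$adc <- tm$adc * 1e6             # report in 1e-6 mm^2/s
  maps$fa <- tm$fa
  validity$adc <- tm$validity
  validity$fa <- tm$validity

  summarize_regions(maps, ph$labels, ph$spacing, subject, week, group,
                    validity = validity)
}

#' Run the full seeded pipeline
#'
#' Simulates a longitudinal cohort, builds each subject's phantom per
#' imaging week, synthesizes and reconstructs all quantitative maps (MRE
#' elastograms via the wrapped-phase chain, T2 maps, diffusion tensors),
#' assembles the measured longitudinal table, runs the paired and
#' unpaired comparisons, and writes every stage to `out_dir` together
#' with the effective configuration. Deterministic given the seed.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @return invisibly, a list with `table` (measured longitudinal table),
#'   `truth` (cohort truth), `comparisons` and `report_path`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.null(x)) "null" else x), file.path(out_dir, "config.yaml"))

  design <- default_study_design()
  if (!is.null(config$subjects_per_group)) {
    n <- design$groups
    for (g in names(config$subjects_per_group))
      n[[g]] <- as.integer(config$subjects_per_group[[g]])
    design$groups <- n
    design$week16_n <- min(design$week16_n, n[["radiotherapy"]])
  }
  pipeline_log("stage cohort: ", sum(design$groups), " subjects")
  cohort <- build_longitudinal_cohort(design,
                                      seed = substream_seed(config$seed,
                                                            "cohort"))
  write_longitudinal_table(cohort$truth, file.path(out_dir, "truth.csv"))

  sw <- unique(cohort$truth[, c("subject", "group", "week")])
  rows <- vector("list", nrow(sw))
  for (i in seq_len(nrow(sw))) {
    rows[[i]] <- tryCatch(
      measure_subject_week(cohort, sw$subject[i], sw$week[i], sw$group[i],
                           config),
      error = function(e) stop("stage imaging failed for ", sw$subject[i],
                               " week ", sw$week[i], ": ",
                               conditionMessage(e)))
  }
  table <- do.call(rbind, rows)
  pipeline_log("stage imaging: ", nrow(table), " ROI records")
  write_longitudinal_table(table, file.path(out_dir, "measured.csv"))

  ## --- statistics: paired successive-week tests per group/region/metric,
  ##     plus the cross-group delta and absolute-value comparisons
  comparisons <- list()
  add_cmp <- function(label, cmp) comparisons[[label]] <<- cmp
  for (grp in unique(table$group)) {
    tg <- table[table$group == grp, ]
    for (reg in unique(tg$region)) {
      trg <- tg[tg$region == reg, ]
      for (met in unique(trg$metric)) {
        wks <- sort(unique(trg$week[trg$metric == met]))
        for (i in seq_len(length(wks) - 1)) {
          lbl <- paste("paired", grp, reg, met, wks[i], wks[i + 1], sep = "_")
          cmp <- tryCatch(paired_timepoint_test(table, grp, reg, met,
                                                wks[i], wks[i + 1]),
                          error = function(e) NULL)
          if (!is.null(cmp)) add_cmp(lbl, cmp)
        }
      }
    }
  }
  for (met in c("gstar_kpa", "y", "adc", "fa")) {
    cmp <- tryCatch(group_comparison_test(table, "treatment_control", "sham",
                                          "corpus_callosum", met,
                                          delta_weeks = c(4, 8),
                                          var_equal = config$var_equal),
                    error = function(e) NULL)
    if (!is.null(cmp))
      add_cmp(paste("delta_cc", met, "tc_vs_sham", sep = "_"), cmp)
  }
  cmp <- tryCatch(group_comparison_test(table, "radiotherapy",
                                        "treatment_control", "tumor_core",
                                        "volume_mm3", week = 12,
                                        var_equal = config$var_equal),
                  error = function(e) NULL)
  if (!is.null(cmp)) add_cmp("volume_week12_rt_vs_tc", cmp)
  pipeline_log("stage statistics: ", length(comparisons), " comparisons")

  res <- data.frame(
    comparison = names(comparisons),
    kind = vapply(comparisons, function(x) x$kind, ""),
    estimate = vapply(comparisons, function(x) x$estimate, 0),
    t = vapply(comparisons, function(x) x$t, 0),
    df = vapply(comparisons, function(x) x$df, 0),
    p_value = vapply(comparisons, function(x) x$p_value, 0),
    significant = vapply(comparisons,
                         function(x) x$p_value <= config$alpha, TRUE))
  write.csv(res, file.path(out_dir, "comparisons.csv"), row.names = FALSE)

  report_path <- file.path(out_dir, "report.txt")
  con <- file(report_path, "w")
  writeLines(c("elastoquant pipeline report",
               paste("seed:", config$seed),
               paste("subjects:", sum(design$groups)),
               paste("alpha:", config$alpha), ""), con)
  for (nm in names(comparisons)) {
    writeLines(paste0("== ", nm), con)
    writeLines(utils::capture.output(print(comparisons[[nm]])), con)
    writeLines("", con)
  }
  close(con)
  pipeline_log("report written to ", report_path)
  invisible(list(table = table, truth = cohort$truth,
                 comparisons = comparisons, report_path = report_path))
}
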