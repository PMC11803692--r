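## ---------------------------------------------------------------------------
## Longitudinal study design and cohort synthesis
## ---------------------------------------------------------------------------

#' Default longitudinal study design
#'
#' Encodes the emulated preclinical glioma study: three arms
#' (`treatment_control`, n = 10; `radiotherapy`, n = 13; `sham`, n = 9)
#' imaged every 4 weeks from week 4, the tumor-bearing arms to week 12 and
#' a 5-animal radiotherapy subset to week 16. The ground-truth group
#' trajectories are the published group means for each region and metric
#' (tumor core volume, T2, ADC, FA, |G*|, Y; callosal metrics; sham needle
#' tract and contralateral control). Where a group mean is not printed for
#' a week, the nearest printed value is carried forward (documented in the
#' methods vignette).
#'
#' Between-subject dispersion is specified per metric as a standard
#' deviation; the defaults are reconstructed from printed standard errors
#' as SEM * sqrt(n). Within-subject correlation across weeks defaults to
#' 0.5 and is configurable.
#'
#' @param groups named integer vector of subjects per group.
#' @param weeks imaging weeks.
#' @param between_subject_sd named numeric vector of per-metric SDs
#'   (units of the metric).
#' @param within_subject_correlation correlation of a subject's repeated
#'   values across weeks, in [0, 1).
#' @return class `study_design`.
#' @export
default_study_design <- function(groups = c(treatment_control = 10L,
                                            radiotherapy = 13L,
                                            sham = 9L),
                                 weeks = c(4L, 8L, 12L, 16L),
                                 between_subject_sd = c(
                                   volume_mm3 = 0.72, t2_ms = 1.34,
                                   adc = 38.8, fa = 0.040,
                                   gstar_kpa = 1.06, y = 0.058),
                                 within_subject_correlation = 0.5) {
  tc_core <- list(
    volume_mm3 = c(`4` = 1.6, `8` = 3.76, `12` = 16.88),
    t2_ms = c(`4` = 40.19, `8` = 41.65, `12` = 44.83),
    adc = c(`4` = 600, `8` = 610.2, `12` = 711.2),
    fa = c(`4` = 0.215, `8` = 0.244, `12` = 0.236),
    gstar_kpa = c(`4` = 3.9, `8` = 5.51, `12` = 4.24),
    y = c(`4` = 0.322, `8` = 0.375, `12` = 0.346))
  tc_cc <- list(
    t2_ms = c(`4` = 40.5, `8` = 40.44, `12` = 40.44),
    adc = c(`4` = 598.9, `8` = 608.5, `12` = 608.5),
    fa = c(`4` = 0.382, `8` = 0.386, `12` = 0.386),
    gstar_kpa = c(`4` = 4.44, `8` = 5.31, `12` = 5.31),
    y = c(`4` = 0.337, `8` = 0.354, `12` = 0.354))
  rt_core <- list(
    volume_mm3 = c(`4` = 1.6, `8` = 3.76, `12` = 10.96, `16` = 23.01),
    t2_ms = c(`4` = 40.19, `8` = 41.65, `12` = 43.06, `16` = 44.10),
    adc = c(`4` = 600, `8` = 610.2, `12` = 654.0, `16` = 730.5),
    fa = c(`4` = 0.215, `8` = 0.244, `12` = 0.236, `16` = 0.248),
    gstar_kpa = c(`4` = 4.2, `8` = 4.94, `12` = 5.38, `16` = 4.42),
    y = c(`4` = 0.322, `8` = 0.375, `12` = 0.346, `16` = 0.346))
  rt_cc <- lapply(tc_cc, function(v) c(v, `16` = unname(v[length(v)])))
  ## sham arm: callosal softening of -1.1 kPa from week 4 to 8 (printed as a
  ## group delta); needle tract and contralateral region show no change.
  sham_cc <- list(
    t2_ms = c(`4` = 40.5, `8` = 40.5, `12` = 40.5),
    adc = c(`4` = 598.9, `8` = 593.9, `12` = 593.9),
    fa = c(`4` = 0.382, `8` = 0.394, `12` = 0.394),
    gstar_kpa = c(`4` = 4.44, `8` = 3.34, `12` = 3.34),
    y = c(`4` = 0.337, `8` = 0.337, `12` = 0.337))
  flat <- list(
    t2_ms = c(`4` = 40.4, `8` = 40.4, `12` = 40.4),
    adc = c(`4` = 600, `8` = 600, `12` = 600),
    fa = c(`4` = 0.20, `8` = 0.20, `12` = 0.20),
    gstar_kpa = c(`4` = 4.4, `8` = 4.4, `12` = 4.4),
    y = c(`4` = 0.33, `8` = 0.33, `12` = 0.33))
  traj <- list(
    treatment_control = list(tumor_core = tc_core, corpus_callosum = tc_cc),
    radiotherapy = list(tumor_core = rt_core, corpus_callosum = rt_cc),
    sham = list(corpus_callosum = sham_cc, needle_tract = flat,
                contralateral = flat))
  group_weeks <- list(treatment_control = c(4L, 8L, 12L),
                      radiotherapy = c(4L, 8L, 12L, 16L),
                      sham = c(4L, 8L, 12L))
  ## only the first `week16_n` radiotherapy subjects (by id) are imaged at 16
  structure(list(groups = groups, weeks = weeks, group_weeks = group_weeks,
                 week16_n = 5L, truth_trajectories = traj,
                 between_subject_sd = between_subject_sd,
                 within_subject_correlation = within_subject_correlation),
            class = "study_design")
}

#' Simulate a longitudinal cohort with known subject-level truth
#'
#' Draws per-subject ground-truth trajectories around the design's group
#' means: `value = group mean + b_s + e_sw`, where the subject effect
#' `b_s` and the occasion effect `e_sw` are zero-mean Gaussians
#' partitioning the between-subject variance so that values of one subject
#' correlate `rho` across weeks. With zero dispersion every subject equals
#' the group mean. Identical seeds give bitwise-identical tables.
#'
#' @param design a `study_design`.
#' @param seed integer seed.
#' @return class `longitudinal_cohort`: list with `truth` (data.frame of
#'   subject, group, week, region, metric, value) and `design`.
#' @export
build_longitudinal_cohort <- function(design = default_study_design(),
                                      seed = 1) {
  stopifnot(inherits(design, "study_design"))
  if (any(design$groups < 2)) stop("need at least 2 subjects per group")
  sds <- design$between_subject_sd
  rho <- design$within_subject_correlation
  subj_c <- grp_c <- reg_c <- met_c <- character(0)
  week_c <- integer(0)
  val_c <- numeric(0)
  with_seed(seed, {
    for (grp in names(design$groups)) {
      n <- design$groups[[grp]]
      gw <- design$group_weeks[[grp]]
      regs <- design$truth_trajectories[[grp]]
      if (is.null(regs)) stop("no trajectories for group ", grp)
      for (s in seq_len(n)) {
        sid <- sprintf("%s_%02d", grp, s)
        s_weeks <- gw
        if (grp == "radiotherapy" && s > design$week16_n)
          s_weeks <- setdiff(gw, 16L)
        for (reg in names(regs)) {
          for (met in names(regs[[reg]])) {
            tr <- regs[[reg]][[met]]
            if (!all(as.character(s_weeks) %in% names(tr)))
              stop("trajectory ", grp, "/", reg, "/", met,
                   " does not cover all imaged weeks")
            if (!met %in% names(sds)) stop("no dispersion for metric ", met)
            sdm <- sds[[met]]
            b <- rnorm(1, sd = sqrt(rho) * sdm)
            e <- rnorm(length(s_weeks), sd = sqrt(1 - rho) * sdm)
            v <- unname(tr[as.character(s_weeks)]) + b + e
            if (met == "volume_mm3") v <- pmax(v, 0.01)
            nw <- length(s_weeks)
            subj_c <- c(subj_c, rep(sid, nw))
            grp_c <- c(grp_c, rep(grp, nw))
            week_c <- c(week_c, as.integer(s_weeks))
            reg_c <- c(reg_c, rep(reg, nw))
            met_c <- c(met_c, rep(met, nw))
            val_c <- c(val_c, v)
          }
        }
      }
    }
  })
  truth <- data.frame(subject = subj_c, group = grp_c, week = week_c,
                      region = reg_c, metric = met_c, value = val_c,
                      stringsAsFactors = FALSE)
  structure(list(truth = truth, design = design, seed = seed),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat("Longitudinal cohort:", length(unique(x$truth$subject)), "subjects,",
      nrow(x$truth), "truth records\n")
  print(table(x$truth$group[!duplicated(x$truth$subject)]))
  invisible(x)
}

#' Build the property phantom of one subject at one week
#'
#' Converts the subject's ground-truth metrics into a voxelized phantom:
#' the tumor core is an ellipsoid calibrated to the subject's true volume,
#' the corpus callosum a curved band, and per-region moduli are derived
#' from `|G*|` and `Y` via `gd = |G*| cos(Y pi / 2)`,
#' `gl = |G*| sin(Y pi / 2)`. Diffusion tensors are prolate with mean
#' diffusivity equal to the true ADC and anisotropy matching the true FA.
#'
#' @param cohort a `longitudinal_cohort`.
#' @param subject subject id present in the cohort.
#' @param week imaging week.
#' @param grid_shape,spacing phantom geometry.
#' @return a `property_phantom`.
#' @export
build_subject_phantom <- function(cohort, subject, week,
                                  grid_shape = c(64, 64, 9),
                                  spacing = c(0.3, 0.3, 0.3)) {
  tr <- cohort$truth
  tr <- tr[tr$subject == subject & tr$week == week, ]
  if (!nrow(tr)) stop("no truth records for ", subject, " week ", week)
  getv <- function(region, metric, default = NA_real_) {
    v <- tr$value[tr$region == region & tr$metric == metric]
    if (length(v)) v[[1]] else default
  }
  fov <- grid_shape * spacing
  ctr <- (grid_shape - 1) / 2 * spacing
  regions <- list()
  mk_params <- function(region) {
    gstar <- getv(region, "gstar_kpa") * 1000
    y <- getv(region, "y")
    out <- list()
    if (is.finite(gstar) && is.finite(y)) {
      y <- min(max(y, 0), 1)
      out$gd <- max(gstar * cos(y * pi / 2), 50)
      out$gl <- max(gstar * sin(y * pi / 2), 0)
    }
    t2 <- getv(region, "t2_ms")
    if (is.finite(t2)) out$t2 <- max(t2, 1)
    adc <- getv(region, "adc")
    fa <- getv(region, "fa")
    if (is.finite(adc) && is.finite(fa)) {
      md <- max(adc, 50) * 1e-6          # table unit is 1e-6 mm^2/s
      fa <- min(max(fa, 0), 0.95)
      delta <- fa * sqrt(3 / (9 - 6 * fa^2))
      out$eigenvalues <- md * c(1 + 2 * delta, 1 - delta, 1 - delta)
    }
    out
  }
  regs_here <- unique(tr$region)
  if ("tumor_core" %in% regs_here) {
    p <- mk_params("tumor_core")
    p$shape <- "ellipsoid"
    p$center_mm <- ctr + c(0.15 * fov[1] + 0.131 * spacing[1], 0.1 * fov[2] + 0.217 * spacing[2], 0.113 * spacing[3])
    p$radii_mm <- c(1.4, 1.2, 0.55)
    p$volume_mm3 <- max(getv("tumor_core", "volume_mm3", 2), 0.1)
    regions$tumor_core <- p
  }
  if ("corpus_callosum" %in% regs_here) {
    p <- mk_params("corpus_callosum")
    p$shape <- "band"
    p$center_mm <- c(ctr[1], ctr[2] - 0.18 * fov[2], ctr[3])
    p$curvature <- 0.04
    p$half_thickness_mm <- 0.75
    p$half_length_mm <- 0.35 * fov[1]
    p$half_depth_mm <- fov[3]
    regions$corpus_callosum <- p
  }
  if ("needle_tract" %in% regs_here) {
    p <- mk_params("needle_tract")
    p$shape <- "cylinder"
    p$center_mm <- ctr + c(0.15 * fov[1], 0.1 * fov[2], 0)
    p$radius_mm <- 0.9
    regions$needle_tract <- p
  }
  if ("contralateral" %in% regs_here) {
    p <- mk_params("contralateral")
    p$shape <- "cylinder"
    p$center_mm <- ctr + c(-0.15 * fov[1], 0.1 * fov[2], 0)
    p$radius_mm <- 0.9
    regions$contralateral <- p
  }
  build_property_phantom(grid_shape, spacing, regions)
}
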