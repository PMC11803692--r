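## ---------------------------------------------------------------------------
## ROI extraction, longitudinal tables, paired and unpaired comparisons
## ---------------------------------------------------------------------------

sem <- function(x) sd(x) / sqrt(length(x))

#' Summarize quantitative maps over labeled regions
#'
#' Computes the arithmetic mean of each named map over the valid in-mask
#' voxels of each region, plus the region volume (voxel count times voxel
#' volume) as `volume_mm3`, and returns tidy longitudinal-table rows.
#'
#' @param maps named list of 3-D arrays (metric name -> map). Units are
#'   the caller's; conventional metric names are `gstar_kpa`, `y`,
#'   `t2_ms`, `adc`, `fa`.
#' @param labels integer label volume (see [region_labels()]), same grid
#'   as the maps.
#' @param spacing voxel spacing, mm.
#' @param subject,week,group identifiers attached to the rows.
#' @param validity optional named list of logical masks per metric;
#'   voxels outside are ignored. NAs in a map are always ignored.
#' @param regions region names to summarize; default: all present except
#'   background and brain.
#' @param volume_region region whose volume is reported (default
#'   `tumor_core` when present).
#' @return data.frame with columns subject, group, week, region, metric,
#'   value, n_voxels.
#' @export
summarize_regions <- function(maps, labels, spacing, subject, week, group,
                              validity = NULL, regions = NULL,
                              volume_region = "tumor_core") {
  stopifnot(is.list(maps), length(maps) > 0)
  lv <- REGION_LEVELS
  present <- names(lv)[lv %in% unique(as.integer(labels))]
  if (is.null(regions))
    regions <- setdiff(present, c("background", "brain"))
  rows <- list()
  for (reg in regions) {
    rmask <- labels == lv[[reg]]
    if (!any(rmask)) stop("empty mask for region ", reg)
    for (met in names(maps)) {
      mp <- maps[[met]]
      if (!identical(dim(mp), dim(labels)))
        stop("map ", met, " does not share the label grid")
      vm <- rmask & !is.na(mp)
      if (!is.null(validity[[met]])) vm <- vm & validity[[met]]
      if (!any(vm)) {
        message("region ", reg, ": no valid voxels for ", met, "; omitted")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, group = group, week = week, region = reg,
        metric = met, value = mean(mp[vm]), n_voxels = sum(vm),
        stringsAsFactors = FALSE)
    }
    if (reg == volume_region) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, group = group, week = week, region = reg,
        metric = "volume_mm3", value = sum(rmask) * prod(spacing),
        n_voxels = sum(rmask), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

select_values <- function(table, group, region, metric, week) {
  v <- table[table$group == group & table$region == region &
               table$metric == metric & table$week == week, ]
  setNames(v$value, v$subject)
}

comparison_result <- function(kind, tt, groups, means, sems, ns) {
  structure(list(kind = kind, estimate = unname(tt$estimate[1] -
                                                  ifelse(length(tt$estimate) > 1, tt$estimate[2], 0)),
                 group_means = means, group_sems = sems, n = ns,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, groups = groups),
            class = "mre_comparison")
}

#' Paired t-test between two time points
#'
#' Two-sided paired t-test on the per-subject differences of one metric in
#' one region of one group, using only subjects present at both weeks.
#' Group means and SEMs are reported over the paired subset.
#'
#' @param table longitudinal table (see [summarize_regions()] or
#'   [build_longitudinal_cohort()]).
#' @param group,region,metric selection.
#' @param week_a,week_b the two time points.
#' @return class `mre_comparison`.
#' @export
paired_timepoint_test <- function(table, group, region, metric,
                                  week_a, week_b) {
  va <- select_values(table, group, region, metric, week_a)
  vb <- select_values(table, group, region, metric, week_b)
  common <- intersect(names(va), names(vb))
  if (length(common) < 2) stop("fewer than 2 subjects with both weeks")
  va <- va[common]; vb <- vb[common]
  d <- vb - va
  tt <- if (all(d == 0)) {
    list(estimate = 0, statistic = 0, parameter = length(d) - 1, p.value = 1)
  } else t.test(vb, va, paired = TRUE)
  comparison_result(
    "paired_timepoints", tt, c(paste0("week", week_b), paste0("week", week_a)),
    means = c(mean(vb), mean(va)), sems = c(sem(vb), sem(va)),
    ns = c(length(vb), length(va)))
}

#' Per-subject differences between two time points
#'
#' Computes `value(week_b) - value(week_a)` per subject, region and
#' metric; subjects missing either week are excluded (with a message).
#'
#' @param table longitudinal table.
#' @param week_a,week_b the two weeks (`week_a` the baseline).
#' @return data.frame with columns subject, group, region, metric,
#'   week_a, week_b, delta.
#' @export
longitudinal_deltas <- function(table, week_a, week_b) {
  a <- table[table$week == week_a, ]
  b <- table[table$week == week_b, ]
  m <- merge(a, b, by = c("subject", "group", "region", "metric"),
             suffixes = c("_a", "_b"))
  if (!nrow(m)) {
    warning("no subjects shared between weeks ", week_a, " and ", week_b)
    return(data.frame(subject = character(), group = character(),
                      region = character(), metric = character(),
                      week_a = integer(), week_b = integer(),
                      delta = numeric()))
  }
  dropped <- setdiff(unique(a$subject), unique(m$subject))
  if (length(dropped))
    message(length(dropped), " subject(s) missing week ", week_b,
            " excluded from deltas")
  data.frame(subject = m$subject, group = m$group, region = m$region,
             metric = m$metric, week_a = week_a, week_b = week_b,
             delta = m$value_b - m$value_a, stringsAsFactors = FALSE)
}

#' Unpaired t-test between two groups
#'
#' Two-sided unpaired t-test comparing either the absolute values of a
#' metric at one week (`week = ...`) or the per-subject differences
#' between two successive weeks (`delta_weeks = c(a, b)`). The default is
#' the pooled-variance (Student) test; `var_equal = FALSE` selects Welch.
#'
#' @param table longitudinal table.
#' @param group_1,group_2 the two arms.
#' @param region,metric selection.
#' @param week week for an absolute-value comparison.
#' @param delta_weeks length-2 weeks for a delta comparison.
#' @param var_equal pooled variance (default) vs. Welch.
#' @return class `mre_comparison`.
#' @export
group_comparison_test <- function(table, group_1, group_2, region, metric,
                                  week = NULL, delta_weeks = NULL,
                                  var_equal = TRUE) {
  if (is.null(week) == is.null(delta_weeks))
    stop("specify exactly one of `week` or `delta_weeks`")
  if (!is.null(week)) {
    x1 <- select_values(table, group_1, region, metric, week)
    x2 <- select_values(table, group_2, region, metric, week)
    kind <- "unpaired_groups"
  } else {
    dd <- longitudinal_deltas(table, delta_weeks[1], delta_weeks[2])
    dd <- dd[dd$region == region & dd$metric == metric, ]
    x1 <- dd$delta[dd$group == group_1]
    x2 <- dd$delta[dd$group == group_2]
    kind <- "unpaired_delta"
  }
  if (length(x1) < 2 || length(x2) < 2)
    stop("fewer than 2 subjects in an arm")
  degenerate <- var(x1) == 0 && var(x2) == 0
  tt <- if (degenerate && mean(x1) == mean(x2)) {
    warning("degenerate zero-variance arms with equal means; p set to 1")
    list(estimate = c(mean(x1), mean(x2)), statistic = 0,
         parameter = length(x1) + length(x2) - 2, p.value = 1)
  } else t.test(x1, x2, var.equal = var_equal)
  comparison_result(kind, tt, c(group_1, group_2),
                    means = c(mean(x1), mean(x2)),
                    sems = c(sem(x1), sem(x2)),
                    ns = c(length(x1), length(x2)))
}

#' Benjamini-Hochberg adjustment of a set of comparisons
#'
#' Optional multiple-testing control for reuse outside the exploratory
#' setting: adjusts the p-values of a list of `mre_comparison` objects.
#'
#' @param comparisons list of `mre_comparison` objects.
#' @return the list with `p_adjusted` added to each element.
#' @export
adjust_comparisons <- function(comparisons) {
  p <- vapply(comparisons, function(x) x$p_value, 0)
  pa <- stats::p.adjust(p, method = "BH")
  Map(function(cmp, padj) { cmp$p_adjusted <- padj; cmp }, comparisons, pa)
}

#' @export
print.mre_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s\n", x$kind, x$groups[1], x$groups[2]))
  for (i in 1:2)
    cat(sprintf("  %-18s %8.4g +/- %.4g (SEM), n = %d\n", x$groups[i],
                x$group_means[i], x$group_sems[i], x$n[i]))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g%s\n", x$t, x$df, x$p_value,
              if (x$p_value <= 0.05) "  (significant at alpha = 0.05)" else ""))
  invisible(x)
}
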