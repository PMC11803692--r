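test_that("region summaries are masked means plus voxel-count volumes", {
  ph <- build_property_phantom(grid_shape = c(32, 32, 9), regions = list(
    brain = list(gd = 5000),
    corpus_callosum = list(shape = "band", center_mm = c(4.65, 3, 1.2),
                           curvature = 0, half_thickness_mm = 0.45,
                           half_length_mm = 3, half_depth_mm = 10),
    tumor_core = list(shape = "ellipsoid", center_mm = c(6, 6, 1.2),
                      radii_mm = c(1.5, 1.2, 1))))
  lv <- region_labels()
  cc <- ph$labels == lv[["corpus_callosum"]]
  maps <- list(gstar_kpa = array(5.31, dim(ph$labels)))
  rows <- summarize_regions(maps, ph$labels, ph$spacing,
                            subject = "s1", week = 8, group = "g")
  cc_row <- rows[rows$region == "corpus_callosum" &
                   rows$metric == "gstar_kpa", ]
  expect_equal(cc_row$value, 5.31)
  expect_equal(cc_row$n_voxels, sum(cc))
  vol_row <- rows[rows$metric == "volume_mm3", ]
  expect_equal(vol_row$value,
               sum(ph$labels == lv[["tumor_core"]]) * prod(ph$spacing))

  ## a 625-voxel mask at 0.3 mm isotropic is 16.875 mm^3
  expect_equal(625 * prod(c(0.3, 0.3, 0.3)), 16.875)

  ## half-invalid map: mean over the valid half only
  m2 <- array(2, dim(ph$labels))
  v <- array(TRUE, dim(ph$labels))
  idx <- which(cc)
  half <- idx[seq_len(floor(length(idx) / 2))]
  v[half] <- FALSE
  m2[half] <- 1e6          # must be ignored
  rows2 <- summarize_regions(list(x = m2), ph$labels, ph$spacing,
                             subject = "s", week = 1, group = "g",
                             validity = list(x = v))
  r2 <- rows2[rows2$region == "corpus_callosum" & rows2$metric == "x", ]
  expect_equal(r2$value, 2)
  expect_equal(r2$n_voxels, sum(cc) - length(half))
})

test_that("paired t-test matches the textbook closed form on hand data", {
  tab <- toy_table(list(`4` = c(4, 4, 4), `8` = c(5, 6, 7)))
  cmp <- paired_timepoint_test(tab, "g", "r", "m", 4, 8)
  d <- c(1, 2, 3)
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 2)
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 2)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-12)
  expect_equal(cmp$group_means, c(6, 4))
  expect_equal(cmp$group_sems, c(sd(c(5, 6, 7)) / sqrt(3), 0))
  ## null data: t = 0, p = 1
  tab0 <- toy_table(list(`4` = c(1, 2, 3), `8` = c(1, 2, 3)))
  cmp0 <- paired_timepoint_test(tab0, "g", "r", "m", 4, 8)
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p_value, 1)
  ## pairing uses only subjects present at both weeks
  tab2 <- rbind(tab, data.frame(subject = "s9", group = "g", week = 4L,
                                region = "r", metric = "m", value = 100))
  cmp2 <- paired_timepoint_test(tab2, "g", "r", "m", 4, 8)
  expect_equal(cmp2$n, c(3L, 3L))
  expect_error(paired_timepoint_test(tab[tab$subject == "s1", ],
                                     "g", "r", "m", 4, 8), "2 subjects")
})

test_that("unpaired test matches the pooled-variance closed form", {
  x <- c(4.1, 5.2, 6.3, 5.0)
  y <- c(3.0, 3.5, 4.1)
  tab <- rbind(
    data.frame(subject = paste0("a", 1:4), group = "g1", week = 8L,
               region = "r", metric = "m", value = x),
    data.frame(subject = paste0("b", 1:3), group = "g2", week = 8L,
               region = "r", metric = "m", value = y))
  cmp <- group_comparison_test(tab, "g1", "g2", "r", "m", week = 8)
  sp2 <- (3 * var(x) + 2 * var(y)) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(cmp$t, t_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 5)
  expect_equal(cmp$estimate, mean(x) - mean(y), tolerance = 1e-12)
  ## identical hand data: t = 0, p = 1
  tab2 <- rbind(
    data.frame(subject = paste0("a", 1:3), group = "g1", week = 8L,
               region = "r", metric = "m", value = c(1, 2, 3)),
    data.frame(subject = paste0("b", 1:3), group = "g2", week = 8L,
               region = "r", metric = "m", value = c(1, 2, 3)))
  cmp2 <- group_comparison_test(tab2, "g1", "g2", "r", "m", week = 8)
  expect_equal(cmp2$t, 0)
  expect_equal(cmp2$p_value, 1)
  ## Welch option changes the degrees of freedom
  cmpw <- group_comparison_test(tab, "g1", "g2", "r", "m", week = 8,
                                var_equal = FALSE)
  expect_false(isTRUE(all.equal(cmpw$df, 5)))
})

test_that("deltas subtract baseline from follow-up per subject", {
  tab <- toy_table(list(`4` = c(4.44, 5.0), `8` = c(5.31, 5.5)))
  dd <- longitudinal_deltas(tab, 4, 8)
  expect_equal(dd$delta[dd$subject == "s1"], 0.87, tolerance = 1e-12)
  ## same-week delta is identically zero
  dd0 <- longitudinal_deltas(tab, 4, 4)
  expect_true(all(dd0$delta == 0))
  ## disjoint subjects -> empty result with a warning
  a <- toy_table(list(`4` = c(1, 2)))
  b <- toy_table(list(`8` = c(1, 2)))
  b$subject <- paste0("z", 1:2)
  expect_warning(out <- longitudinal_deltas(rbind(a, b), 4, 8),
                 "no subjects")
  expect_equal(nrow(out), 0)
})

test_that("reported SEM equals sd/sqrt(n) on random tables", {
  set.seed(12)
  for (i in 1:5) {
    v4 <- rnorm(7); v8 <- rnorm(7)
    tab <- toy_table(list(`4` = v4, `8` = v8))
    cmp <- paired_timepoint_test(tab, "g", "r", "m", 4, 8)
    expect_equal(cmp$group_sems, c(sd(v8) / sqrt(7), sd(v4) / sqrt(7)),
                 tolerance = 1e-12)
  }
})

test_that("type-I error is calibrated near alpha under the null", {
  set.seed(77)
  n_rep <- 2000
  rej_p <- rej_u <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(10); b <- rnorm(10)
    rej_p[i] <- t.test(a, b, paired = TRUE)$p.value <= 0.05
    rej_u[i] <- t.test(rnorm(12), rnorm(9), var.equal = TRUE)$p.value <= 0.05
  }
  expect_gt(mean(rej_p), 0.03); expect_lt(mean(rej_p), 0.07)
  expect_gt(mean(rej_u), 0.03); expect_lt(mean(rej_u), 0.07)
})

test_that("the callosal stiffening is detected with high power at n = 23", {
  ## paired test on the generator's week-4 -> week-8 callosal trajectory
  ## (4.44 -> 5.31 kPa) in a 23-animal tumor-bearing cohort
  des <- default_study_design(groups = c(treatment_control = 23L,
                                         radiotherapy = 2L, sham = 9L))
  hits <- vapply(1:200, function(s) {
    tab <- build_longitudinal_cohort(des, seed = 5000 + s)$truth
    paired_timepoint_test(tab, "treatment_control", "corpus_callosum",
                          "gstar_kpa", 4, 8)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("group delta comparison separates stiffening from sham softening", {
  ## printed deltas: +0.88 kPa (tumor-bearing, n = 23) vs -1.1 kPa (sham,
  ## n = 9); significance in >= 80% of replicates at default dispersion
  des <- default_study_design(groups = c(treatment_control = 23L,
                                         radiotherapy = 2L, sham = 9L))
  hits <- vapply(1:100, function(s) {
    tab <- build_longitudinal_cohort(des, seed = 7000 + s)$truth
    group_comparison_test(tab, "treatment_control", "sham",
                          "corpus_callosum", "gstar_kpa",
                          delta_weeks = c(4, 8))$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("BH adjustment is available and monotone", {
  cmps <- list(
    structure(list(p_value = 0.01), class = "mre_comparison"),
    structure(list(p_value = 0.04), class = "mre_comparison"),
    structure(list(p_value = 0.5), class = "mre_comparison"))
  adj <- adjust_comparisons(cmps)
  expect_equal(vapply(adj, `[[`, 0, "p_adjusted"),
               stats::p.adjust(c(0.01, 0.04, 0.5), "BH"))
})
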