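test_that("group t-tests use the pooled form, signed TR minus DD", {
  coh <- simulate_cohort(n_per_group = 12, n_rois = 3,
                         informative_rois = 2, effect_sizes = 2,
                         confound_effects = list(), seed = 1)
  tt <- roi_group_ttests(coh$features, coh$labels)
  expect_equal(nrow(tt), 3 * 5)
  expect_true(all(tt$df == 22))
  # planted TR > DD gives positive t in the informative ROI
  expect_true(all(tt$t[tt$roi == "roi002"] > 0))
  # dual route: moments of the same samples through the summary formula
  tr <- coh$labels == -1
  x1 <- coh$features[!tr, 2, 1]; x2 <- coh$features[tr, 2, 1]
  by_summary <- t_from_summary(mean(x1), sd(x1), 12, mean(x2), sd(x2), 12)
  row <- tt[tt$roi == "roi002" & tt$contrast == "M-vs-B", ]
  expect_equal(row$t, by_summary$t, tolerance = 1e-10)
  expect_equal(row$p, by_summary$p, tolerance = 1e-10)
})

test_that("swapping group labels flips t and preserves p", {
  coh <- toy_cohort(n_per_group = 8, n_rois = 2, d = 1.5, seed = 2)
  a <- roi_group_ttests(coh$features, coh$labels)
  b <- roi_group_ttests(coh$features, -coh$labels)
  expect_equal(b$t, -a$t, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("identical groups give t = 0, degenerate cells error", {
  feats <- array(rep(rnorm(10), 4), dim = c(8, 1, 5))
  feats[1:4, , ] <- feats[5:8, , ]
  labels <- rep(c(1, -1), each = 4)
  tt <- roi_group_ttests(feats, labels)
  expect_true(all(abs(tt$t) < 1e-12))
  expect_true(all(tt$p > 1 - 1e-12))
  const <- array(1, dim = c(8, 1, 5))
  expect_error(roi_group_ttests(const, labels), "variance")
})

test_that("planted d = 1.5 at n = 22 matches the noncentral-t oracle", {
  ts <- numeric(500)
  for (s in 1:500) {
    coh <- simulate_cohort(n_per_group = 22, n_rois = 1, n_contrasts = 1,
                           informative_rois = 1, effect_sizes = 1.5,
                           confound_effects = list(), seed = 2000 + s)
    tr <- coh$labels == -1
    ts[s] <- t_from_summary(mean(coh$features[!tr, 1, 1]),
                            sd(coh$features[!tr, 1, 1]), 22,
                            mean(coh$features[tr, 1, 1]),
                            sd(coh$features[tr, 1, 1]), 22)$t
  }
  ncp <- 1.5 * sqrt(22 / 2)
  expected <- noncentral_t_mean(ncp, 42)
  expect_equal(ncp, 4.97, tolerance = 0.01)
  expect_lt(abs(mean(ts) - expected), 3 * sd(ts) / sqrt(500))
})

test_that("printed summary moments reproduce the published t statistics", {
  res <- recompute_table1()
  expect_true(all(abs(res$delta) < 0.05))
  expect_true(all(res$df == 42))
  iq <- t_from_summary(10.59, 1.78, 22, 13.70, 2.82, 22)
  expect_equal(iq$t, 4.374, tolerance = 1e-3)
  dsm <- t_from_summary(60.09, 10.73, 22, 46.11, 5.49, 22)
  expect_equal(dsm$t, -5.440, tolerance = 1e-3)
  expect_error(t_from_summary(1, 0, 5, 1, 0, 5), "variance")
})

test_that("chi-square matches direct summation, without continuity
          correction", {
  prop <- rbind(c(10, 20), c(5, 10))
  expect_equal(chi_square_counts(prop)$chisq, 0, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    tab <- matrix(sample(5:30, 4), 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    brute <- sum((tab - expected)^2 / expected)
    got <- chi_square_counts(tab)
    expect_equal(got$chisq, brute, tolerance = 1e-10)
    expect_equal(got$df, 1)
    expect_equal(got$p, pchisq(brute, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(chi_square_counts(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("composites average their listed components", {
  np <- data.frame(TR_accuracy = 1, TR_speed = 0, SWR_accuracy = -1,
                   SWR_speed = 0, SPWR_accuracy = 1, SPWR_speed = -1,
                   SLFS = 2, SLBS = 2, SDFS = 2, SDBS = 2, SNWR = -0.5)
  cs <- composite_scores(np)
  expect_equal(cs$reading, 0)
  expect_equal(cs$vwm, 2)
  expect_equal(cs$phonology, -0.5)
  allsame <- np
  allsame[1, ] <- 0.7
  expect_equal(composite_scores(allsame)$reading, 0.7)
  expect_error(composite_scores(np[, -3]), "SWR_accuracy")
})

test_that("brain-behavior correlations: self-correlation, planted
          coupling, affine invariance", {
  coh <- toy_cohort(n_per_group = 22, n_rois = 2, d = 0, seed = 4)
  self <- data.frame(reading = coh$features[, 1, 3])
  res <- roi_behavior_correlations(coh$features, self, roi_subset = 1)
  expect_equal(res$r[res$contrast == "CML6-vs-B"], 1, tolerance = 1e-12)
  # affine rescaling of the behavioral score leaves r unchanged
  res2 <- roi_behavior_correlations(
    coh$features, data.frame(reading = 10 - 3 * self$reading),
    roi_subset = 1)
  expect_equal(abs(res2$r), abs(res$r), tolerance = 1e-12)
  # planted linear coupling recovered on average
  rhat <- numeric(500)
  set.seed(5)
  for (s in 1:500) {
    reading <- rnorm(44)
    feat <- 0.6 * reading + rnorm(44)
    rhat[s] <- cor(feat, reading)
  }
  rho <- 0.6 / sqrt(0.36 + 1)
  expect_lt(abs(mean(rhat) - rho), 0.02)
})

test_that("pairwise deletion records per-cell n", {
  coh <- toy_cohort(n_per_group = 10, n_rois = 2, d = 0, seed = 6)
  comp <- data.frame(reading = c(NA, rnorm(19)))
  res <- roi_behavior_correlations(coh$features, comp, roi_subset = 1:2)
  expect_true(all(res$n == 19))
})

test_that("Bonferroni threshold arithmetic and monotone flag counts", {
  expect_equal(bonferroni_threshold(1, 1, 1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(11, 5, 3, 0.05), 0.05 / 165)
  expect_equal(round(bonferroni_threshold(11, 5, 3, 0.05), 4), 3e-04)
  expect_equal(bonferroni_threshold(2, 2, 2, 0.04), 0.005)
  expect_error(bonferroni_threshold(0, 1, 1, 0.05))
  coh <- simulate_cohort(n_per_group = 22, n_rois = 6,
                         informative_rois = 1:3, effect_sizes = 1,
                         confound_effects = list(), seed = 7)
  comp <- data.frame(reading = coh$features[, 1, 1] + rnorm(44, sd = 0.5))
  small <- roi_behavior_correlations(coh$features, comp, roi_subset = 1:2)
  large <- roi_behavior_correlations(coh$features, comp, roi_subset = 1:6)
  n_small <- sum(small$significant)
  n_large_same_cells <- sum(large$significant[large$roi %in%
                                                c("roi001", "roi002")])
  expect_lte(n_large_same_cells, n_small)
})

test_that("the shipped summary fixture is complete and well formed", {
  tab <- table1_summary()
  expect_true(all(c("Age", "IQ", "IQ_Vocabulary", "IQ_BlockDesign",
                    "SNWR", "DSM_IV_I") %in% tab$measure))
  expect_true(all(tab$dd_sd >= 0 & tab$tr_sd >= 0))
  expect_equal(sum(!is.na(tab$dd_n)), 12)
})
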