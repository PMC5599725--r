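test_that("integration pattern metrics are exact on constructed maps", {
  roi <- 1:27
  dmap <- rep(1, 50)
  expect_equal(roi_size_metric(dmap, roi), 27)
  expect_equal(roi_size_metric(rep(0, 50), roi), 0)
  half <- c(rep(1, 13), rep(0, 37))
  expect_equal(roi_size_metric(half, 1:26), 13)
  expect_error(roi_size_metric(dmap, integer(0)), "empty")

  expect_equal(roi_meanfc_metric(rep(3.5, 50), roi), 3.5)
  expect_equal(roi_meanfc_metric(c(1, 2, 3, rep(99, 47)), 1:3), 2)
  fmap <- rnorm(50)
  fmap2 <- fmap; fmap2[40:50] <- 1e6
  expect_equal(roi_meanfc_metric(fmap, roi), roi_meanfc_metric(fmap2, roi))
})

test_that("group difference test equals the pooled-t oracle", {
  set.seed(42)
  x <- c(rnorm(12, 5), rnorm(15, 6))
  g <- c(rep("MHE", 12), rep("NMHE", 15))
  out <- group_difference_test(x, g)
  oracle <- t.test(x[g == "MHE"], x[g == "NMHE"], var.equal = TRUE)
  expect_equal(out$t, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(out$p, oracle$p.value, tolerance = 1e-9)

  same <- group_difference_test(rep(2, 10), rep(c("MHE", "NMHE"), 5))
  expect_true(same$degenerate)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("partial correlation matches Pearson and respects covariates", {
  set.seed(1)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-9)

  # y identical to a covariate: residual correlation vanishes
  z <- rnorm(30)
  pc0 <- partial_correlation(x, z, covariates = cbind(z))
  expect_lt(abs(pc0$r), 1e-10)

  expect_error(partial_correlation(x, y, cbind(z, z)), "rank")
  expect_error(partial_correlation(x[1:4], y[1:4], cbind(z[1:4], x[1:4])),
               "n >")
})

test_that("Bonferroni flags use the family-size-adjusted bound", {
  expect_true(bonferroni_flags(0.015, 3))
  expect_false(bonferroni_flags(0.02, 3))
  expect_true(bonferroni_flags(0.04, 1))
  expect_equal(bonferroni_flags(c(0.001, 0.02, 0.015), 3),
               c(TRUE, FALSE, TRUE))
})

test_that("the MHE diagnostic rule requires two impaired tests", {
  rec <- list(tmt_a = 70, tmt_b = 100, dst = 20, bdt = 20)
  expect_equal(diagnose_mhe(rec), "MHE")
  only_one <- list(tmt_a = 50, tmt_b = 160, dst = 30, bdt = 20)
  expect_equal(diagnose_mhe(only_one), "NMHE")
  all_bad <- list(tmt_a = 80, tmt_b = 200, dst = 10, bdt = 10)
  expect_equal(diagnose_mhe(all_bad), "MHE")
  # boundary values are not impaired (strict comparisons)
  at_cut <- list(tmt_a = 68, tmt_b = 156, dst = 23, bdt = 16)
  expect_equal(diagnose_mhe(at_cut), "NMHE")
  expect_error(diagnose_mhe(list(tmt_a = 70, tmt_b = NA, dst = 20,
                                 bdt = 20)), "missing")
})

test_that("2x2 chi-square matches the expected-counts oracle", {
  tab <- matrix(c(12, 8, 5, 15), 2, byrow = TRUE)
  out <- chi_square_2x2(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq_oracle <- sum((tab - expected)^2 / expected)
  expect_equal(out$chisq, chisq_oracle, tolerance = 1e-12)
  expect_equal(out$p, 1 - pchisq(chisq_oracle, 1), tolerance = 1e-12)

  sym <- matrix(c(4, 9, 4, 9), 2, byrow = TRUE)
  out_sym <- chi_square_2x2(sym)
  expect_equal(out_sym$chisq, 0)
  expect_equal(out_sym$p, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("summary t-test agrees with a raw-data t-test on matched data", {
  # construct samples with exact means and SDs
  mk <- function(n, m, s) {
    z <- scale(rnorm(n))
    as.numeric(m + s * z)
  }
  set.seed(9)
  x1 <- mk(42, 47.3, 16.9); x2 <- mk(32, 75.2, 19.8)
  out <- ttest_from_summary(47.3, 16.9, 42, 75.2, 19.8, 32)
  oracle <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(out$t, unname(oracle$statistic), tolerance = 1e-6)
  expect_equal(out$p, oracle$p.value, tolerance = 1e-6)
  expect_lt(out$p, 0.001)

  eq <- ttest_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  degen <- ttest_from_summary(3, 0, 5, 3, 0, 5)
  expect_equal(degen$p, 1)
})

test_that("ROI overlap counts shrink as the threshold rises", {
  fix <- tiny_cohort_zstack(seed = 42)
  roi <- fix$planted$voxels
  prev <- NULL
  for (thr in threshold_grid()) {
    n_ov <- integration_patterns(fix$Z, roi, thr)$n_overlap
    if (!is.null(prev)) expect_true(all(n_ov <= prev))
    prev <- n_ov
  }
})

test_that("biomarker evaluation recovers group differences and couplings", {
  fix <- tiny_cohort_zstack(seed = 42, n_mhe = 10, n_nmhe = 12,
                            coupling = 2)
  pat <- integration_patterns(fix$Z, fix$planted$voxels, 2)
  ev <- evaluate_biomarkers(list(ICN01 = pat), fix$records,
                            bonferroni_m = 3)
  gt <- ev$group_tests
  expect_equal(nrow(gt), 2)
  # planted deficit: MHE has fewer suprathreshold voxels and lower FC
  expect_lt(gt$mean_mhe[gt$pattern == "n_overlap"],
            gt$mean_nmhe[gt$pattern == "n_overlap"])
  expect_lt(gt$p[gt$pattern == "n_overlap"], 0.05)
  corr <- ev$correlations
  expect_equal(nrow(corr), 10)  # 2 patterns x 5 clinical scores
  cp <- corr[corr$clinical == "child_pugh" & corr$pattern == "mean_fc", ]
  expect_lt(cp$r, 0)
})

test_that("demographics tables report group summaries and tests", {
  fix <- tiny_cohort_zstack(seed = 42, n_mhe = 10, n_nmhe = 12)
  demo <- demographics_table(fix$records)
  expect_true(all(c("tmt_a", "child_pugh", "age") %in%
                    demo$characteristic))
  expect_true(all(demo$p >= 0 & demo$p <= 1))
  # strongly impaired scores separate the groups
  expect_lt(demo$p[demo$characteristic == "tmt_a"], 0.05)
})
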