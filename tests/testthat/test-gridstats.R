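# Synthetic complete grid builder: one row per (icn, thr, cls) cell.
synth_grid <- function(n_icn = 20, thresholds = threshold_grid(),
                       classifiers = c("SVM", "MLP", "TREE"),
                       fill = function(icn, thr, cls) 80) {
  rows <- expand.grid(icn = sprintf("ICN%02d", seq_len(n_icn)),
                      threshold = thresholds, classifier = classifiers,
                      stringsAsFactors = FALSE)
  rows$acc <- mapply(fill, rows$icn, rows$threshold, rows$classifier)
  rows$sen <- rows$acc
  rows$spe <- rows$acc
  rows
}

test_that("pairwise classifier tests match the closed-form paired t", {
  set.seed(42)
  vals <- matrix(rnorm(60, 85, 5), 20, 3)
  g <- synth_grid(fill = function(icn, thr, cls) {
    i <- as.integer(sub("ICN", "", icn))
    j <- match(cls, c("SVM", "MLP", "TREE"))
    vals[i, j]
  })
  out <- pairwise_classifier_tests(g)
  expect_equal(nrow(out), 9)  # 3 pairs x 3 metrics
  row <- out[out$metric == "acc" & out$pair == "SVM/MLP", ]
  d <- vals[, 1] - vals[, 2]
  t_oracle <- mean(d) / (sd(d) / sqrt(20))
  expect_equal(row$t, t_oracle, tolerance = 1e-9)
  expect_equal(row$p, 2 * pt(-abs(t_oracle), 19), tolerance = 1e-9)

  # identical classifiers -> degenerate flag, p = 1
  g_eq <- synth_grid(fill = function(icn, thr, cls)
    as.integer(sub("ICN", "", icn)))
  out_eq <- pairwise_classifier_tests(g_eq)
  expect_true(all(out_eq$degenerate))
  expect_true(all(out_eq$p == 1))
})

test_that("factorial ANOVA has the complete-grid df structure", {
  set.seed(7)
  g <- synth_grid(fill = function(icn, thr, cls) rnorm(1, 80, 5))
  av <- factorial_anova(g)
  tab <- av$acc
  df <- setNames(tab$df, tab$term)
  expect_equal(unname(df["THR"]), 8)
  expect_equal(unname(df["CLS"]), 2)
  expect_equal(unname(df["ICN"]), 19)
  expect_equal(unname(df["THR:CLS"]), 16)
  expect_equal(unname(df["THR:ICN"]), 152)
  expect_equal(unname(df["CLS:ICN"]), 38)

  # a pure threshold effect is detected and the null classifier is not
  g2 <- synth_grid(fill = function(icn, thr, cls) 10 * thr + rnorm(1))
  av2 <- factorial_anova(g2)$acc
  expect_lt(av2$p[av2$term == "THR"], 0.001)
  expect_gt(av2$p[av2$term == "CLS"], 0.05)

  # constant metric reports no effects
  g3 <- synth_grid()
  av3 <- factorial_anova(g3)$acc
  expect_true(all(av3$F == 0) && all(av3$p == 1))

  expect_error(factorial_anova(g[-1, ]), "incomplete")
})

test_that("df identities hold for any complete three-factor grid", {
  for (dims in list(c(4, 2, 3), c(5, 3, 2))) {
    g <- synth_grid(n_icn = dims[3],
                    thresholds = seq(1, by = 0.5, length.out = dims[1]),
                    classifiers = LETTERS[seq_len(dims[2])],
                    fill = function(icn, thr, cls) rnorm(1, 70, 4))
    tab <- factorial_anova(g)$acc
    df <- setNames(tab$df, tab$term)
    expect_equal(unname(df[c("THR", "CLS", "ICN")]), dims - 1)
    expect_equal(unname(df["THR:CLS"]), (dims[1] - 1) * (dims[2] - 1))
    expect_equal(unname(df["THR:ICN"]), (dims[1] - 1) * (dims[3] - 1))
    expect_equal(unname(df["CLS:ICN"]), (dims[2] - 1) * (dims[3] - 1))
  }
})

test_that("stability probabilities count strict exceedances out of 27", {
  g <- synth_grid(n_icn = 2, fill = function(icn, thr, cls) {
    if (icn == "ICN01") {
      # 24 of 27 cells above 85
      if (thr <= 1.5 && cls == "SVM") 80 else 90
    } else 85  # exactly at the cut: strict rule excludes all
  })
  stab <- stability_probability(g, acc_cut = 85)
  expect_equal(stab$probability[stab$icn == "ICN01"], 88.9)
  expect_equal(stab$n_cells[1], 27)
  expect_equal(stab$probability[stab$icn == "ICN02"], 0)

  g_all <- synth_grid(n_icn = 1, fill = function(...) 90)
  expect_equal(stability_probability(g_all)$probability, 100)

  # monotone non-increasing in the accuracy cut
  set.seed(3)
  g_r <- synth_grid(n_icn = 3, fill = function(...) runif(1, 60, 100))
  probs <- sapply(c(60, 70, 80, 90), function(ct)
    sum(stability_probability(g_r, ct)$probability))
  expect_true(all(diff(probs) <= 0))
})

test_that("representative selection applies the inclusive 70% cut", {
  stab <- data.frame(icn = c("TLN", "SCN", "SMN", "VN"),
                     n_pass = c(20, 19, 24, 17), n_cells = 27,
                     probability = c(74.1, 70.4, 88.9, 63.0))
  sel <- select_representative(stab, 70)
  expect_equal(sel, c("SMN", "TLN", "SCN"))
  expect_warning(empty <- select_representative(stab, 95), "no ICN")
  expect_length(empty, 0)
  expect_equal(sort(select_representative(stab, 0)), sort(stab$icn))
  # exact boundary is selected
  expect_true("SCN" %in% select_representative(stab, 70.4))
})

test_that("best thresholds return all co-optimal cells", {
  g_eq <- synth_grid(n_icn = 1, fill = function(...) 90)
  bt <- best_thresholds(g_eq, "ICN01")
  expect_setequal(unique(bt$threshold), threshold_grid())

  g_one <- synth_grid(n_icn = 1, fill = function(icn, thr, cls)
    ifelse(thr == 2 & cls == "TREE", 99, 80))
  bt1 <- best_thresholds(g_one, "ICN01")
  expect_equal(nrow(bt1), 1)
  expect_equal(bt1$threshold, 2)
  expect_equal(bt1$acc, 99)
  expect_error(best_thresholds(g_one, "ICN99"), "not present")
})

test_that("best-threshold metrics dominate the ICN's grid mean on planted data", {
  fix <- tiny_cohort_zstack(seed = 42)
  g <- run_grid(list(ICN01 = fix$Z), fix$records$group,
                thresholds = c(1.5, 2, 2.5), gamma_params(B = 99),
                k_folds = 7, seed = 3)
  bt <- best_thresholds(g, "ICN01")
  expect_gte(bt$acc[1], mean(g$acc))
})
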