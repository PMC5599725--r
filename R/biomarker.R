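# Evaluation of discovered ROIs against clinical variables, plus the
# clinical-side computations (MHE diagnostic rule, demographics tests).

#' Size integration pattern: suprathreshold voxels within an ROI
#'
#' Number of voxels of a subject's binarized high-connectivity map that
#' fall inside the ROI.
#'
#' @param dmap Binary map (array or vector) for one subject.
#' @param roi Non-empty vector of linear voxel indices.
#' @return Integer count in 0..|ROI|.
#' @export
roi_size_metric <- function(dmap, roi) {
  if (length(roi) == 0) stop("empty ROI")
  sum(dmap[roi] == 1)
}

#' FC integration pattern: mean connectivity within an ROI
#'
#' Arithmetic mean of the subject's unthresholded z map over the ROI
#' voxels.
#'
#' @param fmap Numeric z map (array or vector) for one subject.
#' @param roi Non-empty vector of linear voxel indices.
#' @return Scalar mean connectivity.
#' @export
roi_meanfc_metric <- function(fmap, roi) {
  if (length(roi) == 0) stop("empty ROI")
  mean(fmap[roi])
}

#' Integration patterns for all subjects of one ROI
#'
#' @param Z Subjects x voxels z matrix for the ICN ([stack_zmaps()]).
#' @param roi Linear voxel indices of the ROI.
#' @param threshold z threshold defining the high-connectivity maps.
#' @return `data.frame` with subject_id, n_overlap and mean_fc.
#' @export
integration_patterns <- function(Z, roi, threshold) {
  S <- discretize_zmap(Z, threshold)
  data.frame(
    subject_id = if (!is.null(rownames(Z))) rownames(Z)
                 else sprintf("sub%03d", seq_len(nrow(Z))),
    n_overlap = as.integer(rowSums(S[, roi, drop = FALSE])),
    mean_fc = rowMeans(Z[, roi, drop = FALSE]))
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided t-test with pooled variance, flagged degenerate (t = 0,
#' p = 1) when the pooled variance is zero.
#'
#' @param values Numeric vector.
#' @param group Class labels aligned with `values`.
#' @return List with `t`, `df`, `p`, `mean_mhe`, `mean_nmhe`, `degenerate`.
#' @export
group_difference_test <- function(values, group) {
  y <- normalize_group(group)
  x1 <- values[y == "MHE"]; x2 <- values[y == "NMHE"]
  if (length(x1) < 2 || length(x2) < 2) stop("need >= 2 per group")
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    degen <- TRUE
    tval <- if (mean(x1) == mean(x2)) 0 else Inf * sign(mean(x1) - mean(x2))
    p <- if (mean(x1) == mean(x2)) 1 else 0
  } else {
    degen <- FALSE
    tval <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tval), n1 + n2 - 2)
  }
  list(t = tval, df = n1 + n2 - 2, p = p, mean_mhe = mean(x1),
       mean_nmhe = mean(x2), degenerate = degen)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after ordinary
#' least squares on the covariates (intercept included). The p-value comes
#' from the t distribution with n - k - 2 degrees of freedom, k the number
#' of covariates. With no covariates this is the plain Pearson
#' correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix / data.frame (n rows).
#' @return List with `r`, `df`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    k <- 0
    rx <- x - mean(x); ry <- y - mean(y)
  } else {
    Z <- as.matrix(covariates)
    storage.mode(Z) <- "double"
    k <- ncol(Z)
    if (n <= k + 2) stop("need n > #covariates + 2")
    X <- cbind(1, Z)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
    rx <- lm.fit(X, x)$residuals
    ry <- lm.fit(X, y)$residuals
  }
  # residual sums of squares that vanish relative to the inputs mean the
  # variable is explained by the covariates: define r = 0 there
  tol <- .Machine$double.eps^0.75
  if (sum(rx^2) <= tol * sum((x - mean(x))^2) ||
      sum(ry^2) <= tol * sum((y - mean(y))^2)) {
    return(list(r = 0, df = n - k - 2, p = 1))
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  dfree <- n - k - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(dfree / (1 - r^2))
    p <- 2 * pt(-abs(tval), dfree)
  }
  list(r = r, df = dfree, p = p)
}

#' Bonferroni significance flags
#'
#' @param pvals Numeric vector of p-values.
#' @param m Family size (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector: `p <= alpha / m`.
#' @export
bonferroni_flags <- function(pvals, m, alpha = 0.05) {
  stopifnot(m >= 1)
  pvals <= alpha / m
}

#' Clinical cutoffs for the MHE diagnostic rule
#'
#' Impairment cutoffs two standard deviations beyond normative
#' performance: TMT-A > 68 s, TMT-B > 156 s, DST < 23, BDT < 16; MHE
#' requires impairment on at least `n_required` of the four tests.
#'
#' @param tmt_a_max,tmt_b_max,dst_min,bdt_min Cutoff values.
#' @param n_required Minimum number of impaired tests (1..4).
#' @return Named list of class `clinical_cutoffs`.
#' @export
clinical_cutoffs <- function(tmt_a_max = 68, tmt_b_max = 156, dst_min = 23,
                             bdt_min = 16, n_required = 2) {
  stopifnot(tmt_a_max > 0, tmt_b_max > 0, dst_min > 0, bdt_min > 0,
            n_required %in% 1:4)
  structure(list(tmt_a_max = tmt_a_max, tmt_b_max = tmt_b_max,
                 dst_min = dst_min, bdt_min = bdt_min,
                 n_required = n_required), class = "clinical_cutoffs")
}

#' Apply the MHE diagnostic rule to one subject record
#'
#' @param record List or one-row data.frame with fields `tmt_a`, `tmt_b`,
#'   `dst`, `bdt`.
#' @param cutoffs A [clinical_cutoffs()] list.
#' @return `"MHE"` or `"NMHE"`.
#' @export
diagnose_mhe <- function(record, cutoffs = clinical_cutoffs()) {
  need <- c("tmt_a", "tmt_b", "dst", "bdt")
  vals <- lapply(need, function(f) record[[f]])
  if (any(vapply(vals, function(v) is.null(v) || is.na(v), TRUE)))
    stop("missing neuropsychological score(s)")
  impaired <- c(record$tmt_a > cutoffs$tmt_a_max,
                record$tmt_b > cutoffs$tmt_b_max,
                record$dst < cutoffs$dst_min,
                record$bdt < cutoffs$bdt_min)
  if (sum(impaired) >= cutoffs$n_required) "MHE" else "NMHE"
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Without continuity correction, df = 1, two-sided.
#'
#' @param table 2 x 2 matrix of non-negative counts with positive margins.
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in contingency table")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  chisq <- sum((table - expected)^2 / expected)
  list(chisq = chisq, df = 1, p = 1 - pchisq(chisq, 1))
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sided t-test computed from group means, SDs and
#' sizes (the form reproducible from published demographics tables). When
#' both SDs are zero: p = 1 for equal means, p = 0 otherwise.
#'
#' @param m1,s1,n1 Mean, SD, size of group 1.
#' @param m2,s2,n2 Mean, SD, size of group 2.
#' @return List with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  dfree <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / dfree
  if (sp2 == 0) {
    if (m1 == m2) return(list(t = 0, df = dfree, p = 1))
    return(list(t = Inf * sign(m1 - m2), df = dfree, p = 0))
  }
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = dfree, p = 2 * pt(-abs(tval), dfree))
}

#' Demographics comparison table
#'
#' Group means +/- SD and pooled-t p-values for continuous clinical
#' characteristics, plus a chi-square p for gender, from a subject table.
#'
#' @param records Subject `data.frame` with a `group` column.
#' @param continuous Character vector of continuous columns to compare.
#' @return `data.frame` with characteristic, group summaries, test and p.
#' @export
demographics_table <- function(records,
                               continuous = c("age", "education", "tmt_a",
                                              "tmt_b", "dst", "bdt",
                                              "child_pugh")) {
  y <- normalize_group(records$group)
  rows <- lapply(continuous, function(v) {
    x1 <- records[[v]][y == "MHE"]; x2 <- records[[v]][y == "NMHE"]
    tt <- ttest_from_summary(mean(x2), sd(x2), length(x2),
                             mean(x1), sd(x1), length(x1))
    data.frame(characteristic = v,
               nmhe = sprintf("%.1f ± %.1f", mean(x2), sd(x2)),
               mhe = sprintf("%.1f ± %.1f", mean(x1), sd(x1)),
               test = "t", p = tt$p)
  })
  if ("gender" %in% names(records)) {
    tab <- table(records$gender, y)
    if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0)) {
      cs <- chi_square_2x2(tab)
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = "gender",
        nmhe = paste(tab[, "NMHE"], collapse = "/"),
        mhe = paste(tab[, "MHE"], collapse = "/"),
        test = "chisq", p = cs$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate discovered biomarkers against clinical variables
#'
#' For each (ICN, ROI) the two integration patterns (ROI-overlap voxel
#' count and mean FC) are tested for group differences (pooled t) and
#' partially correlated with each clinical score, controlling for
#' movement, age, gender and education. Bonferroni correction is applied
#' per clinical measure and pattern across the `m` ICNs in the family.
#'
#' @param patterns Named list (per ICN) of [integration_patterns()]
#'   data.frames.
#' @param records Subject table aligned with the pattern rows.
#' @param clinical Character vector of clinical score columns.
#' @param covariates Character vector of covariate columns; `gender` is
#'   encoded 0/1.
#' @param bonferroni_m Family size for the correction (default: number of
#'   ICNs in `patterns`).
#' @param alpha Significance level.
#' @return List with `group_tests` and `correlations` data.frames.
#' @export
evaluate_biomarkers <- function(patterns, records,
                                clinical = c("tmt_a", "tmt_b", "dst",
                                             "bdt", "child_pugh"),
                                covariates = c("movement", "age", "gender",
                                               "education"),
                                bonferroni_m = length(patterns),
                                alpha = 0.05) {
  y <- normalize_group(records$group)
  Zc <- records[covariates]
  if ("gender" %in% covariates)
    Zc$gender <- as.numeric(factor(Zc$gender)) - 1
  Zc <- as.matrix(data.frame(lapply(Zc, as.numeric)))
  # constant covariates (e.g. single-gender cohorts) carry no information
  Zc <- Zc[, apply(Zc, 2, stats::var) > 0, drop = FALSE]
  gt <- list(); corr <- list()
  for (icn in names(patterns)) {
    pat <- patterns[[icn]]
    for (measure in c("n_overlap", "mean_fc")) {
      v <- pat[[measure]]
      tt <- group_difference_test(v, records$group)
      gt[[length(gt) + 1]] <- data.frame(
        icn = icn, pattern = measure,
        mean_mhe = tt$mean_mhe, sd_mhe = sd(v[y == "MHE"]),
        mean_nmhe = tt$mean_nmhe, sd_nmhe = sd(v[y == "NMHE"]),
        t = tt$t, p = tt$p)
      for (cl in clinical) {
        pc <- partial_correlation(v, as.numeric(records[[cl]]), Zc)
        corr[[length(corr) + 1]] <- data.frame(
          icn = icn, pattern = measure, clinical = cl,
          r = pc$r, p = pc$p)
      }
    }
  }
  gt <- do.call(rbind, gt)
  corr <- do.call(rbind, corr)
  corr$significant <- bonferroni_flags(corr$p, bonferroni_m, alpha)
  rownames(gt) <- rownames(corr) <- NULL
  list(group_tests = gt, correlations = corr,
       bonferroni_m = bonferroni_m, alpha = alpha)
}
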