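# ROI-state features and cross-validated classifier evaluation over the
# ICN x threshold grid.

#' Extract ROI-state features from a fitted GAMMA model
#'
#' @param model A `gamma_model` with at least one validated ROI.
#' @param S Subjects x voxels binary matrix at the model's threshold.
#' @return Subjects x ROIs binary matrix; columns named `roi1`, `roi2`, ...
#'   A model with zero validated ROIs raises an error of class
#'   `icnmhe_empty_features`; grid code catches it and records the
#'   majority-class baseline.
#' @export
extract_features <- function(model, S) {
  stopifnot(inherits(model, "gamma_model"))
  if (model$n_validated < 1) {
    stop(structure(class = c("icnmhe_empty_features", "error", "condition"),
                   list(message = "model has no validated ROIs",
                        call = sys.call())))
  }
  F <- vapply(model$rois, function(roi)
    roi_states_matrix(S, roi, model$params$tau), integer(nrow(S)))
  F <- matrix(F, nrow = nrow(S))
  colnames(F) <- paste0("roi", seq_len(ncol(F)))
  rownames(F) <- rownames(S)
  F
}

# Stratified fold assignment: shuffle within class, deal round-robin.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

train_predict <- function(kind, x_train, y_train, x_test, seed) {
  # Degenerate training features: fall back to the majority class.
  if (ncol(x_train) == 0 || all(apply(x_train, 2, var) == 0)) {
    maj <- names(which.max(table(y_train)))
    return(factor(rep(maj, nrow(x_test)), levels = levels(y_train)))
  }
  train_df <- data.frame(x_train)
  test_df <- data.frame(x_test)
  colnames(test_df) <- colnames(train_df)
  train_df$.y <- y_train
  if (kind == "TREE") {
    fit <- rpart::rpart(.y ~ ., data = train_df, method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(
                          minsplit = 4, minbucket = 2, cp = 0.01,
                          xval = 0))
    predict(fit, test_df, type = "class")
  } else if (kind == "SVM") {
    fit <- e1071::svm(.y ~ ., data = train_df, kernel = "polynomial",
                      degree = 1, coef0 = 0, cost = 1, scale = FALSE)
    predict(fit, test_df)
  } else if (kind == "MLP") {
    with_seed(seed, {
      fit <- nnet::nnet(.y ~ ., data = train_df,
                        size = max(1, (ncol(x_train) + 2) %/% 2),
                        decay = 0.01, maxit = 200, trace = FALSE)
    })
    factor(predict(fit, test_df, type = "class"), levels = levels(y_train))
  } else {
    stop("unknown classifier kind: ", kind)
  }
}

#' Cross-validated classification metrics
#'
#' Stratified k-fold cross-validation with predictions pooled over folds.
#' The positive class is MHE: sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP), accuracy = (TP + TN) / n, all in percent.
#'
#' @param features Subjects x features numeric matrix (binary ROI states).
#' @param labels Class labels (MHE/NMHE or logical, TRUE = MHE).
#' @param kind One of `"SVM"`, `"MLP"`, `"TREE"`.
#' @param k_folds Number of folds (default 10).
#' @param seed Integer seed governing fold assignment and classifier
#'   initialisation.
#' @return Named numeric vector `c(acc, sen, spe)` in percent.
#' @export
crossval_metrics <- function(features, labels, kind = "TREE", k_folds = 10,
                             seed = 1) {
  kind <- toupper(kind)
  if (!kind %in% c("SVM", "MLP", "TREE"))
    stop("unknown classifier kind: ", kind)
  y <- if (is.logical(labels)) factor(ifelse(labels, "MHE", "NMHE"),
                                      levels = c("NMHE", "MHE"))
       else normalize_group(labels)
  features <- as.matrix(features)
  n <- length(y)
  stopifnot(n >= k_folds, nrow(features) == n, nlevels(droplevels(y)) == 2)
  fold <- stratified_folds(y, k_folds, derive_seed(seed, 11))
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    pred[te] <- train_predict(kind, features[tr, , drop = FALSE], y[tr],
                              features[te, , drop = FALSE],
                              derive_seed(seed, 13, f))
  }
  confusion_metrics(pred, y)
}

confusion_metrics <- function(pred, y) {
  tp <- sum(pred == "MHE" & y == "MHE")
  tn <- sum(pred == "NMHE" & y == "NMHE")
  fp <- sum(pred == "MHE" & y == "NMHE")
  fn <- sum(pred == "NMHE" & y == "MHE")
  c(acc = 100 * (tp + tn) / length(y),
    sen = 100 * tp / (tp + fn),
    spe = 100 * tn / (tn + fp))
}

# Metrics of the always-majority classifier, used for grid cells where
# GAMMA validates zero ROIs (keeps the factorial grid complete).
baseline_metrics <- function(labels) {
  y <- if (is.logical(labels)) factor(ifelse(labels, "MHE", "NMHE"),
                                      levels = c("NMHE", "MHE"))
       else normalize_group(labels)
  maj <- names(which.max(table(y)))
  pred <- factor(rep(maj, length(y)), levels = levels(y))
  confusion_metrics(pred, y)
}

#' Run the full ICN x threshold x classifier performance grid
#'
#' For every (ICN, threshold) cell: binarize the z maps, fit GAMMA,
#' extract ROI-state features and evaluate each classifier with stratified
#' 10-fold cross-validation. Cells where GAMMA validates no ROI (or any
#' cell-level failure) are recorded as the majority-class baseline with a
#' warning, so the factorial grid stays complete for the ANOVA stage.
#'
#' @param zstacks Named list, one subjects x voxels z matrix per ICN (see
#'   [stack_zmaps()]).
#' @param labels Class labels, one per subject.
#' @param thresholds Numeric vector of z thresholds (default
#'   [threshold_grid()]).
#' @param params A [gamma_params()] list.
#' @param classifiers Character vector of classifier kinds.
#' @param k_folds Cross-validation folds.
#' @param seed Master seed; each cell's permutation and fold streams are
#'   derived from it, so reruns are identical.
#' @return `data.frame` of class `performance_grid` with columns icn,
#'   threshold, classifier, acc, sen, spe, n_rois.
#' @export
run_grid <- function(zstacks, labels, thresholds = threshold_grid(),
                     params = gamma_params(),
                     classifiers = c("SVM", "MLP", "TREE"), k_folds = 10,
                     seed = 1) {
  stopifnot(length(zstacks) >= 1, !is.null(names(zstacks)))
  y <- if (is.logical(labels)) labels else normalize_group(labels) == "MHE"
  rows <- list()
  for (ik in seq_along(zstacks)) {
    icn <- names(zstacks)[ik]
    Z <- zstacks[[ik]]
    for (thr in thresholds) {
      S <- discretize_zmap(Z, thr)
      attr(S, "grid_shape") <- attr(Z, "grid_shape")
      cell_seed <- derive_seed(seed, ik, round(100 * thr))
      metrics <- tryCatch({
        model <- fit_gamma(S, y, params, seed = cell_seed,
                           icn = icn, threshold = thr)
        feats <- extract_features(model, S)
        lapply(classifiers, function(cl)
          c(crossval_metrics(feats, y, cl, k_folds,
                             seed = derive_seed(cell_seed, match(cl, classifiers))),
            n_rois = model$n_validated))
      }, error = function(e) {
        if (!inherits(e, "icnmhe_empty_features"))
          warning(sprintf("grid cell (%s, %.2f) failed (%s); recording baseline",
                          icn, thr, conditionMessage(e)), call. = FALSE)
        base <- baseline_metrics(y)
        lapply(classifiers, function(cl) c(base, n_rois = 0))
      })
      for (j in seq_along(classifiers)) {
        m <- metrics[[j]]
        rows[[length(rows) + 1]] <- data.frame(
          icn = icn, threshold = thr, classifier = classifiers[j],
          acc = unname(m["acc"]), sen = unname(m["sen"]),
          spe = unname(m["spe"]), n_rois = unname(m["n_rois"]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("performance_grid", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "k_folds") <- k_folds
  out
}
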