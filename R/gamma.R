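# GAMMA: graphical-model-based multivariate analysis. From binarized
# z-maps and a two-class clinical variable, find discriminative ROIs by
# maximizing a Bayesian Dirichlet score, with similarity-based region
# growing and an embedded permutation validation step.

#' Default z-threshold ladder
#'
#' Nine voxelwise z thresholds from 1 to 3 in steps of 0.25, applied to
#' subject z-score maps before GAMMA.
#'
#' @return Numeric vector of 9 strictly increasing thresholds.
#' @export
threshold_grid <- function() seq(1, 3, by = 0.25)

#' GAMMA parameter set
#'
#' @param alpha_ess Equivalent sample size of the Dirichlet prior; the
#'   default 2 puts a uniform Dirichlet(1, 1) on the class distribution
#'   within each ROI state.
#' @param kappa_sim Minimum across-subject agreement (Hamming similarity)
#'   with the representative voxel for a voxel to join its ROI; must be in
#'   (0.5, 1].
#' @param tau Majority fraction for the ROI state (default 0.5, with >= at
#'   the boundary).
#' @param smoothing Add-count for the conditional probability table.
#' @param B Number of label permutations in the validation step.
#' @param alpha Validation level; a candidate ROI with permutation
#'   p >= alpha stops the search.
#' @param max_rois Maximum number of ROIs extracted per model.
#' @param z_cap Cap used when z maps were built (metadata).
#' @return Named list of class `gamma_params`.
#' @export
gamma_params <- function(alpha_ess = 2, kappa_sim = 0.9, tau = 0.5,
                         smoothing = 1, B = 199, alpha = 0.05,
                         max_rois = 5, z_cap = 10) {
  stopifnot(alpha_ess > 0, kappa_sim > 0.5, kappa_sim <= 1,
            tau > 0, tau <= 1, smoothing >= 0, B >= 99,
            alpha > 0, alpha < 1, max_rois >= 1)
  structure(list(alpha_ess = alpha_ess, kappa_sim = kappa_sim, tau = tau,
                 smoothing = smoothing, B = as.integer(B), alpha = alpha,
                 max_rois = as.integer(max_rois), z_cap = z_cap),
            class = "gamma_params")
}

#' Binarize a z map at a threshold
#'
#' A voxel is labelled 1 (high connectivity) iff its z-score is strictly
#' larger than the threshold, 0 otherwise. The result is the subject's
#' high-connectivity map D at that threshold.
#'
#' @param z 3-D numeric array (or vector/matrix) of z-scores.
#' @param thr Finite z threshold.
#' @return Integer array of the same shape with values in \{0, 1\}.
#' @export
discretize_zmap <- function(z, thr) {
  stopifnot(is.finite(thr))
  out <- (z > thr) + 0L
  if (!is.null(dim(z))) dim(out) <- dim(z)
  out
}

# Vectorized BD score over many candidate state columns.
# S: n x V binary matrix; y: logical (TRUE = MHE). Returns length-V scores.
bd_score_columns <- function(S, y, alpha_ess = 2) {
  a <- alpha_ess / 2           # Dirichlet count per (state, class) cell
  A <- alpha_ess               # prior mass per state
  n_pos <- sum(y); n_neg <- sum(!y)
  n1 <- colSums(S[y, , drop = FALSE])        # positives in state 1
  m1 <- colSums(S[!y, , drop = FALSE])       # negatives in state 1
  f <- function(u, v) {
    lgamma(A) - lgamma(A + u + v) +
      lgamma(a + u) - lgamma(a) + lgamma(a + v) - lgamma(a)
  }
  f(n1, m1) + f(n_pos - n1, n_neg - m1)
}

#' Bayesian Dirichlet score of class given a binary state
#'
#' Log marginal likelihood of the class labels under a model in which the
#' class depends on the binary state, with a Dirichlet prior of equivalent
#' sample size `alpha_ess` on the class distribution within each state
#' (each (state, class) cell gets count `alpha_ess / 2`). Equals the log
#' of the product of sequential predictive probabilities (Polya urn) run
#' separately within each state.
#'
#' @param states Binary vector over subjects (0/1).
#' @param labels Class labels; anything [normalize_group()] accepts, or a
#'   logical vector (TRUE = positive class).
#' @param alpha_ess Prior equivalent sample size (> 0).
#' @return Scalar log score (always negative).
#' @export
log_bd_score <- function(states, labels, alpha_ess = 2) {
  states <- as.integer(states)
  if (!all(states %in% c(0L, 1L))) stop("states must be binary")
  y <- if (is.logical(labels)) labels else normalize_group(labels) == "MHE"
  if (length(states) != length(y) || length(y) < 2)
    stop("states and labels must have equal length n >= 2")
  if (length(unique(y)) < 2)
    stop("degenerate labels: only one class present")
  as.numeric(bd_score_columns(matrix(states, ncol = 1), y, alpha_ess))
}

#' Grow an ROI around a representative voxel
#'
#' Candidate voxels are those whose across-subject binary vector agrees
#' with the representative voxel's in at least a fraction `kappa_sim` of
#' subjects (Hamming similarity). The ROI is the 26-connected component of
#' the candidate set containing the representative voxel.
#'
#' @param rep_voxel Linear voxel index (1-based, x-fastest).
#' @param S Subjects x voxels binary matrix with attribute `grid_shape`
#'   (or pass `grid_shape`).
#' @param kappa_sim Similarity cutoff in (0.5, 1].
#' @param grid_shape Integer triple if not carried by `S`.
#' @param allowed Optional logical vector over voxels restricting the
#'   candidate set (used to keep ROIs disjoint).
#' @return Sorted integer vector of linear voxel indices.
#' @export
grow_roi <- function(rep_voxel, S, kappa_sim = 0.9, grid_shape = NULL,
                     allowed = NULL) {
  if (is.null(grid_shape)) grid_shape <- attr(S, "grid_shape")
  stopifnot(!is.null(grid_shape), kappa_sim > 0.5, kappa_sim <= 1,
            rep_voxel >= 1, rep_voxel <= ncol(S))
  sim <- colMeans(S == S[, rep_voxel])
  cand <- sim >= kappa_sim
  if (!is.null(allowed)) cand <- cand & allowed
  cand[rep_voxel] <- TRUE
  cand_arr <- array(cand, dim = grid_shape)
  connected_component26(cand_arr, as.integer(rep_voxel))
}

#' ROI state of one subject
#'
#' The ROI-level binary feature: 1 iff the mean of the subject's binary
#' map over the ROI voxels is at least `tau` (ties count as 1).
#'
#' @param map Binary map (array or vector) for one subject.
#' @param roi Non-empty vector of linear voxel indices.
#' @param tau Majority fraction (default 0.5).
#' @return 0 or 1.
#' @export
roi_state <- function(map, roi, tau = 0.5) {
  if (length(roi) == 0) stop("empty ROI")
  as.integer(mean(map[roi]) >= tau)
}

roi_states_matrix <- function(S, roi, tau = 0.5) {
  if (length(roi) == 0) stop("empty ROI")
  as.integer(rowMeans(S[, roi, drop = FALSE]) >= tau)
}

#' Conditional probability table for class given ROI state
#'
#' `P(class = c | state = j) = (N_jc + s) / (N_j + 2 s)` with add-count
#' smoothing `s` (default 1).
#'
#' @param states Binary vector over subjects.
#' @param labels Class labels (see [log_bd_score()]).
#' @param smoothing Non-negative add-count.
#' @return 2 x 2 matrix, rows = state 0/1, columns = NMHE/MHE; rows sum
#'   to 1.
#' @export
build_cpt <- function(states, labels, smoothing = 1) {
  stopifnot(smoothing >= 0)
  y <- if (is.logical(labels)) labels else normalize_group(labels) == "MHE"
  states <- as.integer(states)
  cpt <- matrix(NA_real_, 2, 2,
                dimnames = list(state = c("0", "1"),
                                class = c("NMHE", "MHE")))
  for (j in 0:1) {
    n_mhe <- sum(states == j & y)
    n_nmhe <- sum(states == j & !y)
    tot <- n_mhe + n_nmhe + 2 * smoothing
    if (tot == 0) {
      cpt[j + 1, ] <- c(0.5, 0.5)
    } else {
      cpt[j + 1, ] <- c(n_nmhe + smoothing, n_mhe + smoothing) / tot
    }
  }
  cpt
}

# Max voxel-level BD score over `mask_idx` for each of B permuted label
# vectors. Returns length-B vector. Vectorized as one crossprod.
perm_max_scores <- function(S, y, mask_idx, B, alpha_ess, seed) {
  n <- nrow(S)
  Y <- with_seed(seed, {
    vapply(seq_len(B), function(b) sample(y), logical(n))
  })
  Sm <- S[, mask_idx, drop = FALSE]
  tot1 <- colSums(Sm)                       # state-1 count per voxel
  N1 <- crossprod(Sm, Y + 0)                # V x B: positives in state 1
  M1 <- tot1 - N1                           # negatives in state 1
  n_pos <- colSums(Y); n_neg <- n - n_pos
  a <- alpha_ess / 2; A <- alpha_ess
  f <- function(u, v) {
    lgamma(A) - lgamma(A + u + v) +
      lgamma(a + u) - lgamma(a) + lgamma(a + v) - lgamma(a)
  }
  sc <- f(N1, M1) +
    f(sweep(-N1, 2, n_pos, "+"), sweep(-M1, 2, n_neg, "+"))
  apply(sc, 2, max)
}

#' Permutation validation of a candidate model score
#'
#' Estimates how often a label permutation could produce a representative
#' voxel at least as good as the observed model: each permutation reruns
#' the voxelwise score search over the current mask, and
#' `p = (1 + #\{best permuted score >= observed\}) / (B + 1)`. A model
#' with `p >= alpha` is considered a potential statistical artifact.
#'
#' @param observed_score Observed log BD score to beat.
#' @param S Subjects x voxels binary matrix.
#' @param labels Class labels.
#' @param mask_idx Integer indices of voxels searched.
#' @param B Number of permutations (>= 99).
#' @param alpha_ess Prior equivalent sample size.
#' @param seed Integer seed for the permutation stream.
#' @return Permutation p-value in (0, 1].
#' @export
validate_model <- function(observed_score, S, labels, mask_idx = NULL,
                           B = 199, alpha_ess = 2, seed = 1) {
  stopifnot(B >= 99)
  y <- if (is.logical(labels)) labels else normalize_group(labels) == "MHE"
  if (is.null(mask_idx)) mask_idx <- seq_len(ncol(S))
  pm <- perm_max_scores(S, y, mask_idx, B, alpha_ess, seed)
  (1 + sum(pm >= observed_score)) / (B + 1)
}

#' Fit a GAMMA model
#'
#' Iteratively (1) scores every in-mask voxel's binary state vector
#' against the class labels with the Bayesian Dirichlet score, (2) takes
#' the arg-max voxel as representative (ties broken by smallest linear
#' index), (3) grows its ROI by vector similarity and 26-connectivity,
#' (4) rescores the majority-vote ROI state and validates the candidate by
#' label permutation — the observed statistic is the representative
#' voxel's score, matched to the permutation statistic (max voxel score
#' over the same mask) so the p-value stays calibrated — and (5) masks out
#' the ROI and repeats. The search stops at the first candidate failing
#' validation or after `max_rois` ROIs.
#'
#' @param S Subjects x voxels binary matrix with attribute `grid_shape`
#'   (see [stack_zmaps()] + [discretize_zmap()]), or a list of per-subject
#'   binary 3-D arrays.
#' @param labels Class labels, one per subject (MHE/NMHE or logical).
#' @param params A [gamma_params()] list.
#' @param mask Optional logical vector/array over voxels restricting the
#'   search; default: voxels where at least one subject is 1.
#' @param seed Integer seed for the permutation stream.
#' @param icn,threshold Optional metadata stored in the model.
#' @return Object of class `gamma_model`: list with `rois` (list of sorted
#'   linear voxel indices), `representative_voxels`, `cpts`, `scores`,
#'   `pvalues`, `log_bd` and `validation_p` (of the first ROI, or of the
#'   failed first candidate when no ROI validates), `n_validated`, plus
#'   `params`, `grid_shape`, `icn`, `threshold`.
#' @export
fit_gamma <- function(S, labels, params = gamma_params(), mask = NULL,
                      seed = 1, icn = NA, threshold = NA) {
  if (is.list(S) && !is.matrix(S)) {
    gs <- dim(S[[1]])
    S <- do.call(rbind, lapply(S, as.vector))
    attr(S, "grid_shape") <- gs
  }
  grid_shape <- attr(S, "grid_shape")
  if (is.null(grid_shape)) stop("S must carry a grid_shape attribute")
  y <- if (is.logical(labels)) labels else normalize_group(labels) == "MHE"
  if (length(y) != nrow(S)) stop("one label per subject required")
  if (sum(y) < 2 || sum(!y) < 2) stop("need >= 2 subjects per class")
  live <- if (is.null(mask)) colSums(S) > 0 else as.vector(mask)
  if (!any(live)) stop("empty analysis mask")
  rois <- list(); reps <- integer(); cpts <- list()
  scores <- numeric(); pvals <- numeric()
  first_p <- NA_real_
  for (r in seq_len(params$max_rois)) {
    idx <- which(live)
    if (length(idx) == 0) break
    vox_scores <- bd_score_columns(S[, idx, drop = FALSE], y,
                                   params$alpha_ess)
    rep_vox <- idx[which.max(vox_scores)]   # ties -> smallest linear index
    obs_vox <- max(vox_scores)
    roi <- grow_roi(rep_vox, S, params$kappa_sim, grid_shape,
                    allowed = live)
    st <- roi_states_matrix(S, roi, params$tau)
    obs <- log_bd_score(st, y, params$alpha_ess)
    # Validation compares the observed best voxel score against the same
    # statistic (max voxel score over the same mask) under permuted
    # labels: identical statistics on both sides keep the permutation
    # p-value calibrated under the null.
    p <- validate_model(obs_vox, S, y, mask_idx = idx, B = params$B,
                        alpha_ess = params$alpha_ess,
                        seed = derive_seed(seed, 101, r))
    if (r == 1) first_p <- p
    if (p >= params$alpha) break
    rois[[length(rois) + 1]] <- roi
    reps <- c(reps, rep_vox)
    cpts[[length(cpts) + 1]] <- build_cpt(st, y, params$smoothing)
    scores <- c(scores, obs)
    pvals <- c(pvals, p)
    live[roi] <- FALSE
  }
  structure(list(rois = rois, representative_voxels = reps, cpts = cpts,
                 scores = scores, pvalues = pvals,
                 log_bd = if (length(scores)) scores[1] else NA_real_,
                 validation_p = if (length(pvals)) pvals[1] else first_p,
                 n_validated = length(rois), params = params,
                 grid_shape = grid_shape, icn = icn, threshold = threshold),
            class = "gamma_model")
}

#' @export
print.gamma_model <- function(x, ...) {
  cat(sprintf(
    "GAMMA model (icn=%s, thr=%s): %d validated ROI(s)\n",
    as.character(x$icn), as.character(x$threshold), x$n_validated))
  if (x$n_validated > 0) {
    for (i in seq_len(x$n_validated)) {
      cat(sprintf("  ROI %d: %d voxels, logBD=%.3f, p=%.4f\n", i,
                  length(x$rois[[i]]), x$scores[i], x$pvalues[i]))
    }
  } else {
    cat(sprintf("  first candidate p=%.4f (not validated)\n",
                x$validation_p))
  }
  invisible(x)
}

#' Serialize a GAMMA model to JSON
#'
#' ROIs are written as 0-based (x, y, z) voxel triples so the file is
#' readable outside R.
#'
#' @param model A `gamma_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gamma_model <- function(model, path) {
  rois0 <- lapply(model$rois, function(r) {
    unname(as.data.frame(arrayInd(r, model$grid_shape) - 1L))
  })
  obj <- list(icn = model$icn, threshold = model$threshold,
              n_validated = model$n_validated,
              rois_xyz0 = rois0,
              representative_voxels_xyz0 =
                if (length(model$representative_voxels))
                  as.data.frame(arrayInd(model$representative_voxels,
                                         model$grid_shape) - 1L)
                else list(),
              cpts = model$cpts, scores = model$scores,
              pvalues = model$pvalues, log_bd = model$log_bd,
              validation_p = model$validation_p,
              params = unclass(model$params),
              grid_shape = model$grid_shape)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
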