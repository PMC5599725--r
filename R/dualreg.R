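# Two-stage dual regression: template maps -> subject time courses
# (spatial regression) -> subject beta/z maps (temporal regression).

#' Analysis mask from a template set
#'
#' Union of the template supports, dilated by `dilate` voxels with
#' 26-connectivity. Voxels outside the mask are excluded from both
#' regression stages and receive z = 0.
#'
#' @param templates An [icn_template_set()].
#' @param dilate Number of dilation steps (default 1).
#' @return Logical 3-D array.
#' @export
analysis_mask <- function(templates, dilate = 1L) {
  m <- Reduce(`|`, lapply(templates$maps, function(x) x > 0))
  if (dilate > 0) m <- dilate26(m, dilate)
  m
}

template_design <- function(templates, mask) {
  X <- cbind(1, vapply(templates$maps, function(m) as.vector(m)[mask],
                       numeric(sum(mask))))
  colnames(X) <- c("(intercept)", templates$names)
  X
}

#' Stage-1 spatial regression
#'
#' For every time point, ordinary least squares of the in-mask volume on
#' the K template maps (intercept included). The fitted coefficients form
#' the subject's per-ICN time courses.
#'
#' @param scan An `icn_scan`.
#' @param templates An [icn_template_set()].
#' @param mask Optional logical 3-D array; default [analysis_mask()].
#' @return Object of class `icn_timecourses`: list with T x K matrix
#'   `values` (columns named after the ICNs) and `tr_seconds`.
#' @export
spatial_regression <- function(scan, templates, mask = NULL) {
  stopifnot(inherits(scan, "icn_scan"), inherits(templates, "icn_template_set"))
  d <- dim(scan$data)
  if (!identical(as.integer(d[1:3]), templates$grid_shape))
    stop("scan grid does not match template grid")
  K <- length(templates$maps)
  Tn <- d[4]
  if (Tn <= K + 1) stop("need T > K + 1 time points")
  if (is.null(mask)) mask <- analysis_mask(templates)
  mv <- as.vector(mask)
  X <- template_design(templates, mv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear template maps over the analysis mask: ",
         paste(drop, collapse = ", "))
  }
  Y <- matrix(scan$data, prod(d[1:3]), Tn)[mv, , drop = FALSE]
  B <- qr.coef(qrX, Y)               # (K+1) x T
  tc <- t(B[-1, , drop = FALSE])     # T x K
  colnames(tc) <- templates$names
  structure(list(values = tc, tr_seconds = scan$tr_seconds),
            class = "icn_timecourses")
}

#' Stage-2 temporal regression
#'
#' Per in-mask voxel, ordinary least squares of the voxel time series on
#' the K subject time courses (intercept included). Returns per-ICN beta
#' maps and the per-voxel, per-regressor standard errors derived from the
#' residual variance.
#'
#' @param scan An `icn_scan`.
#' @param tc An `icn_timecourses` from [spatial_regression()].
#' @param mask Optional logical 3-D array; voxels outside get beta = se = 0.
#' @return List with `beta` and `se` (each a list of K 3-D arrays, named by
#'   ICN), and `df`, the residual degrees of freedom T - K - 1.
#' @export
temporal_regression <- function(scan, tc, mask = NULL) {
  stopifnot(inherits(scan, "icn_scan"), inherits(tc, "icn_timecourses"))
  d <- dim(scan$data)
  V <- as.matrix(tc$values)
  K <- ncol(V)
  Tn <- d[4]
  if (nrow(V) != Tn) stop("time course length does not match scan")
  if (Tn <= K + 1) stop("need T > K + 1 time points")
  if (any(apply(V, 2, stats::sd) == 0))
    stop("constant (zero-variance) time course column: collinear with intercept")
  X <- cbind(1, V)
  XtXinv <- tryCatch(solve(crossprod(X)),
                     error = function(e) stop("collinear time courses"))
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  mv <- as.vector(mask)
  Y <- matrix(scan$data, prod(d[1:3]), Tn)[mv, , drop = FALSE]
  B <- XtXinv %*% crossprod(X, t(Y))          # (K+1) x nvox
  resid <- t(Y) - X %*% B
  dfree <- Tn - K - 1
  sigma2 <- colSums(resid^2) / dfree
  dXtX <- diag(XtXinv)
  beta <- se <- vector("list", K)
  for (k in seq_len(K)) {
    b <- array(0, dim = d[1:3]); s <- array(0, dim = d[1:3])
    b[mv] <- B[k + 1, ]
    s[mv] <- sqrt(pmax(sigma2 * dXtX[k + 1], 0))
    beta[[k]] <- b; se[[k]] <- s
  }
  names(beta) <- names(se) <- colnames(V)
  list(beta = beta, se = se, df = dfree)
}

#' z-score map from beta and standard-error maps
#'
#' `z = beta / se`, clamped to `[-z_cap, z_cap]`. The clamp guards voxels
#' with (numerically) zero residual variance, where the ratio diverges:
#' an exactly zero `se` gives `sign(beta) * z_cap`, and 0/0 gives 0. All
#' thresholds of analytic interest sit well below the cap.
#'
#' @param beta,se 3-D arrays on the same grid.
#' @param z_cap Magnitude cap (default 10).
#' @return 3-D array of z-scores.
#' @export
zscore_map <- function(beta, se, z_cap = 10) {
  if (!identical(dim(beta), dim(se))) stop("beta and se grids differ")
  z <- beta / se
  zero <- se == 0
  z[zero] <- sign(beta[zero]) * z_cap
  pmin(pmax(z, -z_cap), z_cap)
}

#' Full dual regression for one subject
#'
#' Runs [spatial_regression()] then [temporal_regression()] and converts
#' each ICN's beta map to a z map via [zscore_map()]. The z maps are the
#' subject's voxelwise ICN connectivity maps used for discretization
#' (GAMMA) and for the functional-connectivity biomarker evaluation.
#'
#' @inheritParams spatial_regression
#' @param subject_id Identifier stored with the result.
#' @param z_cap Passed to [zscore_map()].
#' @return Object of class `subject_icn_maps`: list with `subject_id`,
#'   `beta`, `z` (lists of K named 3-D arrays) and `timecourses`.
#' @export
dual_regression <- function(scan, templates, subject_id = "sub", mask = NULL,
                            z_cap = 10) {
  if (is.null(mask)) mask <- analysis_mask(templates)
  tc <- spatial_regression(scan, templates, mask)
  tr <- temporal_regression(scan, tc, mask)
  z <- mapply(zscore_map, tr$beta, tr$se,
              MoreArgs = list(z_cap = z_cap), SIMPLIFY = FALSE)
  structure(list(subject_id = subject_id, beta = tr$beta, z = z,
                 timecourses = tc, df = tr$df),
            class = "subject_icn_maps")
}

#' Stack one ICN's z maps across subjects
#'
#' Assembles the subjects x voxels matrix GAMMA and the classifier grid
#' operate on.
#'
#' @param maps_list List of `subject_icn_maps`, one per subject.
#' @param icn ICN name or index.
#' @return Numeric matrix (subjects x voxels) with attribute `grid_shape`;
#'   row names are subject ids.
#' @export
stack_zmaps <- function(maps_list, icn) {
  zs <- lapply(maps_list, function(m) {
    if (!inherits(m, "subject_icn_maps")) stop("expected subject_icn_maps")
    as.vector(m$z[[icn]])
  })
  out <- do.call(rbind, zs)
  rownames(out) <- vapply(maps_list, function(m) m$subject_id, "")
  attr(out, "grid_shape") <- dim(maps_list[[1]]$z[[icn]])
  out
}
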