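# Statistical treatment of the performance grid: classifier comparisons,
# factorial ANOVA, stability probabilities, representative-ICN selection
# and best thresholds.

grid_metrics <- c("acc", "sen", "spe")

check_grid <- function(grid) {
  stopifnot(is.data.frame(grid),
            all(c("icn", "threshold", "classifier", grid_metrics) %in%
                  names(grid)))
  grid
}

#' Pairwise classifier comparisons
#'
#' For each metric, performances are first averaged over thresholds within
#' (ICN, classifier); each classifier pair is then compared with a paired
#' two-sided t-test across ICNs. All-zero difference vectors are flagged
#' degenerate and reported with p = 1.
#'
#' @param grid A [run_grid()] result.
#' @return `data.frame` with metric, pair, t, df, p and `degenerate` flag.
#' @export
pairwise_classifier_tests <- function(grid) {
  check_grid(grid)
  icns <- unique(grid$icn)
  if (length(icns) < 2) stop("need >= 2 ICNs for pairwise tests")
  cls <- unique(grid$classifier)
  means <- stats::aggregate(grid[grid_metrics],
                            by = list(icn = grid$icn,
                                      classifier = grid$classifier), mean)
  rows <- list()
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  for (metric in grid_metrics) {
    for (pr in pairs) {
      a <- means[means$classifier == pr[1], ]
      b <- means[means$classifier == pr[2], ]
      d <- a[[metric]][match(icns, a$icn)] - b[[metric]][match(icns, b$icn)]
      n <- length(d)
      degen <- stats::sd(d) == 0
      if (degen) {
        tval <- 0; p <- 1
      } else {
        tval <- mean(d) / (stats::sd(d) / sqrt(n))
        p <- 2 * stats::pt(-abs(tval), n - 1)
      }
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, pair = paste(pr, collapse = "/"),
        t = tval, df = n - 1, p = p, degenerate = degen)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Factorial ANOVA of the performance grid
#'
#' Fixed-effects factorial ANOVA of each metric on threshold (THR),
#' classifier (CLS) and ICN with all two-way interactions. With a complete
#' L1 x L2 x L3 grid and one observation per cell, the main-effect degrees
#' of freedom are Li - 1 and the interaction dfs (Li - 1)(Lj - 1); the
#' three-way term is the residual.
#'
#' @param grid A complete [run_grid()] result.
#' @return Named list (one `data.frame` per metric) with columns term, df,
#'   F and p. Terms are THR, CLS, ICN, THR:CLS, THR:ICN, CLS:ICN,
#'   Residuals.
#' @export
factorial_anova <- function(grid) {
  check_grid(grid)
  d <- data.frame(THR = factor(grid$threshold),
                  CLS = factor(grid$classifier),
                  ICN = factor(grid$icn))
  counts <- table(d$THR, d$CLS, d$ICN)
  if (any(counts == 0)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    stop("incomplete factorial grid; missing cells such as (",
         paste(dimnames(counts)[[1]][miss[1, 1]],
               dimnames(counts)[[2]][miss[1, 2]],
               dimnames(counts)[[3]][miss[1, 3]], sep = ", "), ")")
  }
  out <- list()
  for (metric in grid_metrics) {
    d$y <- grid[[metric]]
    if (stats::sd(d$y) == 0) {
      # Constant metric: no variance to attribute; report zero effects.
      lv <- vapply(d[c("THR", "CLS", "ICN")], nlevels, 1L)
      df <- c(lv - 1, (lv[1] - 1) * (lv[2] - 1), (lv[1] - 1) * (lv[3] - 1),
              (lv[2] - 1) * (lv[3] - 1))
      tab <- data.frame(term = c("THR", "CLS", "ICN", "THR:CLS", "THR:ICN",
                                 "CLS:ICN"),
                        df = as.integer(df), F = 0, p = 1)
    } else {
      fit <- stats::aov(y ~ (THR + CLS + ICN)^2, data = d)
      s <- summary(fit)[[1]]
      term <- trimws(rownames(s))
      tab <- data.frame(term = term, df = s$Df, F = s$`F value`,
                        p = s$`Pr(>F)`)
    }
    out[[metric]] <- tab
  }
  out
}

#' Stability probability per ICN
#'
#' For each ICN, the fraction of its (threshold, classifier) grid cells
#' whose cross-validated accuracy is strictly above `acc_cut`, expressed
#' in percent to one decimal.
#'
#' @param grid A [run_grid()] result.
#' @param acc_cut Accuracy cut in percent (default 85).
#' @return `data.frame` with icn, n_pass, n_cells and probability
#'   (percent).
#' @export
stability_probability <- function(grid, acc_cut = 85) {
  check_grid(grid)
  sp <- lapply(split(grid, grid$icn), function(g) {
    data.frame(icn = g$icn[1], n_pass = sum(g$acc > acc_cut),
               n_cells = nrow(g),
               probability = round(100 * sum(g$acc > acc_cut) / nrow(g), 1))
  })
  out <- do.call(rbind, sp)
  rownames(out) <- NULL
  out[order(-out$probability, out$icn), ]
}

#' Select representative ICNs by stability
#'
#' ICNs whose stability probability is at least `p_cut` percent, sorted by
#' probability descending. An empty selection is returned (with a warning)
#' when no ICN reaches the cut.
#'
#' @param stab A [stability_probability()] table.
#' @param p_cut Selection cut in percent (default 70; inclusive).
#' @return Character vector of selected ICN names.
#' @export
select_representative <- function(stab, p_cut = 70) {
  sel <- stab[stab$probability >= p_cut, ]
  sel <- sel[order(-sel$probability), ]
  if (nrow(sel) == 0) warning("no ICN reaches the stability cut")
  sel$icn
}

#' Best thresholds for an ICN
#'
#' Finds the grid cells maximizing accuracy for the ICN, breaking ties by
#' sensitivity then specificity, and returns all co-optimal thresholds
#' (from any classifier) with the achieved metrics.
#'
#' @param grid A [run_grid()] result.
#' @param icn ICN name.
#' @return `data.frame` with threshold, classifier, acc, sen, spe; one row
#'   per co-optimal cell, thresholds ascending.
#' @export
best_thresholds <- function(grid, icn) {
  check_grid(grid)
  g <- grid[grid$icn == icn, ]
  if (nrow(g) == 0) stop("ICN not present in grid: ", icn)
  ord <- order(-g$acc, -g$sen, -g$spe)
  best <- g[ord[1], ]
  hit <- g$acc == best$acc & g$sen == best$sen & g$spe == best$spe
  out <- g[hit, c("threshold", "classifier", "acc", "sen", "spe")]
  out <- out[order(out$threshold), ]
  rownames(out) <- NULL
  out
}
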