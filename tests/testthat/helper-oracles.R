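# Independent oracles and small fixture builders used across tests.

# Polya-urn oracle for the BD score: log of the product of sequential
# predictive probabilities, run separately within each state cell, with
# Dirichlet(alpha_ess/2) per class within each state.
polya_log_bd <- function(states, y, alpha_ess = 2) {
  a <- alpha_ess / 2
  logp <- 0
  for (j in 0:1) {
    counts <- c(a, a)  # (negative, positive) pseudo-counts
    for (i in which(states == j)) {
      cls <- if (y[i]) 2 else 1
      logp <- logp + log(counts[cls] / sum(counts))
      counts[cls] <- counts[cls] + 1
    }
  }
  logp
}

# Precision-matrix oracle for the partial correlation of x and y given Z.
precision_partial_cor <- function(x, y, Z) {
  M <- cbind(x = x, y = y, Z)
  P <- solve(stats::cov(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Small synthetic cohort run through dual regression for one ICN.
# Returns the subjects x voxels z matrix, labels and planted voxel set.
tiny_cohort_zstack <- function(seed, n_mhe = 6, n_nmhe = 8, delta = 1,
                               noise_sd = 0.2, grid = c(12, 12, 12),
                               n_templates = 2, n_timepoints = 40,
                               coupling = 1) {
  cfg <- simulation_config(n_mhe = n_mhe, n_nmhe = n_nmhe,
                           grid_shape = grid, n_templates = n_templates,
                           n_timepoints = n_timepoints,
                           planted = list(icn = 1, core_level = 0.6,
                                          delta = delta),
                           noise_sd = noise_sd,
                           clinical_coupling = coupling, seed = seed)
  cohort <- simulate_cohort(cfg)
  mask <- analysis_mask(cohort$templates)
  maps <- lapply(seq_along(cohort$scans), function(i)
    dual_regression(cohort$scans[[i]], cohort$templates,
                    cohort$records$subject_id[i], mask))
  Z <- stack_zmaps(maps, 1)
  list(Z = Z, records = cohort$records, planted = cohort$planted,
       templates = cohort$templates, cohort = cohort)
}

binarize_stack <- function(Z, thr) {
  S <- discretize_zmap(Z, thr)
  attr(S, "grid_shape") <- attr(Z, "grid_shape")
  S
}
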