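test_that("discretization uses a strict threshold", {
  expect_equal(discretize_zmap(2.3, 2.0), 1L)
  expect_equal(discretize_zmap(2.0, 2.0), 0L)
  expect_equal(discretize_zmap(c(1.0, 2.6, 3.1), 2.5), c(0L, 1L, 1L))
  z <- array(c(1, 3, 2, 0), c(2, 2, 1))
  expect_equal(dim(discretize_zmap(z, 1.5)), dim(z))
})

test_that("the default threshold ladder has nine quarter steps", {
  expect_identical(threshold_grid(), seq(1, 3, 0.25))
})

test_that("BD score matches its worked values and is count-sufficient", {
  y4 <- c("NMHE", "NMHE", "MHE", "MHE")
  expect_equal(log_bd_score(c(1, 1, 0, 0), y4), log(1 / 9),
               tolerance = 1e-12)
  expect_equal(log_bd_score(c(1, 1, 1, 1), y4), log(1 / 30),
               tolerance = 1e-12)
  # permutation of subjects leaves the score unchanged
  set.seed(1)
  s <- rbinom(12, 1, 0.5)
  y <- rep(c(TRUE, FALSE), 6)
  o <- sample(12)
  expect_equal(log_bd_score(s, y), log_bd_score(s[o], y[o]))
  expect_error(log_bd_score(c(1, 0, 1), c(TRUE, TRUE, TRUE)), "degenerate")
})

test_that("sharpening a majority-aligned state vector never lowers the score", {
  y <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  n <- 8
  for (code in 0:(2^n - 1)) {
    s <- as.integer(intToBits(code)[1:n])
    mm <- which(s != as.integer(y))
    if (length(mm) == 0 || length(mm) >= n / 2) next
    sc <- log_bd_score(s, y)
    for (i in mm) {
      s2 <- s; s2[i] <- as.integer(y[i])
      expect_gte(log_bd_score(s2, y), sc - 1e-12)
    }
  }
})

test_that("ROI growing is similarity-gated and 26-connected", {
  gs <- c(5, 5, 5)
  n <- 10
  # rep voxel unlike all its neighbours -> singleton ROI
  S <- matrix(0L, n, prod(gs))
  rep_vox <- 63L
  S[, rep_vox] <- rep(c(1L, 0L), 5)
  roi <- grow_roi(rep_vox, S, kappa_sim = 0.9, grid_shape = gs)
  expect_identical(roi, rep_vox)

  # identical 3x3x3 block -> all 27 voxels
  blk <- array(FALSE, gs); blk[2:4, 2:4, 2:4] <- TRUE
  S2 <- matrix(0L, n, prod(gs))
  S2[, which(blk)] <- rep(c(1L, 0L), 5)
  roi2 <- grow_roi(63L, S2, kappa_sim = 0.9, grid_shape = gs)  # (3,3,3)
  expect_setequal(roi2, which(blk))

  # two identical but disconnected blocks: only the rep's component
  blk2 <- array(FALSE, gs)
  blk2[1:2, 1:2, 1:2] <- TRUE; blk2[4:5, 4:5, 4:5] <- TRUE
  S3 <- matrix(0L, n, prod(gs))
  S3[, which(blk2)] <- rep(c(1L, 0L), 5)
  roi3 <- grow_roi(1L, S3, kappa_sim = 0.9, grid_shape = gs)
  lower_block <- array(FALSE, gs); lower_block[1:2, 1:2, 1:2] <- TRUE
  expect_setequal(roi3, which(lower_block))
})

test_that("ROI states follow the majority rule with ties counting as 1", {
  m <- c(rep(1, 20), rep(0, 7))
  expect_equal(roi_state(m, seq_along(m), tau = 0.5), 1L)
  m2 <- c(rep(1, 13), rep(0, 14))
  expect_equal(roi_state(m2, seq_along(m2), tau = 0.5), 0L)
  m3 <- c(rep(1, 5), rep(0, 5))
  expect_equal(roi_state(m3, seq_along(m3), tau = 0.5), 1L)
  expect_error(roi_state(m, integer(0)), "empty")
})

test_that("conditional probability tables are smoothed and normalized", {
  # state 1: 2 NMHE / 0 MHE with add-1 smoothing
  st <- c(1, 1, 0, 0)
  y <- c("NMHE", "NMHE", "MHE", "MHE")
  cpt <- build_cpt(st, y, smoothing = 1)
  expect_equal(cpt["1", "MHE"], 0.25)
  cpt0 <- build_cpt(c(0, 0, 0, 1), c("MHE", "MHE", "MHE", "NMHE"),
                    smoothing = 0)
  expect_equal(cpt0["0", "MHE"], 1)
  set.seed(2)
  for (r in 1:5) {
    cpt_r <- build_cpt(rbinom(10, 1, 0.5),
                       rep(c("MHE", "NMHE"), 5), smoothing = r %% 3)
    expect_equal(unname(rowSums(cpt_r)), c(1, 1))
  }
})

test_that("permutation validation bounds and perfect separation behave", {
  n <- 12
  y <- rep(c(TRUE, FALSE), each = 6)
  S <- matrix(rbinom(n * 50, 1, 0.3), n, 50)
  attr(S, "grid_shape") <- c(50, 1, 1)
  p <- validate_model(-1e9, S, y, B = 99, seed = 1)
  expect_gte(p, 1 / 100)  # plus-one estimator floor
  # perfectly separating state: only a label-recreating permutation ties
  S[, 1] <- as.integer(y)
  obs <- log_bd_score(S[, 1], y)
  p2 <- validate_model(obs, S, y, B = 199, seed = 1)
  expect_lt(p2, 0.05)
})

test_that("fit_gamma recovers a planted region and is deterministic", {
  fix <- tiny_cohort_zstack(seed = 42)
  S <- binarize_stack(fix$Z, 2)
  params <- gamma_params(B = 99)
  m <- fit_gamma(S, fix$records$group, params, seed = 7,
                 icn = "ICN01", threshold = 2)
  expect_s3_class(m, "gamma_model")
  expect_gte(m$n_validated, 1)
  jac <- length(intersect(m$rois[[1]], fix$planted$voxels)) /
    length(union(m$rois[[1]], fix$planted$voxels))
  expect_gte(jac, 0.5)
  # representative voxel inside its ROI, ROIs disjoint and CPT rows sum 1
  for (i in seq_len(m$n_validated)) {
    expect_true(m$representative_voxels[i] %in% m$rois[[i]])
    expect_equal(unname(rowSums(m$cpts[[i]])), c(1, 1))
  }
  if (m$n_validated > 1) {
    expect_length(Reduce(intersect, m$rois), 0)
  }
  m2 <- fit_gamma(S, fix$records$group, params, seed = 7,
                  icn = "ICN01", threshold = 2)
  expect_identical(m$rois, m2$rois)
  expect_identical(m$pvalues, m2$pvalues)

  # a perfectly class-aligned voxel dominates the first selection
  expect_equal(unname(S[, m$representative_voxels[1]]),
               as.integer(fix$records$group == "NMHE"))
})

test_that("fit_gamma rejects degenerate inputs", {
  S <- matrix(rbinom(40, 1, 0.5), 4, 10)
  attr(S, "grid_shape") <- c(10, 1, 1)
  expect_error(fit_gamma(S, c(TRUE, TRUE, TRUE, TRUE)), "class|degenerate")
  S0 <- matrix(0L, 4, 10)
  attr(S0, "grid_shape") <- c(10, 1, 1)
  expect_error(fit_gamma(S0, c(TRUE, TRUE, FALSE, FALSE)), "mask")
})

test_that("gamma models serialize to JSON with 0-based voxel triples", {
  fix <- tiny_cohort_zstack(seed = 42)
  S <- binarize_stack(fix$Z, 2)
  m <- fit_gamma(S, fix$records$group, gamma_params(B = 99), seed = 7)
  path <- file.path(tempdir(), "gamma.json")
  write_gamma_model(m, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$n_validated, m$n_validated)
  first <- obj$rois_xyz0[[1]]
  expect_equal(length(first), length(m$rois[[1]]))
  tri <- unlist(first[[1]])
  expect_true(all(tri >= 0 & tri < max(m$grid_shape)))
})
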