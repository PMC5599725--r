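# Synthetic cohort generator: template ICN maps, mixed 4-D scans and a
# clinical table with the statistical structure the downstream analysis
# assumes (a planted connectivity deficit in MHE plus coupled clinical
# scores).

#' Construct an ICN template set
#'
#' Container for K spatial template maps defined on a common 3-D voxel grid.
#'
#' @param names Character vector of unique ICN labels.
#' @param maps List of 3-D numeric arrays, one per ICN, sharing one grid.
#' @param voxel_size_mm Numeric triple, voxel edge lengths in millimetres.
#' @return An object of class `icn_template_set` with fields `names`,
#'   `maps`, `grid_shape` and `voxel_size_mm`.
#' @export
icn_template_set <- function(names, maps, voxel_size_mm = c(3, 3, 3)) {
  if (length(names) < 1 || length(names) != length(maps))
    stop("need at least one template and one name per map")
  if (anyDuplicated(names)) stop("template names must be unique")
  dims <- lapply(maps, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stop("template maps must be 3-D arrays")
  if (length(unique(lapply(dims, as.integer))) != 1)
    stop("all template maps must share one grid shape")
  if (any(!vapply(maps, function(m) any(m > 0), TRUE)))
    stop("each template must have at least one strictly positive voxel")
  structure(
    list(names = as.character(names), maps = maps,
         grid_shape = as.integer(dims[[1]]),
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "icn_template_set")
}

#' @export
print.icn_template_set <- function(x, ...) {
  cat(sprintf("ICN template set: %d maps on %s grid\n",
              length(x$names), paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

# Lattice layout used to place low-overlap blobs: smallest near-cubic
# cell grid with at least n cells.
blob_lattice <- function(n, grid_shape) {
  cx <- ceiling(n^(1 / 3))
  cy <- ceiling(sqrt(n / cx))
  cz <- ceiling(n / (cx * cy))
  cells <- c(cx, cy, cz)
  cell_size <- grid_shape / cells
  list(cells = cells, cell_size = cell_size)
}

#' Generate a synthetic ICN template set
#'
#' Places `n_templates` compact Gaussian blobs on disjoint lattice cells of
#' the grid, mimicking the mutually low-overlap spatial supports of real ICN
#' template maps. Each blob is binarized at a fixed kernel level and then
#' weighted by the kernel, so supports are compact and weights peak at 1.
#'
#' @param n_templates Number of ICN templates (K >= 1).
#' @param grid_shape Integer triple, voxel grid dimensions.
#' @param seed Integer seed; identical arguments give identical maps.
#' @param voxel_size_mm Voxel size triple (metadata only).
#' @return An [icn_template_set()].
#' @examples
#' tpl <- make_template_set(4, c(20, 20, 20), seed = 1)
#' @export
make_template_set <- function(n_templates, grid_shape = c(30, 36, 30),
                              seed = 1, voxel_size_mm = c(3, 3, 3)) {
  stopifnot(n_templates >= 1, length(grid_shape) == 3, all(grid_shape >= 1))
  lat <- blob_lattice(n_templates, grid_shape)
  if (min(lat$cell_size) < 4)
    stop(sprintf(
      "grid %s too small to place %d low-overlap templates (cell %.1f < 4)",
      paste(grid_shape, collapse = "x"), n_templates, min(lat$cell_size)))
  sigma <- max(1.2, min(lat$cell_size) / 5)
  radius <- 2 * sigma
  with_seed(seed, {
    n_cells <- prod(lat$cells)
    cell_order <- sample.int(n_cells)[seq_len(n_templates)]
    cell_idx <- arrayInd(cell_order, lat$cells)
    coords <- list(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
    maps <- vector("list", n_templates)
    for (k in seq_len(n_templates)) {
      lo <- (cell_idx[k, ] - 1) * lat$cell_size
      centre <- lo + lat$cell_size / 2
      jit_max <- pmax(lat$cell_size / 2 - radius - 0.5, 0)
      centre <- centre + runif(3, -jit_max, jit_max)
      dx2 <- outer(
        outer((coords$x - 0.5 - centre[1])^2,
              (coords$y - 0.5 - centre[2])^2, "+"),
        (coords$z - 0.5 - centre[3])^2, "+")
      kern <- exp(-dx2 / (2 * sigma^2))
      cut <- exp(-radius^2 / (2 * sigma^2))
      m <- array(0, dim = grid_shape)
      inside <- kern >= cut
      m[inside] <- kern[inside] / max(kern[inside])
      maps[[k]] <- m
    }
    icn_template_set(sprintf("ICN%02d", seq_len(n_templates)), maps,
                     voxel_size_mm)
  })
}

#' Simulate one subject's 4-D scan from the ICN mixing model
#'
#' Generates `data(v, t) = sum_k loadings(t, k) * map_k(v) * gain_k(v) +
#' noise`, the linear spatio-temporal mixing model that dual regression
#' assumes, with i.i.d. Gaussian noise.
#'
#' @param templates An [icn_template_set()].
#' @param loadings T x K matrix of per-ICN time courses.
#' @param spatial_gain Either `NULL` (gain 1 everywhere), or a list of K 3-D
#'   arrays of voxelwise multipliers (scalars are recycled).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @param tr_seconds Repetition time of the synthetic acquisition.
#' @return An object of class `icn_scan`: list with 4-D `data` and
#'   `tr_seconds`.
#' @export
simulate_subject_scan <- function(templates, loadings, spatial_gain = NULL,
                                  noise_sd = 0.2, seed = 1,
                                  tr_seconds = 2.5) {
  stopifnot(inherits(templates, "icn_template_set"))
  loadings <- as.matrix(loadings)
  K <- length(templates$maps)
  if (ncol(loadings) != K)
    stop("loadings must have one column per template")
  if (nrow(loadings) < K + 2)
    stop("need T >= K + 2 time points for overdetermined regressions")
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  gs <- templates$grid_shape
  nvox <- prod(gs)
  M <- matrix(0, nvox, K)
  for (k in seq_len(K)) {
    g <- if (is.null(spatial_gain)) 1 else spatial_gain[[k]]
    if (!is.numeric(g)) stop("spatial_gain entries must be numeric")
    if (length(g) != 1 && !identical(as.integer(dim(g)), gs))
      stop("spatial_gain grid does not match template grid")
    M[, k] <- as.vector(templates$maps[[k]]) * as.vector(g)
  }
  dat <- M %*% t(loadings)
  if (noise_sd > 0) {
    dat <- dat + with_seed(seed, {
      matrix(rnorm(length(dat), sd = noise_sd), nrow(dat), ncol(dat))
    })
  }
  structure(list(data = array(dat, dim = c(gs, nrow(loadings))),
                 tr_seconds = tr_seconds),
            class = "icn_scan")
}

#' Simulate one subject's clinical record
#'
#' Draws neuropsychological scores (TMT-A, TMT-B, DST, BDT) and the
#' Child-Pugh score from group-conditional distributions in which MHE
#' subjects score worse (longer trail-making times, lower digit-symbol and
#' block-design scores, higher Child-Pugh), and couples each score to the
#' subject's planted ICN integration level: lower integration pushes scores
#' in the impaired direction when `coupling > 0`. Age, gender, education and
#' the movement summary (mean framewise displacement) are drawn
#' independently of group.
#'
#' @param group `"MHE"` or `"NMHE"`.
#' @param planted_integration Subject's true spatial gain over the planted
#'   region (1 = intact).
#' @param coupling Non-negative coefficient scaling the score-integration
#'   linkage; 0 decouples scores from the planted effect.
#' @param seed Integer seed.
#' @return Named list of clinical fields for one [subject record][simulate_cohort].
#' @export
simulate_clinical <- function(group, planted_integration = 1, coupling = 1,
                              seed = 1) {
  group <- as.character(normalize_group(group))
  stopifnot(is.finite(coupling), is.finite(planted_integration))
  # Group-conditional score distributions (mean, sd): MHE impaired.
  base <- list(
    NMHE = list(tmt_a = c(47.3, 16.9), tmt_b = c(124.1, 41.9),
                dst = c(40.0, 11.0), bdt = c(28.5, 9.6),
                child_pugh = c(7.0, 2.0)),
    MHE = list(tmt_a = c(75.2, 19.8), tmt_b = c(175.4, 47.6),
               dst = c(25.1, 7.6), bdt = c(18.5, 7.2),
               child_pugh = c(8.2, 2.2)))[[group]]
  # Direction of the integration linkage: deficit (integration < 1) raises
  # TMT times and Child-Pugh, lowers DST/BDT.
  dir <- c(tmt_a = -1, tmt_b = -1, dst = 1, bdt = 1, child_pugh = -1)
  with_seed(seed, {
    dev <- planted_integration - 1
    scores <- lapply(names(base), function(s) {
      base[[s]][1] + coupling * dir[[s]] * dev * base[[s]][2] +
        rnorm(1, sd = base[[s]][2])
    })
    names(scores) <- names(base)
    c(list(group = group),
      scores,
      list(age = rnorm(1, 51, 9),
           gender = if (runif(1) < 0.8) "M" else "F",
           education = max(0, rnorm(1, 8, 2.5)),
           movement = rlnorm(1, log(0.12), 0.4)))
  })
}

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic cohort. The defaults are the study
#' conditions the rest of the package is exercised under: 32 MHE and 42
#' NMHE subjects, 20 templates on a 30 x 36 x 30 grid (a coarse stand-in
#' for 3 mm template space), 115 retained time points at TR 2.5 s, one
#' planted discriminative region in the first ICN where MHE spatial gain is
#' reduced by `delta` (default 1, a complete loss), noise SD 0.2 and unit
#' clinical coupling.
#'
#' @param n_mhe,n_nmhe Group sizes (each >= 2).
#' @param grid_shape Voxel grid triple.
#' @param n_templates Number of ICN templates.
#' @param n_timepoints Retained volumes per scan.
#' @param tr_seconds Repetition time.
#' @param planted List with `icn` (template index), `core_level` (template
#'   weight level defining the planted region) and `delta` (gain reduction
#'   in MHE, 0 <= delta). Alternatively `voxels` may give explicit linear
#'   voxel indices.
#' @param noise_sd Scan noise SD.
#' @param clinical_coupling Coefficient passed to [simulate_clinical()].
#' @param seed Master integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_mhe = 32, n_nmhe = 42,
                              grid_shape = c(30, 36, 30), n_templates = 20,
                              n_timepoints = 115, tr_seconds = 2.5,
                              planted = list(icn = 1, core_level = 0.6,
                                             delta = 1),
                              noise_sd = 0.2, clinical_coupling = 1,
                              seed = 1) {
  stopifnot(n_mhe >= 2, n_nmhe >= 2, n_timepoints >= n_templates + 2,
            noise_sd >= 0, planted$delta >= 0)
  structure(list(n_mhe = n_mhe, n_nmhe = n_nmhe,
                 grid_shape = as.integer(grid_shape),
                 n_templates = n_templates, n_timepoints = n_timepoints,
                 tr_seconds = tr_seconds, planted = planted,
                 noise_sd = noise_sd,
                 clinical_coupling = clinical_coupling, seed = seed),
            class = "simulation_config")
}

# Resolve the planted voxel set (linear indices) for a template set.
planted_voxels <- function(templates, planted) {
  if (!is.null(planted$voxels)) {
    v <- as.integer(planted$voxels)
    if (any(templates$maps[[planted$icn]][v] <= 0))
      stop("planted voxel set must lie inside the template support")
    return(sort(v))
  }
  m <- templates$maps[[planted$icn]]
  sort(which(m >= planted$core_level))
}

#' Simulate a full synthetic cohort
#'
#' Generates the template set, one 4-D scan per subject and the clinical
#' table. MHE subjects have their spatial gain on the planted region
#' multiplied by `1 - delta`; NMHE gain is 1 everywhere. Clinical scores
#' are coupled to each subject's true planted gain via
#' [simulate_clinical()]. Fully reproducible from the config seed.
#'
#' @param cfg A [simulation_config()].
#' @param scan_fun Optional function `(scan, subject_index, templates)`
#'   applied to each scan as it is generated; when supplied, its return
#'   values are stored in `$derived` and the raw scans are discarded
#'   (memory-friendly at full cohort scale).
#' @return List with `templates`, `scans` (or `derived`), `records` (a
#'   data.frame, one row per subject), `planted` (icn index, voxel set,
#'   delta) and `true_integration` (per-subject planted gain).
#' @export
simulate_cohort <- function(cfg, scan_fun = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  templates <- make_template_set(cfg$n_templates, cfg$grid_shape,
                                 seed = derive_seed(cfg$seed, 1))
  pv <- planted_voxels(templates, cfg$planted)
  n <- cfg$n_mhe + cfg$n_nmhe
  groups <- c(rep("MHE", cfg$n_mhe), rep("NMHE", cfg$n_nmhe))
  K <- cfg$n_templates
  gain_map <- array(1, dim = cfg$grid_shape)
  gain_map[pv] <- 1 - cfg$planted$delta
  records <- vector("list", n)
  scans <- if (is.null(scan_fun)) vector("list", n) else NULL
  derived <- if (is.null(scan_fun)) NULL else vector("list", n)
  true_integration <- numeric(n)
  for (i in seq_len(n)) {
    gain <- vector("list", K)
    for (k in seq_len(K)) gain[[k]] <- 1
    gi <- if (groups[i] == "MHE") 1 - cfg$planted$delta else 1
    true_integration[i] <- gi
    if (groups[i] == "MHE") gain[[cfg$planted$icn]] <- gain_map
    loadings <- with_seed(derive_seed(cfg$seed, 2, i), {
      matrix(rnorm(cfg$n_timepoints * K), cfg$n_timepoints, K)
    })
    scan <- simulate_subject_scan(templates, loadings, gain,
                                  noise_sd = cfg$noise_sd,
                                  seed = derive_seed(cfg$seed, 3, i),
                                  tr_seconds = cfg$tr_seconds)
    if (is.null(scan_fun)) scans[[i]] <- scan
    else derived[[i]] <- scan_fun(scan, i, templates)
    rec <- simulate_clinical(groups[i], planted_integration = gi,
                             coupling = cfg$clinical_coupling,
                             seed = derive_seed(cfg$seed, 4, i))
    records[[i]] <- data.frame(subject_id = sprintf("sub%03d", i),
                               as.data.frame(rec, stringsAsFactors = FALSE))
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  list(templates = templates, scans = scans, derived = derived,
       records = records,
       planted = list(icn = cfg$planted$icn, voxels = pv,
                      delta = cfg$planted$delta),
       true_integration = true_integration)
}
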