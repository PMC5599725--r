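# End-to-end orchestration: dual regression -> GAMMA -> classifier grid
# -> ICN selection -> biomarker evaluation, with all artifacts written
# under the configured output directory.

write_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the inputs referenced by the configuration:
#' per-subject dual regression against the template set, the GAMMA +
#' classifier performance grid over all ICNs and thresholds, pairwise
#' classifier tests and factorial ANOVA of the grid, stability-based
#' selection of representative ICNs, refitting GAMMA at each selected
#' ICN's best threshold, and evaluation of the discriminative ROI's
#' integration patterns against group and clinical variables. Writes TSV
#' and JSON artifacts plus a single `report.json` under
#' `cfg$output_dir` and returns the report invisibly. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @param inputs Optional pre-loaded [load_inputs()] result (used by the
#'   simulate-then-run workflow to skip re-reading files).
#' @return The run report (list), invisibly.
#' @export
run_pipeline <- function(cfg, inputs = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(inputs)) inputs <- load_inputs(cfg)
  templates <- inputs$templates
  records <- inputs$records
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  mask <- analysis_mask(templates)

  message("stage dualreg: ", length(inputs$scans), " subjects, K = ",
          length(templates$names))
  maps_list <- lapply(seq_along(inputs$scans), function(i) {
    dual_regression(inputs$scans[[i]], templates,
                    subject_id = records$subject_id[i], mask = mask,
                    z_cap = cfg$gamma$z_cap)
  })
  zstacks <- lapply(templates$names, function(icn)
    stack_zmaps(maps_list, icn))
  names(zstacks) <- templates$names

  message("stage grid: ", length(zstacks), " ICNs x ",
          length(cfg$thresholds), " thresholds x ",
          length(cfg$classifiers), " classifiers (seed ", cfg$seed, ")")
  grid <- run_grid(zstacks, records$group, cfg$thresholds, cfg$gamma,
                   cfg$classifiers, cfg$k_folds, seed = cfg$seed)
  write_tsv(grid, file.path(out, "performance_grid.tsv"))
  jsonlite::write_json(grid, file.path(out, "performance_grid.json"),
                       auto_unbox = TRUE, digits = NA)

  message("stage select")
  anova_tabs <- if (length(unique(grid$icn)) > 1 &&
                      length(cfg$thresholds) > 1 &&
                      length(cfg$classifiers) > 1)
    factorial_anova(grid) else NULL
  pairwise <- if (length(unique(grid$icn)) > 1 &&
                    length(cfg$classifiers) > 1)
    pairwise_classifier_tests(grid) else NULL
  stab <- stability_probability(grid, cfg$acc_cut)
  selected <- suppressWarnings(select_representative(stab, cfg$p_cut))
  write_tsv(stab, file.path(out, "stability.tsv"))
  if (!is.null(pairwise))
    write_tsv(pairwise, file.path(out, "pairwise_classifier_tests.tsv"))
  if (!is.null(anova_tabs)) {
    for (m in names(anova_tabs))
      write_tsv(anova_tabs[[m]],
                file.path(out, sprintf("anova_%s.tsv", m)))
  }

  message("stage evaluate: ", length(selected), " selected ICN(s)")
  best <- list(); patterns <- list(); models <- list()
  for (icn in selected) {
    bt <- best_thresholds(grid, icn)
    best[[icn]] <- bt
    thr <- bt$threshold[1]
    Z <- zstacks[[icn]]
    S <- discretize_zmap(Z, thr)
    attr(S, "grid_shape") <- attr(Z, "grid_shape")
    model <- fit_gamma(S, records$group, cfg$gamma,
                       seed = derive_seed(cfg$seed,
                                          match(icn, templates$names),
                                          round(100 * thr)),
                       icn = icn, threshold = thr)
    models[[icn]] <- model
    write_gamma_model(model, file.path(out,
                                       sprintf("gamma_%s_%.2f.json", icn, thr)))
    if (model$n_validated > 0)
      patterns[[icn]] <- integration_patterns(Z, model$rois[[1]], thr)
  }
  evaluation <- NULL
  if (length(patterns) > 0) {
    evaluation <- evaluate_biomarkers(
      patterns, records, covariates = cfg$covariates,
      bonferroni_m = cfg$bonferroni_m %||% length(patterns))
    write_tsv(evaluation$group_tests, file.path(out, "group_tests.tsv"))
    write_tsv(evaluation$correlations,
              file.path(out, "partial_correlations.tsv"))
  }
  demo <- demographics_table(records)
  write_tsv(demo, file.path(out, "demographics.tsv"))

  report <- list(
    seed = cfg$seed,
    n_subjects = nrow(records),
    n_mhe = sum(normalize_group(records$group) == "MHE"),
    n_nmhe = sum(normalize_group(records$group) == "NMHE"),
    icns = templates$names,
    thresholds = cfg$thresholds,
    classifiers = cfg$classifiers,
    stability = stab,
    selected_icns = selected,
    best_thresholds = lapply(best, identity),
    n_validated_rois = lapply(models, function(m) m$n_validated),
    group_tests = evaluation$group_tests,
    partial_correlations = evaluation$correlations)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("subjects: %d (MHE %d / NMHE %d)", report$n_subjects,
            report$n_mhe, report$n_nmhe),
    sprintf("grid: %d ICNs x %d thresholds x %d classifiers",
            length(report$icns), length(report$thresholds),
            length(report$classifiers)),
    sprintf("selected ICNs: %s",
            if (length(selected)) paste(selected, collapse = ", ")
            else "(none)")),
    file.path(out, "report.txt"))
  invisible(report)
}

#' Simulate a cohort to disk in the pipeline's input formats
#'
#' Convenience wrapper writing templates, per-subject scans and the
#' subject table produced by [simulate_cohort()] under `dir`, so the
#' file-based pipeline can be exercised end to end.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory.
#' @return List with the input paths and the `planted` description.
#' @export
simulate_to_dir <- function(cfg, dir) {
  cohort <- simulate_cohort(cfg)
  tdir <- file.path(dir, "templates")
  sdir <- file.path(dir, "scans")
  write_template_set(cohort$templates, tdir)
  for (i in seq_along(cohort$scans)) {
    write_scan(cohort$scans[[i]],
               file.path(sdir, paste0(cohort$records$subject_id[i],
                                      ".nii.gz")))
  }
  tab <- file.path(dir, "subjects.tsv")
  write_subject_table(cohort$records, tab)
  list(templates_dir = tdir, scans_dir = sdir, subject_table = tab,
       planted = cohort$planted)
}
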