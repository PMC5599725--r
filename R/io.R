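# File formats: NIfTI-1 volumes, the TSV subject table and the YAML run
# configuration.

subject_table_columns <- c("subject_id", "group", "tmt_a", "tmt_b", "dst",
                           "bdt", "child_pugh", "age", "gender",
                           "education", "movement")

as_nifti_volume <- function(arr, voxel_size_mm = c(3, 3, 3),
                            tr_seconds = NULL) {
  img <- RNifti::asNifti(arr)
  pd <- if (length(dim(arr)) == 4) c(voxel_size_mm, tr_seconds %||% 1)
        else voxel_size_mm
  RNifti::pixdim(img) <- pd
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a template set as NIfTI volumes
#'
#' One `.nii.gz` file per ICN, named `<icn>.nii.gz`.
#'
#' @param templates An [icn_template_set()].
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_template_set <- function(templates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(templates$names, ".nii.gz"))
  for (k in seq_along(templates$maps)) {
    RNifti::writeNifti(as_nifti_volume(templates$maps[[k]],
                                       templates$voxel_size_mm),
                       paths[k])
  }
  invisible(paths)
}

#' Read a template set from a directory of NIfTI volumes
#'
#' @param dir Directory containing one 3-D `.nii(.gz)` file per ICN; ICN
#'   names are the file stems, read in lexicographic order.
#' @return An [icn_template_set()].
#' @export
read_template_set <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(paths) == 0) stop("no NIfTI templates found in ", dir)
  maps <- lapply(paths, function(p) {
    arr <- as.array(RNifti::readNifti(p))
    if (length(dim(arr)) != 3) stop("template is not 3-D: ", p)
    arr
  })
  vs <- RNifti::pixdim(RNifti::readNifti(paths[1]))[1:3]
  nm <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  icn_template_set(nm, maps, vs)
}

#' Write a 4-D scan as NIfTI
#' @param scan An `icn_scan`.
#' @param path Output `.nii.gz` path.
#' @param voxel_size_mm Voxel size triple.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, voxel_size_mm = c(3, 3, 3)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(as_nifti_volume(scan$data, voxel_size_mm,
                                     scan$tr_seconds), path)
  invisible(path)
}

#' Read a 4-D scan from NIfTI
#' @param path A 4-D NIfTI file.
#' @return An `icn_scan`.
#' @export
read_scan <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("scan is not 4-D: ", path)
  if (any(!is.finite(arr))) stop("non-finite values in scan: ", path)
  tr <- RNifti::pixdim(img)
  tr <- if (length(tr) >= 4) tr[4] else 1
  structure(list(data = arr, tr_seconds = tr), class = "icn_scan")
}

#' Write subject z maps as NIfTI volumes
#'
#' One file per ICN, named `{subject}_{icn}_z.nii.gz`.
#'
#' @param maps A `subject_icn_maps` object.
#' @param dir Output directory.
#' @param voxel_size_mm Voxel size triple.
#' @return File paths, invisibly.
#' @export
write_zmaps <- function(maps, dir, voxel_size_mm = c(3, 3, 3)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_%s_z.nii.gz", maps$subject_id,
                                  names(maps$z)))
  for (k in seq_along(maps$z)) {
    RNifti::writeNifti(as_nifti_volume(maps$z[[k]], voxel_size_mm),
                       paths[k])
  }
  invisible(paths)
}

#' Write the subject table as TSV
#' @param records Subject `data.frame` with the canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(records, path) {
  missing_cols <- setdiff(subject_table_columns, names(records))
  if (length(missing_cols) > 0)
    stop("subject table missing columns: ",
         paste(missing_cols, collapse = ", "))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.table(records[subject_table_columns], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate the subject table
#'
#' Enforces the fixed header, rejects non-finite scores and normalizes
#' group labels (case-insensitive MHE/NMHE).
#'
#' @param path TSV file path.
#' @return Validated `data.frame`.
#' @export
read_subject_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  missing_cols <- setdiff(subject_table_columns, names(tab))
  if (length(missing_cols) > 0)
    stop("malformed subject table; missing columns: ",
         paste(missing_cols, collapse = ", "))
  tab$group <- as.character(normalize_group(tab$group))
  num <- setdiff(subject_table_columns, c("subject_id", "group", "gender"))
  for (v in num) {
    if (any(!is.finite(as.numeric(tab[[v]]))))
      stop("non-finite values in subject table column: ", v)
  }
  tab
}

#' Pipeline run configuration
#'
#' @param templates_dir,scans_dir Directories of NIfTI inputs.
#' @param subject_table Path to the TSV subject table.
#' @param output_dir Directory for all stage artifacts.
#' @param thresholds z-threshold ladder (default [threshold_grid()]).
#' @param gamma A [gamma_params()] list.
#' @param classifiers Classifier kinds for the grid.
#' @param k_folds Cross-validation folds.
#' @param acc_cut,p_cut Stability accuracy cut and selection cut (percent).
#' @param bonferroni_m Family size for the clinical correlations; default
#'   the number of selected ICNs.
#' @param covariates Covariate columns for the partial correlations.
#' @param seed Master seed.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(templates_dir, scans_dir, subject_table, output_dir,
                       thresholds = threshold_grid(),
                       gamma = gamma_params(),
                       classifiers = c("SVM", "MLP", "TREE"), k_folds = 10,
                       acc_cut = 85, p_cut = 70, bonferroni_m = NULL,
                       covariates = c("movement", "age", "gender",
                                      "education"),
                       seed = 1) {
  structure(list(templates_dir = templates_dir, scans_dir = scans_dir,
                 subject_table = subject_table, output_dir = output_dir,
                 thresholds = thresholds, gamma = gamma,
                 classifiers = classifiers, k_folds = k_folds,
                 acc_cut = acc_cut, p_cut = p_cut,
                 bonferroni_m = bonferroni_m, covariates = covariates,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$gamma <- unclass(obj$gamma)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$gamma <- do.call(gamma_params, obj$gamma)
  do.call(run_config, obj)
}

#' Load and validate all pipeline inputs
#'
#' Reads the template set, all subject scans and the subject table;
#' checks grid agreement across volumes and that every subject in the
#' table has a scan named `<subject_id>.nii.gz`.
#'
#' @param cfg A [run_config()].
#' @return List with `templates`, `scans` (named by subject) and
#'   `records`.
#' @export
load_inputs <- function(cfg) {
  templates <- read_template_set(cfg$templates_dir)
  records <- read_subject_table(cfg$subject_table)
  paths <- file.path(cfg$scans_dir, paste0(records$subject_id, ".nii.gz"))
  missing_scans <- records$subject_id[!file.exists(paths)]
  if (length(missing_scans) > 0)
    stop("missing scan(s) for subject id(s): ",
         paste(missing_scans, collapse = ", "))
  scans <- lapply(paths, read_scan)
  names(scans) <- records$subject_id
  for (s in names(scans)) {
    if (!identical(as.integer(dim(scans[[s]]$data)[1:3]),
                   templates$grid_shape))
      stop("grid mismatch between scan ", s, " and templates")
  }
  list(templates = templates, scans = scans, records = records)
}
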