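#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (numeric array), `voxel_size` (mm per spatial
#'   axis) and, for 4D images, `tr` (s).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_neuromkl("file not found: ", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  list(data = array(as.numeric(arr), dim = dim(arr)),
       voxel_size = pd[1:3],
       tr = if (length(dim(arr)) >= 4L) pd[4] else NULL)
}

#' Write a NIfTI volume
#'
#' @param volume 3D or 4D numeric array.
#' @param voxel_size mm per spatial axis (scalar or length 3).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param tr repetition time in s, stored in the 4th pixdim slot for 4D
#'   images.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(volume, voxel_size, path, tr = NULL) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  img <- RNifti::asNifti(volume)
  pd <- as.numeric(voxel_size)
  if (length(dim(volume)) == 4L) pd <- c(pd, tr %||% 1)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Extract GMV, ALFF and ReHo feature matrices from a cohort
#'
#' Per subject: the structural volume becomes the GMV map; the functional
#' series is truncated of its leading `n_discard` volumes, then (a) each
#' volume is smoothed and voxelwise ALFF over `band` computed, and (b) ReHo
#' is computed on the unsmoothed series and the finished map smoothed. ALFF
#' and ReHo maps are divided by their within-mask global mean. Maps are
#' stacked into subjects-by-voxels matrices in the shared voxel order.
#'
#' @param cohort an `mkl_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param mask a [brain_mask()] (default: all voxels).
#' @param features subset of `c("GMV", "ALFF", "ReHo")`.
#' @param band ALFF band in Hz.
#' @param fwhm smoothing FWHM in mm (default 4).
#' @param n_discard leading volumes to drop (default 10).
#' @return Named list of `feature_matrix` objects.
#' @export
extract_features <- function(cohort, mask = NULL,
                             features = c("GMV", "ALFF", "ReHo"),
                             band = c(0.01, 0.08), fwhm = 4, n_discard = 10L) {
  features <- match.arg(features, several.ok = TRUE)
  if (is.null(mask)) mask <- brain_mask(array(TRUE, dim = dim(cohort[[1]]$structural)))
  out <- list()
  gmv_maps <- list(); alff_maps <- list(); reho_maps <- list()
  for (scan in cohort) {
    vs <- scan$voxel_size
    if ("GMV" %in% features) {
      gmv_maps[[scan$subject_id]] <- gmv_map(scan$structural, mask, scan$subject_id)
    }
    if (any(c("ALFF", "ReHo") %in% features)) {
      fun <- discard_volumes(scan$functional, n_discard)
      if ("ALFF" %in% features) {
        alff_maps[[scan$subject_id]] <- alff_map(fun, scan$tr, band, mask,
                                                 fwhm = fwhm, voxel_size = vs,
                                                 subject_id = scan$subject_id)
      }
      if ("ReHo" %in% features) {
        reho_maps[[scan$subject_id]] <- reho_map(fun, mask, fwhm = fwhm,
                                                 voxel_size = vs,
                                                 subject_id = scan$subject_id)
      }
    }
  }
  if ("GMV" %in% features) out$GMV <- vectorize(gmv_maps, mask)
  if ("ALFF" %in% features) out$ALFF <- vectorize(alff_maps, mask)
  if ("ReHo" %in% features) out$ReHo <- vectorize(reho_maps, mask)
  out
}

#' Assemble a pipeline run configuration
#'
#' @param cohort_dir optional directory of an existing cohort (NIfTI pairs
#'   plus `participants.tsv`); if `NULL`, a synthetic cohort is generated
#'   from `cohort` (a [cohort_config()], default [default_cohort_config()]).
#' @param out_dir output directory.
#' @param comparison name of the two-group comparison, used in file names.
#' @param features non-empty subset of `c("GMV", "ALFF", "ReHo")`.
#' @param band ALFF band in Hz (must lie below Nyquist for the cohort TR).
#' @param fwhm smoothing FWHM in mm.
#' @param n_discard leading volumes to drop.
#' @param C SVM box constraint, > 0.
#' @param theta discrimination-map threshold fraction.
#' @param seed master seed; every random draw in the run derives from it.
#' @param cohort a [cohort_config()] used when `cohort_dir` is `NULL`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, cohort_dir = NULL, comparison = "pos-vs-neg",
                       features = c("GMV", "ALFF", "ReHo"),
                       band = c(0.01, 0.08), fwhm = 4, n_discard = 10L,
                       C = 100, theta = 0.30, seed = 1L, cohort = NULL) {
  features <- match.arg(features, several.ok = TRUE)
  if (length(features) < 1L) stop_neuromkl("feature set must be non-empty")
  check_scalar(C, "C", lower = 1e-12)
  check_scalar(theta, "theta", lower = 1e-12, upper = 1)
  if (is.null(cohort) && is.null(cohort_dir)) {
    cohort <- default_cohort_config(seed = derive_seed(seed, "simulate"))
  }
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir,
                 comparison = comparison, features = features, band = band,
                 fwhm = fwhm, n_discard = as.integer(n_discard), C = C,
                 theta = theta, seed = as.integer(seed), cohort = cohort),
            class = "run_config")
}

#' Read a pipeline run configuration from a YAML file
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_neuromkl("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("out_dir", "cohort_dir", "comparison",
                                  "features", "band", "fwhm", "n_discard",
                                  "C", "theta", "seed"))]
  do.call(run_config, args)
}

stage_checksum <- function(x) {
  v <- unlist(x, use.names = FALSE)
  v <- as.numeric(v[is.finite(as.numeric(v))])
  sprintf("%.10e", sum(v * seq_along(v) %% 97))
}

#' Run the full pipeline: simulate, extract, evaluate, map
#'
#' Executes all stages in order, writes a Table-style metrics report (one
#' row per single feature plus the combined classifier, with SEN/SPE/ACC/
#' AUC), ROC points, per-feature discrimination maps (NIfTI), and a
#' provenance record (config echo, seed, package version, per-stage
#' checksums). Identical configuration and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `metrics` (tibble), `fold_results`,
#'   `maps`, `beta` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(seed = config$seed,
                     version = as.character(utils::packageVersion("neuromkl")),
                     config = config[c("comparison", "features", "band", "fwhm",
                                       "n_discard", "C", "theta", "seed")],
                     stages = list())

  # -- simulate / load -------------------------------------------------------
  if (!is.null(config$cohort_dir)) {
    if (!dir.exists(config$cohort_dir)) {
      stop_neuromkl("cohort directory not found: ", config$cohort_dir)
    }
    cohort <- read_cohort(config$cohort_dir)
    mask <- brain_mask(array(TRUE, dim = dim(cohort[[1]]$structural)))
  } else {
    cohort <- generate_cohort(config$cohort)
    mask <- cohort_mask(config$cohort)
  }
  labels <- purrr::map_dbl(cohort, "label")
  nyq <- 1 / (2 * cohort[[1]]$tr)
  if (config$band[2] > nyq + 1e-12) {
    stop_neuromkl(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz",
                          config$band[2], nyq))
  }
  provenance$stages$simulate <- stage_checksum(purrr::map(cohort, "structural"))

  # -- extract ---------------------------------------------------------------
  fm <- extract_features(cohort, mask, features = config$features,
                         band = config$band, fwhm = config$fwhm,
                         n_discard = config$n_discard)
  provenance$stages$extract <- stage_checksum(purrr::map(fm, unclass))

  # -- evaluate --------------------------------------------------------------
  folds_comb <- loocv(fm, labels, C = config$C)
  rep_comb <- metrics_report(folds_comb, config$comparison)
  single <- purrr::imap(fm, function(X, f) {
    metrics_report(loocv(fm[f], labels, C = config$C), paste0(config$comparison, ":", f))
  })
  metrics <- dplyr::bind_rows(c(purrr::imap(single, function(r, f) metrics_row(r, f)),
                                list(metrics_row(rep_comb, "Combined"))))
  if (length(single) >= 1L) {
    metrics$improvement <- c(rep(NA_real_, length(single)),
                             improvement_over_best_single(
                               rep_comb$confusion$accuracy,
                               purrr::map_dbl(single, ~ .x$confusion$accuracy)))
  }
  utils::write.table(metrics, file.path(config$out_dir,
                                        paste0(config$comparison, "_metrics.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(rep_comb$roc, file.path(config$out_dir,
                                           paste0(config$comparison, "_roc.csv")),
                   row.names = FALSE)
  provenance$stages$evaluate <- stage_checksum(folds_comb$decision)

  # -- maps ------------------------------------------------------------------
  full <- fit_full_and_map(fm, labels, mask, C = config$C, theta = config$theta)
  vs <- cohort[[1]]$voxel_size
  for (f in names(full$maps)) {
    write_discrimination_map(full$maps[[f]], vs,
                             file.path(config$out_dir,
                                       paste0(config$comparison, "_", f)))
  }
  provenance$stages$maps <- stage_checksum(purrr::map(full$maps, "weights"))

  jsonlite::write_json(provenance,
                       file.path(config$out_dir,
                                 paste0(config$comparison, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = tibble::as_tibble(metrics), fold_results = folds_comb,
                 report = rep_comb, single = single, maps = full$maps,
                 beta = full$beta, provenance = provenance))
}

metrics_row <- function(report, feature) {
  tibble::tibble(feature = feature,
                 SEN = report$confusion$report$SEN,
                 SPE = report$confusion$report$SPE,
                 ACC = report$confusion$report$ACC,
                 AUC = round_half_up(report$auc, 2))
}
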