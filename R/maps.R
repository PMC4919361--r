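#' Build a thresholded discrimination map from a weight vector
#'
#' Scatters the per-voxel classifier weights back into the volume through
#' the shared voxel order and retains the voxels whose absolute weight is at
#' least `theta` times the maximum absolute weight (default 30%). Retention
#' depends on `|w|` only; signs are preserved in the weight volume.
#' Out-of-mask voxels are 0 and never retained. Because the classifier is
#' multivariate, retained voxels mark contribution to the whole-brain
#' decision, not locally significant differences.
#'
#' @param w numeric weight vector of length `D` (one per in-mask voxel).
#' @param mask a [brain_mask()].
#' @param theta threshold fraction in (0, 1].
#' @param feature optional feature name carried in the result.
#' @return A `discrimination_map`: signed `weights` volume, logical
#'   `retained` volume, `theta`, `max_abs`, `feature`.
#' @export
build_discrimination_map <- function(w, mask, theta = 0.30, feature = NA_character_) {
  check_scalar(theta, "theta", lower = 1e-12, upper = 1)
  vox <- voxel_order(mask)
  if (length(w) != length(vox)) {
    stop_neuromkl(sprintf("weight vector length %d does not match mask D = %d",
                          length(w), length(vox)))
  }
  weights <- map_from_vector(w, mask)
  max_abs <- max(abs(w))
  retained <- array(FALSE, dim = dim(mask))
  if (max_abs > 0) {
    retained[vox] <- abs(w) >= theta * max_abs
  } else {
    warn(sprintf("all weights are zero%s; discrimination map is empty",
                 if (is.na(feature)) "" else paste0(" for feature ", feature)))
  }
  structure(list(feature = feature, weights = weights, retained = retained,
                 theta = theta, max_abs = max_abs),
            class = "discrimination_map")
}

#' @export
print.discrimination_map <- function(x, ...) {
  cat(sprintf("<discrimination_map>%s theta = %.2f, max|w| = %.3g, %d voxels retained\n",
              if (is.na(x$feature)) "" else paste0(" ", x$feature),
              x$theta, x$max_abs, sum(x$retained)))
  invisible(x)
}

#' Fit on all subjects and build one discrimination map per feature
#'
#' Fits the multi-kernel SVM on the full cohort (z-scoring fitted on all
#' subjects), extracts the effective per-feature primal weight vectors, and
#' thresholds each into a discrimination map. One map per comparison, from
#' a single full-data fit.
#'
#' @param feature_matrices named list of subjects-by-voxels matrices.
#' @param labels labels in \{-1, +1\}.
#' @param mask a [brain_mask()].
#' @param C SVM box constraint.
#' @param theta threshold fraction (default 0.30).
#' @param precondition passed to [fit_mkl()].
#' @return List with `maps` (named list of `discrimination_map`s), `model`
#'   (the full-data `mkl_svm`) and `beta` (named kernel weights).
#' @export
fit_full_and_map <- function(feature_matrices, labels, mask, C = 100,
                             theta = 0.30, precondition = TRUE) {
  Z <- purrr::map(feature_matrices, function(X) {
    zscore_apply(unclass(X), zscore_fit(X))
  })
  model <- fit_mkl(purrr::map(Z, tcrossprod), as.numeric(labels), C = C,
                   precondition = precondition)
  w <- extract_weight_vectors(model, Z)
  maps <- purrr::imap(w, function(wf, f) {
    build_discrimination_map(wf, mask, theta = theta, feature = f)
  })
  beta <- stats::setNames(model$beta, names(feature_matrices) %||% model$kernel_names)
  list(maps = maps, model = model, beta = beta)
}

#' Write a discrimination map as NIfTI volumes
#'
#' Writes the signed weight volume and the binary retained mask.
#'
#' @param map a `discrimination_map`.
#' @param voxel_size voxel size in mm.
#' @param prefix output path prefix; `_weights.nii.gz` and `_mask.nii.gz`
#'   are appended.
#' @return Invisibly, the two paths.
#' @export
write_discrimination_map <- function(map, voxel_size, prefix) {
  pw <- paste0(prefix, "_weights.nii.gz")
  pm <- paste0(prefix, "_mask.nii.gz")
  write_nifti(map$weights, voxel_size, pw)
  write_nifti(array(as.numeric(map$retained), dim = dim(map$retained)),
              voxel_size, pm)
  invisible(c(weights = pw, mask = pm))
}
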