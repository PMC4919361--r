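#' Tidy the kernel weights of a fitted multi-kernel SVM
#'
#' @param x an `mkl_svm`.
#' @param ... unused.
#' @return Tibble with one row per kernel: `kernel`, `beta`, `scale`.
#' @export
tidy.mkl_svm <- function(x, ...) {
  tibble::tibble(kernel = x$kernel_names, beta = x$beta, scale = x$scales)
}

#' One-row fit summary of a multi-kernel SVM
#'
#' @param x an `mkl_svm`.
#' @param ... unused.
#' @return Tibble with `n`, `n_kernels`, `n_support`, `C`,
#'   `outer_iterations`, `objective`, `duality_gap`.
#' @export
glance.mkl_svm <- function(x, ...) {
  tibble::tibble(n = x$n, n_kernels = length(x$beta),
                 n_support = length(x$support), C = x$C,
                 outer_iterations = x$diagnostics$outer_iterations,
                 objective = x$diagnostics$objective,
                 duality_gap = x$diagnostics$duality_gap)
}

#' Tidy a metrics report into metric/value rows
#'
#' @param x an `mkl_metrics` from [metrics_report()].
#' @param ... unused.
#' @return Tibble with columns `metric` and `value` (rates in percent, AUC
#'   on `[0, 1]`).
#' @export
tidy.mkl_metrics <- function(x, ...) {
  tibble::tibble(metric = c("sensitivity", "specificity", "accuracy", "auc"),
                 value = c(x$confusion$sensitivity, x$confusion$specificity,
                           x$confusion$accuracy, x$auc))
}

#' One-row summary of a metrics report
#'
#' @param x an `mkl_metrics`.
#' @param ... unused.
#' @return Tibble with `comparison`, `n`, counts, rounded rates and `auc`.
#' @export
glance.mkl_metrics <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(comparison = x$comparison, n = x$n),
                   x$confusion$counts, x$confusion$report,
                   tibble::tibble(AUC = x$auc))
}

#' ROC curve of a metrics report
#'
#' @param object an `mkl_metrics`.
#' @param ... unused.
#' @return A ggplot of the pooled-fold ROC curve with the chance diagonal.
#' @export
autoplot.mkl_metrics <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = if (is.na(object$comparison)) "ROC" else object$comparison,
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Tidy a discrimination map into per-voxel rows
#'
#' @param x a `discrimination_map`.
#' @param ... unused.
#' @return Tibble with voxel coordinates (1-based), `weight` and `retained`,
#'   restricted to voxels with non-zero weight.
#' @export
tidy.discrimination_map <- function(x, ...) {
  idx <- which(x$weights != 0 | x$retained, arr.ind = TRUE)
  w <- x$weights[idx]
  r <- x$retained[idx]
  feat <- x$feature
  tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                 weight = w, retained = r, feature = feat)
}

#' Axial-slice montage of a discrimination map
#'
#' @param object a `discrimination_map`.
#' @param slices z-indices to show (default: four evenly spaced).
#' @param ... unused.
#' @return A ggplot tiling the selected axial slices; retained voxels are
#'   outlined by the fill scale of the signed weights.
#' @export
autoplot.discrimination_map <- function(object, slices = NULL, ...) {
  dz <- dim(object$weights)[3]
  if (is.null(slices)) slices <- unique(round(seq(1, dz, length.out = 4)))
  df <- tidy(object)
  df <- df[df$z %in% slices, , drop = FALSE]
  df$z <- factor(df$z, levels = slices, labels = paste0("z = ", slices))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$weight,
                                   alpha = .data$retained)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1),
                                guide = "none") +
    ggplot2::facet_wrap(~z) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = if (is.na(object$feature)) "Discrimination map"
                  else paste("Discrimination map:", object$feature),
                  subtitle = sprintf("threshold %.0f%% of max |w|",
                                     100 * object$theta)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
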