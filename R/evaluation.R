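#' Leave-one-out cross-validation of the multi-kernel SVM
#'
#' Each subject in turn is held out; per-voxel z-score normalization is
#' fitted on the training fold only (default), linear Grams are built from
#' the normalized training rows, the multi-kernel SVM is fitted on the fold
#' (kernel weights are learned per fold), and the held-out subject is
#' classified from its kernel columns against the fold. Fully deterministic
#' given the inputs.
#'
#' @param feature_matrices named list of subjects-by-voxels matrices, one
#'   per feature, with identical row order.
#' @param labels integer labels in \{-1, +1\}, one per subject.
#' @param C SVM box constraint (default 100).
#' @param normalize `"fold"` (z-score fitted per training fold, the
#'   default), `"global"` (fitted once on all subjects) or `"none"`.
#' @param precondition passed to [fit_mkl()].
#' @param tol,max_outer convergence controls passed to [fit_mkl()].
#' @param subject_ids optional identifiers (default from the first feature
#'   matrix, else `sub-001`...).
#' @return A tibble of class `mkl_loocv` with one row per subject:
#'   `held_out_id`, `y_true`, `y_pred`, `decision`, and a `beta`
#'   list-column of per-fold kernel weights.
#' @export
loocv <- function(feature_matrices, labels, C = 100, normalize = c("fold", "global", "none"),
                  precondition = TRUE, tol = 1e-4, max_outer = 100L,
                  subject_ids = NULL) {
  normalize <- match.arg(normalize)
  if (!is.list(feature_matrices) || length(feature_matrices) < 1L) {
    stop_neuromkl("`feature_matrices` must be a non-empty list")
  }
  n <- nrow(feature_matrices[[1]])
  if (n < 3L) stop_neuromkl("need at least 3 subjects")
  if (!all(purrr::map_int(feature_matrices, nrow) == n)) {
    stop_neuromkl("feature matrices must have identical row counts")
  }
  labels <- as.numeric(labels)
  if (length(labels) != n || !all(labels %in% c(-1, 1))) {
    stop_neuromkl("labels must be -1/+1, one per subject")
  }
  if (is.null(subject_ids)) {
    subject_ids <- attr(feature_matrices[[1]], "subject_ids") %||%
      sprintf("sub-%03d", seq_len(n))
  }
  fnames <- names(feature_matrices) %||% paste0("feature", seq_along(feature_matrices))

  global_params <- NULL
  if (normalize == "global") {
    global_params <- purrr::map(feature_matrices, zscore_fit)
  }

  rows <- purrr::map(seq_len(n), function(i) {
    train <- setdiff(seq_len(n), i)
    y_tr <- labels[train]
    if (length(unique(y_tr)) < 2L) {
      stop_neuromkl(sprintf("training fold for subject %s contains a single class",
                            subject_ids[i]))
    }
    prep <- purrr::imap(feature_matrices, function(X, f) {
      Xtr <- unclass(X)[train, , drop = FALSE]
      xte <- unclass(X)[i, , drop = TRUE]
      if (normalize == "fold") {
        p <- zscore_fit(Xtr)
        Xtr <- zscore_apply(Xtr, p)
        xte <- drop(zscore_apply(xte, p))
      } else if (normalize == "global") {
        p <- global_params[[f]]
        Xtr <- zscore_apply(Xtr, p)
        xte <- drop(zscore_apply(xte, p))
      }
      list(gram = tcrossprod(Xtr), col = drop(Xtr %*% xte))
    })
    model <- fit_mkl(purrr::map(prep, "gram"), y_tr, C = C, tol = tol,
                     max_outer = max_outer, precondition = precondition)
    d <- decision_function(model, purrr::map(prep, "col"))
    tibble::tibble(held_out_id = subject_ids[i], y_true = labels[i],
                   y_pred = if (d >= 0) 1 else -1, decision = d,
                   beta = list(stats::setNames(model$beta, fnames)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mkl_loocv", class(out))
  out
}

#' Confusion counts and classification rates from fold results
#'
#' Patients are the +1 class. Sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/n, reported as percentages; the `report`
#' element rounds half-up to 2 decimals as in tabulated classification
#' reports, while the top-level rates keep full precision.
#'
#' @param fold_results a tibble/data frame with columns `y_true` and
#'   `y_pred` (e.g. from [loocv()]).
#' @return List of class `mkl_confusion`: `counts` (tibble TP/FN/TN/FP),
#'   `sensitivity`, `specificity`, `accuracy` (percent, full precision) and
#'   `report` (tibble rounded to 2 decimals).
#' @export
confusion_metrics <- function(fold_results) {
  y <- fold_results$y_true
  p <- fold_results$y_pred
  if (length(y) == 0L) stop_neuromkl("empty fold results")
  if (!any(y == 1) || !any(y == -1)) stop_neuromkl("need at least one subject of each class")
  TP <- sum(y == 1 & p == 1); FN <- sum(y == 1 & p == -1)
  TN <- sum(y == -1 & p == -1); FP <- sum(y == -1 & p == 1)
  sens <- 100 * TP / (TP + FN)
  spec <- 100 * TN / (TN + FP)
  acc <- 100 * (TP + TN) / length(y)
  structure(list(counts = tibble::tibble(TP = TP, FN = FN, TN = TN, FP = FP),
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 report = tibble::tibble(SEN = round_half_up(sens),
                                         SPE = round_half_up(spec),
                                         ACC = round_half_up(acc))),
            class = "mkl_confusion")
}

#' @export
print.mkl_confusion <- function(x, ...) {
  cat(sprintf("<mkl_confusion> TP=%d FN=%d TN=%d FP=%d | SEN %.2f%% SPE %.2f%% ACC %.2f%%\n",
              x$counts$TP, x$counts$FN, x$counts$TN, x$counts$FP,
              x$report$SEN, x$report$SPE, x$report$ACC))
  invisible(x)
}

#' ROC curve and AUC from pooled decision values
#'
#' The ROC sweeps a threshold over the pooled decision values (ties
#' grouped, predict +1 when `decision >= threshold`). The AUC is the
#' Mann-Whitney statistic: the fraction of patient-control pairs where the
#' patient's decision value is larger, counting ties as 1/2.
#'
#' @param decision numeric decision values.
#' @param labels labels in \{-1, +1\}, both classes present.
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`, monotone
#'   non-decreasing in both coordinates) and `auc` in `[0, 1]`.
#' @export
roc_auc <- function(decision, labels) {
  labels <- as.numeric(labels)
  if (!any(labels == 1) || !any(labels == -1)) {
    stop_neuromkl("labels must contain both classes")
  }
  n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
  r <- rank(decision)  # average ranks handle ties -> half-credit pairs
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(decision), decreasing = TRUE)
  pts <- purrr::map(thr, function(t) {
    pred_pos <- decision >= t
    c(fpr = sum(pred_pos & labels == -1) / n_neg,
      tpr = sum(pred_pos & labels == 1) / n_pos)
  })
  roc <- tibble::tibble(threshold = c(Inf, thr),
                        fpr = c(0, purrr::map_dbl(pts, "fpr")),
                        tpr = c(0, purrr::map_dbl(pts, "tpr")))
  list(roc = roc, auc = auc)
}

#' Full metrics report for a set of fold results
#'
#' Combines [confusion_metrics()] and [roc_auc()] into one object with
#' broom-style [tidy()]/[glance()] methods and an [autoplot()] ROC curve.
#'
#' @param fold_results an `mkl_loocv` tibble (or any data frame with
#'   `y_true`, `y_pred`, `decision`).
#' @param comparison optional label naming the comparison (e.g.
#'   `"patients-vs-controls"`).
#' @return An object of class `mkl_metrics`.
#' @export
metrics_report <- function(fold_results, comparison = NA_character_) {
  cm <- confusion_metrics(fold_results)
  ra <- roc_auc(fold_results$decision, fold_results$y_true)
  structure(list(comparison = comparison, confusion = cm, roc = ra$roc,
                 auc = ra$auc, n = nrow(fold_results)),
            class = "mkl_metrics")
}

#' @export
print.mkl_metrics <- function(x, ...) {
  cat(sprintf("<mkl_metrics>%s n = %d | SEN %.2f%% SPE %.2f%% ACC %.2f%% AUC %.2f\n",
              if (is.na(x$comparison)) "" else paste0(" ", x$comparison),
              x$n, x$confusion$report$SEN, x$confusion$report$SPE,
              x$confusion$report$ACC, x$auc))
  invisible(x)
}

#' Accuracy gain of the combined classifier over the best single feature
#'
#' @param combined_accuracy accuracy (percent) of the multi-kernel
#'   classifier.
#' @param single_accuracies accuracies (percent) of the single-feature
#'   classifiers.
#' @return Difference in percentage points: `combined - max(single)`.
#' @export
improvement_over_best_single <- function(combined_accuracy, single_accuracies) {
  if (length(single_accuracies) < 1L) stop_neuromkl("need at least one single-feature accuracy")
  combined_accuracy - max(single_accuracies)
}
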