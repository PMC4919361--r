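#' Linear Gram matrix of a feature matrix
#'
#' Entry (i, j) is the inner product of subject rows i and j; symmetric and
#' positive semidefinite by construction.
#'
#' @param X subjects-by-voxels matrix.
#' @return n x n Gram matrix.
#' @export
linear_gram <- function(X) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) < 1L) stop_neuromkl("need at least one row")
  tcrossprod(unclass(X))
}

#' Bundle per-feature Gram matrices with simplex weights
#'
#' @param kernels list of symmetric n x n Gram matrices.
#' @param beta non-negative weights summing to 1 (default uniform).
#' @return A `kernel_set`.
#' @export
kernel_set <- function(kernels, beta = rep(1 / length(kernels), length(kernels))) {
  n <- unique(purrr::map_int(kernels, nrow))
  if (length(n) != 1L) stop_neuromkl("kernels must share dimensions")
  for (k in kernels) {
    if (max(abs(k - t(k))) > 1e-10) stop_neuromkl("kernel matrix is not symmetric")
  }
  check_simplex(beta, length(kernels))
  structure(list(kernels = kernels, beta = as.numeric(beta)), class = "kernel_set")
}

check_simplex <- function(beta, F_expected = length(beta), tol = 1e-10) {
  if (length(beta) != F_expected || any(beta < -tol) || abs(sum(beta) - 1) > tol) {
    stop_neuromkl("kernel weights must be non-negative and sum to 1")
  }
  invisible(beta)
}

#' Simplex-weighted combination of Gram matrices
#'
#' Entrywise weighted sum `sum_f beta_f k_f`.
#'
#' @param kset a [kernel_set()].
#' @return Combined n x n Gram matrix.
#' @export
combine_kernels <- function(kset) {
  stopifnot(inherits(kset, "kernel_set"))
  check_simplex(kset$beta)
  Reduce(`+`, purrr::map2(kset$kernels, kset$beta, `*`))
}

#' Solve the soft-margin SVM dual on a precomputed kernel
#'
#' Maximizes `sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j K_ij` subject to
#' `sum_i a_i y_i = 0` and `0 <= a_i <= C`, by compiled sequential minimal
#' optimization. The bias is the KKT average over unbounded support vectors
#' (`1e-6 < a_i < C - 1e-6`); if none exist, the midpoint of the final
#' violating-pair bounds is used.
#'
#' @param gram symmetric PSD n x n kernel matrix.
#' @param y labels in \{-1, +1\}, both classes present.
#' @param C box constraint, > 0.
#' @param tol KKT stopping tolerance of the pair selection.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param alpha0 optional feasible warm start.
#' @return List with `alpha`, `b`, `objective` (dual value), `iterations`,
#'   `support` (indices with `a_i > 1e-8`), and the decision values `fitted`
#'   on the training points.
#' @export
solve_svm_dual <- function(gram, y, C, tol = 1e-8, max_iter = 1000000L,
                           alpha0 = NULL) {
  n <- nrow(gram)
  y <- as.numeric(y)
  if (length(y) != n) stop_neuromkl("label length does not match kernel")
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop_neuromkl("labels must contain both classes, coded -1/+1")
  }
  check_scalar(C, "C", lower = 1e-12)
  if (is.null(alpha0)) alpha0 <- rep(0, n)
  res <- smo_solve(gram, y, C, tol, as.integer(max_iter), alpha0)
  if (!res$converged) {
    stop_neuromkl(sprintf(
      "SVM dual solver did not converge in %d iterations (KKT violation %.3e)",
      max_iter, res$kkt_violation))
  }
  alpha <- res$alpha
  G <- res$grad
  free <- alpha > 1e-6 & alpha < C - 1e-6
  if (any(free)) {
    b <- mean(-y[free] * G[free])
  } else {
    up <- ifelse(y > 0, alpha < C, alpha > 0)
    lo <- ifelse(y > 0, alpha > 0, alpha < C)
    v <- -y * G
    b <- (max(v[up]) + min(v[lo])) / 2
  }
  objective <- 0.5 * (sum(alpha) - sum(alpha * G))
  fitted <- drop(gram %*% (alpha * y)) + b
  list(alpha = alpha, b = b, objective = objective,
       iterations = res$iterations, support = which(alpha > 1e-8),
       fitted = fitted)
}

#' Fit a multi-kernel linear SVM by alternating optimization
#'
#' Learns simplex-constrained kernel weights `beta` jointly with the SVM:
#' starting from uniform weights, the fit alternates (i) a full SVM dual
#' solve on the beta-combined kernel and (ii) a descent step on `beta` over
#' the probability simplex. The descent uses the gradient of the optimal-
#' value function, whose components are
#' `-1/2 sum_ij a_i a_j y_i y_j k_f(i, j)`, followed by a golden-section
#' line search along the simplex-projected path (projection keeps `beta`
#' exactly feasible). The alternation stops when the largest weight change
#' and the relative objective decrease both fall below `tol`, or after
#' `max_outer` rounds.
#'
#' @param kernels list of F symmetric n x n Gram matrices (one per feature).
#' @param y labels in \{-1, +1\}.
#' @param C box constraint (default 100, fixed across all fits).
#' @param tol convergence tolerance on both `max |d beta|` and the relative
#'   objective change.
#' @param max_outer cap on alternation rounds.
#' @param precondition divide each Gram by its mean diagonal before
#'   weighting, so kernels of differently scaled features compete on an
#'   even footing and the learned weights are comparable.
#' @param svm_tol KKT tolerance of the inner dual solver.
#' @return An `mkl_svm` model: `alpha`, `b`, `beta`, `y`, `C`, kernel
#'   `scales`, `support`, training `slacks`, and `diagnostics` (outer
#'   iterations, objective trajectory, final relative duality gap).
#' @export
fit_mkl <- function(kernels, y, C = 100, tol = 1e-4, max_outer = 100L,
                    precondition = TRUE, svm_tol = 1e-8) {
  if (!is.list(kernels) || length(kernels) < 1L) stop_neuromkl("`kernels` must be a non-empty list")
  F_k <- length(kernels)
  n <- nrow(kernels[[1]])
  scales <- rep(1, F_k)
  if (precondition) {
    scales <- purrr::map_dbl(kernels, ~ mean(diag(.x)))
    scales[scales <= 1e-300] <- 1
    kernels <- purrr::map2(kernels, scales, `/`)
  }
  beta <- rep(1 / F_k, F_k)
  combine <- function(b) Reduce(`+`, purrr::map2(kernels, b, `*`))

  fit <- solve_svm_dual(combine(beta), y, C, tol = svm_tol, alpha0 = NULL)
  objective <- fit$objective
  trajectory <- objective
  outer_iter <- 0L
  if (F_k > 1L) {
    for (it in seq_len(max_outer)) {
      outer_iter <- it
      ay <- fit$alpha * y
      grad <- unname(purrr::map_dbl(kernels, ~ -0.5 * drop(crossprod(ay, .x %*% ay))))
      dirn <- grad - mean(grad)
      if (max(abs(dirn)) < 1e-14) break
      t_max <- 2 / max(abs(dirn))
      eval_t <- function(t) {
        bt <- project_simplex(beta - t * grad)
        st <- solve_svm_dual(combine(bt), y, C, tol = svm_tol, alpha0 = fit$alpha)
        list(beta = bt, fit = st, J = st$objective)
      }
      best <- golden_section(eval_t, 0, t_max, n_eval = 24L)
      if (!is.finite(best$J)) stop_neuromkl("non-finite objective during kernel-weight search")
      improvement <- objective - best$J
      delta_beta <- max(abs(best$beta - beta))
      if (improvement > 0) {
        beta <- best$beta
        fit <- best$fit
        objective <- best$J
      }
      trajectory <- c(trajectory, objective)
      if (delta_beta < tol || improvement < tol * (1 + abs(objective))) break
    }
  }

  Kb <- combine(beta)
  fitted <- drop(Kb %*% (fit$alpha * y)) + fit$b
  slacks <- pmax(0, 1 - y * fitted)
  primal <- 0.5 * drop(crossprod(fit$alpha * y, Kb %*% (fit$alpha * y))) + C * sum(slacks)
  gap <- abs(primal - objective) / (1 + abs(objective))

  structure(list(alpha = fit$alpha, b = fit$b, beta = beta, y = as.numeric(y),
                 C = C, scales = scales, support = fit$support,
                 slacks = slacks, fitted = fitted, n = n,
                 kernel_names = names(kernels) %||% paste0("k", seq_len(F_k)),
                 diagnostics = list(outer_iterations = outer_iter,
                                    objective = objective,
                                    trajectory = trajectory,
                                    duality_gap = gap)),
            class = "mkl_svm")
}

# Golden-section minimisation of f over [lo, hi]; f returns a list with $J.
# The endpoint and midpoint candidates are kept so a non-unimodal section
# still returns the best probed point.
golden_section <- function(f, lo, hi, n_eval = 24L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  best <- if (f1$J <= f2$J) f1 else f2
  for (i in seq_len(n_eval - 2L)) {
    if (f1$J <= f2$J) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
    cand <- if (f1$J <= f2$J) f1 else f2
    if (cand$J < best$J) best <- cand
  }
  f0 <- f(lo)
  if (f0$J <= best$J) best <- f0
  best
}

#' @export
print.mkl_svm <- function(x, ...) {
  cat(sprintf("<mkl_svm> n = %d, C = %g, %d kernels, beta = (%s)\n", x$n, x$C,
              length(x$beta), paste(sprintf("%.3f", x$beta), collapse = ", ")))
  cat(sprintf("  objective %.6g after %d outer iterations, duality gap %.2e, %d support vectors\n",
              x$diagnostics$objective, x$diagnostics$outer_iterations,
              x$diagnostics$duality_gap, length(x$support)))
  invisible(x)
}

#' Decision value of a test sample from its kernel columns
#'
#' `f(x) = sum_i a_i y_i sum_f beta_f k_f(x_i, x) + b`; the columns are raw
#' kernel evaluations against the training samples and are rescaled
#' internally with the preconditioning factors stored in the model.
#'
#' @param model an `mkl_svm`.
#' @param test_columns list of F numeric vectors (length n) of kernel values
#'   `k_f(x_i, x)`, in training order; a single matrix n x F also works.
#' @return Scalar decision value.
#' @export
decision_function <- function(model, test_columns) {
  if (is.matrix(test_columns)) {
    test_columns <- purrr::map(seq_len(ncol(test_columns)), ~ test_columns[, .x])
  }
  if (length(test_columns) != length(model$beta)) {
    stop_neuromkl("number of kernel columns does not match the model")
  }
  ay <- model$alpha * model$y
  acc <- 0
  for (f in seq_along(test_columns)) {
    col <- test_columns[[f]]
    if (length(col) != model$n) stop_neuromkl("kernel column length does not match training size")
    acc <- acc + model$beta[f] * sum(ay * col / model$scales[f])
  }
  unname(acc + model$b)
}

#' Predict the class label of a test sample
#'
#' Sign of the decision value, with the tie `f(x) = 0` assigned to the
#' patient class (+1).
#'
#' @inheritParams decision_function
#' @return Label -1 or +1.
#' @export
predict_label <- function(model, test_columns) {
  d <- decision_function(model, test_columns)
  if (d >= 0) 1 else -1
}

#' Effective per-feature primal weight vectors of a linear MKL model
#'
#' For linear kernels the decision function decomposes voxelwise:
#' `f(x) = sum_f <w^(f), x^(f)> + b` with
#' `w^(f) = beta_f / s_f * sum_i a_i y_i x_i^(f)`, where `s_f` is the
#' kernel preconditioning scale. The weights therefore already include the
#' kernel weight, so a feature with `beta_f = 0` has an all-zero vector.
#'
#' @param model an `mkl_svm` fitted on linear Grams of `feature_matrices`.
#' @param feature_matrices list of F matrices (training rows, same order as
#'   the kernels passed to [fit_mkl()]).
#' @return Named list of numeric weight vectors, one per feature.
#' @export
extract_weight_vectors <- function(model, feature_matrices) {
  if (length(feature_matrices) != length(model$beta)) {
    stop_neuromkl("number of feature matrices does not match the model")
  }
  ay <- model$alpha * model$y
  w <- purrr::imap(feature_matrices, function(X, f) {
    i <- if (is.character(f)) match(f, names(feature_matrices)) else f
    if (nrow(X) != model$n) stop_neuromkl("feature matrix rows do not match training size")
    unname(model$beta[i] / model$scales[i]) * drop(crossprod(unclass(X), ay))
  })
  names(w) <- names(feature_matrices) %||% model$kernel_names
  w
}
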