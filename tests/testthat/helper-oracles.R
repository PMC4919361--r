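# Independent oracles and small fixture builders used across the suite.
# Every oracle is written from the definition, not by calling the package.

# Kendall's coefficient of concordance by explicit counting: ranks computed
# by counting smaller values (plus half-credit for ties), then the raw
# sum-of-squares form.
oracle_kendall_w <- function(m) {
  K <- nrow(m); n <- ncol(m)
  ranks <- matrix(0, K, n)
  for (i in seq_len(K)) {
    for (t in seq_len(n)) {
      ranks[i, t] <- sum(m[i, ] < m[i, t]) + (sum(m[i, ] == m[i, t]) + 1) / 2
    }
  }
  R <- colSums(ranks)
  12 * sum((R - mean(R))^2) / (K^2 * (n^3 - n))
}

# Single-sided DFT amplitude at bin k by direct summation.
oracle_dft_amplitude <- function(x, k) {
  n <- length(x)
  t <- 0:(n - 1)
  re <- sum(x * cos(-2 * pi * k * t / n))
  im <- sum(x * sin(-2 * pi * k * t / n))
  2 * sqrt(re^2 + im^2) / n
}

# Generic interior-point QP solve of the SVM dual (kernlab::ipop), returning
# alpha and the dual objective max sum(a) - 1/2 a' Q a.
oracle_qp_svm <- function(K, y, C) {
  Q <- outer(y, y) * K
  sol <- kernlab::ipop(c = rep(-1, length(y)), H = Q, A = matrix(y, 1),
                       b = 0, l = rep(0, length(y)), u = rep(C, length(y)),
                       r = 0, sigf = 9, maxiter = 200)
  alpha <- kernlab::primal(sol)
  list(alpha = alpha,
       objective = sum(alpha) - 0.5 * drop(crossprod(alpha, Q %*% alpha)))
}

# AUC by exhaustive pair counting with half-credit ties.
oracle_auc_pairs <- function(decision, labels) {
  dp <- decision[labels == 1]
  dn <- decision[labels == -1]
  tot <- 0
  for (a in dp) for (b in dn) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(dp) * length(dn))
}

# A small, fast cohort configuration for unit tests (full study scale is
# exercised in the acceptance suite).
small_config <- function(seed, effects = list(), n_pos = 5, n_neg = 5,
                         grid = c(6L, 6L, 6L), n_volumes = 64L, n_discard = 4L) {
  cohort_config(n_pos = n_pos, n_neg = n_neg, grid_dims = grid, voxel_size = 3,
                tr = 2, n_volumes = n_volumes, n_discard = n_discard,
                effects = effects, noise_sd = 1, seed = seed)
}

# Per-seed volume-only study-scale runs shared by the weight-recovery and
# map-enrichment acceptance checks; computed once per test session.
.volume_only_cache <- new.env(parent = emptyenv())
volume_only_runs <- function(n_seeds = 20L) {
  key <- paste0("runs", n_seeds)
  if (!is.null(.volume_only_cache[[key]])) return(.volume_only_cache[[key]])
  runs <- lapply(seq_len(n_seeds), function(seed) {
    cfg <- default_cohort_config(seed = seed,
                                 effect_sizes = c(volume = 1, amplitude = 0,
                                                  synchrony = 0))
    coh <- generate_cohort(cfg)
    mask <- cohort_mask(cfg)
    fm <- extract_features(coh, mask)
    labels <- participants(coh)$label
    fr <- loocv(fm, labels)
    full <- suppressWarnings(fit_full_and_map(fm, labels, mask))
    box <- array(FALSE, dim = cfg$grid_dims)
    bx <- cfg$effects[[1]]$box
    box[bx[1, 1]:bx[1, 2], bx[2, 1]:bx[2, 2], bx[3, 1]:bx[3, 2]] <- TRUE
    ret <- full$maps$GMV$retained
    list(beta = full$beta,
         accuracy = confusion_metrics(fr)$accuracy / 100,
         frac_in = sum(ret & box) / sum(box),
         frac_out = sum(ret & !box) / sum(!box))
  })
  .volume_only_cache[[key]] <- runs
  runs
}

# Fold-results tibble realizing given confusion counts (patients +1 first).
fold_results_from_counts <- function(TP, FN, TN, FP) {
  tibble::tibble(
    y_true = c(rep(1, TP + FN), rep(-1, TN + FP)),
    y_pred = c(rep(1, TP), rep(-1, FN), rep(-1, TN), rep(1, FP)))
}
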