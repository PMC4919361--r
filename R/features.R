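#' Brain mask
#'
#' A boolean 3D grid selecting the `D` voxels that enter every feature
#' vector. All feature matrices produced by the package share a single fixed
#' linear ordering of the in-mask voxels (column-major, first axis fastest),
#' which makes discrimination maps invertible back to volumes.
#'
#' @param grid logical 3D array.
#' @return An object of class `brain_mask` with attribute `D` (number of
#'   `TRUE` voxels).
#' @export
brain_mask <- function(grid) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stop_neuromkl("`grid` must be a 3D array")
  }
  grid <- array(as.logical(grid), dim = dim(grid))
  D <- sum(grid)
  if (D < 1L) stop_neuromkl("mask must contain at least one voxel")
  structure(grid, class = "brain_mask", D = D)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, D = %d in-mask voxels\n",
              paste(dim(x), collapse = "x"), attr(x, "D")))
  invisible(x)
}

# Fixed in-mask voxel order shared by all features and subjects.
voxel_order <- function(mask) which(as.logical(mask))

#' Drop leading functional volumes
#'
#' Discards the first `n_discard` time points of a 4D series (scanner
#' magnetisation-equilibration volumes), preserving temporal order.
#'
#' @param functional 4D array, time on the last axis.
#' @param n_discard number of leading volumes to drop.
#' @return The truncated 4D array.
#' @export
discard_volumes <- function(functional, n_discard) {
  if (length(dim(functional)) != 4L) stop_neuromkl("`functional` must be a 4D array")
  n_t <- dim(functional)[4]
  if (n_discard >= n_t) {
    stop_neuromkl(sprintf("cannot discard %d of %d volumes", n_discard, n_t))
  }
  if (n_discard == 0L) return(functional)
  functional[, , , (n_discard + 1):n_t, drop = FALSE]
}

# Remove a least-squares linear trend from each column of a (time x series)
# matrix.
detrend_linear <- function(m) {
  n <- nrow(m)
  x <- seq_len(n) - (n + 1) / 2
  m <- sweep(m, 2, colMeans(m))
  slope <- crossprod(x, m) / sum(x * x)
  m - outer(x, drop(slope))
}

# In-band single-sided DFT bin indices (frequencies k/(n*tr), k = 1..n/2).
alff_bins <- function(n, tr, band) {
  nyquist <- 1 / (2 * tr)
  if (!(length(band) == 2L && band[1] >= 0 && band[1] < band[2] && band[2] <= nyquist + 1e-12)) {
    stop_neuromkl(sprintf("band [%g, %g] Hz must satisfy 0 <= lo < hi <= Nyquist (%g Hz)",
                          band[1], band[2], nyquist))
  }
  k <- seq_len(floor(n / 2))
  freq <- k / (n * tr)
  bins <- k[freq >= band[1] - 1e-12 & freq <= band[2] + 1e-12]
  if (length(bins) == 0L) {
    stop_neuromkl(sprintf(
      "no DFT bins fall in band [%g, %g] Hz at frequency resolution %g Hz",
      band[1], band[2], 1 / (n * tr)))
  }
  bins
}

#' Amplitude of low-frequency fluctuations of one time series
#'
#' Removes a linear trend, takes the discrete Fourier transform, converts to
#' single-sided amplitudes `a_k = 2 |X_k| / n`, and averages the amplitudes
#' over the bins whose frequencies `k/(n tr)` lie in `band` (inclusive). A
#' constant series has no fluctuation and returns 0.
#'
#' @param series numeric time series of length >= 4.
#' @param tr sampling interval in seconds.
#' @param band low/high band edges in Hz; the default 0.01-0.08 Hz is the
#'   conventional resting-state fluctuation band.
#' @return Non-negative scalar ALFF.
#' @export
compute_alff <- function(series, tr, band = c(0.01, 0.08)) {
  n <- length(series)
  if (n < 4L) stop_neuromkl("series must have at least 4 time points")
  bins <- alff_bins(n, tr, band)
  if (max(series) == min(series)) return(0)
  x <- detrend_linear(matrix(series, ncol = 1))
  amp <- 2 * Mod(fft(drop(x)))[bins + 1L] / n
  mean(amp)
}

#' Kendall's coefficient of concordance of a voxel neighborhood
#'
#' Ranks each of the `K` series over time (average ranks for ties), sums the
#' ranks at each time point (`R_t`), and returns
#' `W = 12 sum_t (R_t - R̄)^2 / (K^2 (n^3 - n))` with `R̄ = K (n + 1) / 2`.
#' No tie-correction term is applied in the denominator, matching the form
#' used by resting-state regional-homogeneity toolkits. If every series is
#' constant, `W = 0`.
#'
#' @param neighborhood numeric `K x n` matrix, one series per row, `K >= 2`
#'   series of `n >= 2` time points.
#' @return Concordance `W` in `[0, 1]`.
#' @export
compute_reho <- function(neighborhood) {
  if (!is.matrix(neighborhood)) stop_neuromkl("`neighborhood` must be a K x n matrix")
  K <- nrow(neighborhood)
  n <- ncol(neighborhood)
  if (K < 2L) stop_neuromkl("need at least 2 series")
  if (n < 2L) stop_neuromkl("need at least 2 time points")
  ranks <- t(apply(neighborhood, 1, rank))
  R_t <- colSums(ranks)
  S <- sum((R_t - K * (n + 1) / 2)^2)
  W <- 12 * S / (K^2 * (n^3 - n))
  min(max(W, 0), 1)
}

#' Separable Gaussian smoothing of a volume
#'
#' Convolves each spatial axis with a unit-sum Gaussian kernel of
#' `sigma = fwhm / (2 sqrt(2 ln 2))` (in mm, converted to voxels via
#' `voxel_size`), using half-sample mirror boundaries. Mirroring folds
#' kernel mass that would leave the grid back inside, so both the total sum
#' of the image and constant images are preserved exactly. `fwhm = 0`
#' returns the input unchanged. A 4D input is smoothed volume-by-volume over
#' its three spatial axes.
#'
#' @param volume 3D (or 4D) numeric array.
#' @param fwhm full width at half maximum in mm, >= 0.
#' @param voxel_size voxel edge length in mm (scalar or length 3).
#' @return Array of the same dimensions.
#' @export
smooth_gaussian <- function(volume, fwhm, voxel_size) {
  check_scalar(fwhm, "fwhm", lower = 0)
  if (fwhm == 0) return(volume)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  nd <- length(dim(volume))
  out <- volume
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    w <- exp(-((-r):r)^2 / (2 * s^2))
    w <- w / sum(w)
    out <- convolve_axis_mirror(out, w, axis, nd)
  }
  out
}

# 1D convolution along `axis` with half-sample mirror boundary handling.
convolve_axis_mirror <- function(arr, w, axis, nd) {
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  len <- d[1]
  m <- matrix(a, nrow = len)
  r <- (length(w) - 1L) / 2L
  # mirror index for positions 1-r .. len+r (half-sample reflection)
  idx <- (1 - r):(len + r)
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  idx <- ifelse(idx > len, 2L * len + 1L - idx, idx)
  # long kernels on short axes can reflect more than once
  while (any(idx < 1L | idx > len)) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > len, 2L * len + 1L - idx, idx)
  }
  pad <- m[idx, , drop = FALSE]
  res <- matrix(0, nrow = len, ncol = ncol(m))
  for (j in seq_along(w)) {
    res <- res + w[j] * pad[(seq_len(len)) + (j - 1L), , drop = FALSE]
  }
  a <- array(res, dim = d)
  aperm(a, order(perm))
}

# Divide a map by its within-mask mean (global-mean scaling). Leaves an
# all-zero map untouched.
scale_global_mean <- function(values, mask) {
  g <- mean(values[as.logical(mask)])
  if (!is.finite(g) || g <= 0) return(values)
  out <- values / g
  out[!as.logical(mask)] <- 0
  out
}

new_feature_map <- function(values, feature, subject_id = NA_character_) {
  structure(list(subject_id = subject_id, feature = feature, values = values),
            class = "feature_map")
}

#' Voxelwise ALFF map
#'
#' Applies [compute_alff()] to every in-mask voxel (after optional spatial
#' smoothing of each functional volume, done before the spectral analysis),
#' then divides by the within-mask global mean so the map has unit in-mask
#' mean. Out-of-mask voxels are 0.
#'
#' @param functional 4D array (already truncated of discard volumes).
#' @param tr sampling interval, s.
#' @param band frequency band in Hz.
#' @param mask a [brain_mask()].
#' @param fwhm smoothing FWHM in mm applied to each volume before ALFF
#'   (0 = none).
#' @param voxel_size voxel size in mm (needed when `fwhm > 0`).
#' @param subject_id optional identifier carried in the result.
#' @return A `feature_map` (feature `"ALFF"`).
#' @export
alff_map <- function(functional, tr, band = c(0.01, 0.08), mask, fwhm = 0,
                     voxel_size = NULL, subject_id = NA_character_) {
  dims <- dim(functional)[1:3]
  if (!all(dims == dim(mask))) stop_neuromkl("functional and mask dims differ")
  if (fwhm > 0) functional <- smooth_gaussian(functional, fwhm, voxel_size)
  n <- dim(functional)[4]
  bins <- alff_bins(n, tr, band)
  vox <- voxel_order(mask)
  m <- matrix(functional, nrow = prod(dims))[vox, , drop = FALSE]
  m <- detrend_linear(t(m))                      # time x voxels
  amp <- 2 * Mod(mvfft(m))[bins + 1L, , drop = FALSE] / n
  vals <- colMeans(amp)
  constant <- apply(m, 2, function(v) max(v) == min(v))
  vals[constant] <- 0
  out <- array(0, dim = dims)
  out[vox] <- vals
  new_feature_map(scale_global_mean(out, mask), "ALFF", subject_id)
}

#' Voxelwise regional-homogeneity (ReHo) map
#'
#' For every in-mask voxel, Kendall's W over the 3x3x3 neighborhood
#' intersected with the mask (edge and partial neighborhoods use however
#' many in-mask series exist; fewer than 2 gives 0). The map can then be
#' smoothed (`fwhm`), and is finally divided by its within-mask global mean.
#'
#' @param functional 4D array (already truncated of discard volumes);
#'   ReHo is conventionally computed on unsmoothed series.
#' @param mask a [brain_mask()].
#' @param fwhm FWHM in mm for smoothing the finished W map (0 = none).
#' @param voxel_size voxel size in mm (needed when `fwhm > 0`).
#' @param subject_id optional identifier carried in the result.
#' @return A `feature_map` (feature `"ReHo"`).
#' @export
reho_map <- function(functional, mask, fwhm = 0, voxel_size = NULL,
                     subject_id = NA_character_) {
  dims <- dim(functional)[1:3]
  if (!all(dims == dim(mask))) stop_neuromkl("functional and mask dims differ")
  n <- dim(functional)[4]
  if (n < 2L) stop_neuromkl("need at least 2 time points after discarding")
  mlog <- array(as.logical(mask), dim = dims)
  if (!any(mlog)) stop_neuromkl("empty mask")

  # rank every in-mask voxel's series over time once
  nvox <- prod(dims)
  vox <- which(mlog)
  series <- matrix(functional, nrow = nvox)[vox, , drop = FALSE]
  flat <- matrix(0, nvox, n)
  flat[vox, ] <- t(apply(series, 1, rank))

  # accumulate rank sums and neighbor counts over the 27 offsets, on the
  # flattened grid (linear-index shifts are much cheaper than 4D slicing)
  S <- matrix(0, nvox, n)
  Kc <- numeric(nvox)
  msk_num <- as.numeric(mlog)
  lin_idx <- function(sx, sy, sz) {
    as.vector(outer(outer(sx, (sy - 1L) * dims[1], `+`),
                    (sz - 1L) * dims[1] * dims[2], `+`))
  }
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- shift_range(dims[1], dx); sy <- shift_range(dims[2], dy)
    sz <- shift_range(dims[3], dz)
    dst <- lin_idx(sx$dst, sy$dst, sz$dst)
    src <- lin_idx(sx$src, sy$src, sz$src)
    S[dst, ] <- S[dst, ] + flat[src, ]
    Kc[dst] <- Kc[dst] + msk_num[src]
  }

  Kv <- Kc[vox]
  Sm <- S[vox, , drop = FALSE]
  dev2 <- rowSums((Sm - Kv * (n + 1) / 2)^2)
  W <- 12 * dev2 / (Kv^2 * (n^3 - n))
  W[Kv < 2] <- 0
  W <- pmin(pmax(W, 0), 1)

  out <- array(0, dim = dims)
  out[vox] <- W
  if (fwhm > 0) {
    out <- smooth_gaussian(out, fwhm, voxel_size)
    out[!mlog] <- 0
  }
  new_feature_map(scale_global_mean(out, mask), "ReHo", subject_id)
}

shift_range <- function(len, d) {
  if (d >= 0) list(dst = (1 + d):len, src = 1:(len - d))
  else list(dst = 1:(len + d), src = (1 - d):len)
}

#' Structural (gray-matter-volume) feature map
#'
#' Wraps a structural volume as a feature map; values outside the mask are
#' zeroed. No global-mean scaling is applied: volume estimates are kept on
#' their native modulated scale (z-scoring later removes scale anyway).
#'
#' @param structural 3D array.
#' @param mask a [brain_mask()].
#' @param subject_id optional identifier.
#' @return A `feature_map` (feature `"GMV"`).
#' @export
gmv_map <- function(structural, mask, subject_id = NA_character_) {
  if (!all(dim(structural) == dim(mask))) stop_neuromkl("structural and mask dims differ")
  out <- structural
  out[!as.logical(mask)] <- 0
  new_feature_map(out, "GMV", subject_id)
}

#' Stack per-subject feature maps into a subjects-by-voxels matrix
#'
#' Row `i` holds subject `i`'s in-mask values in the single fixed voxel
#' order shared by every feature (column-major, first axis fastest).
#'
#' @param maps list of `feature_map`s with a common feature name.
#' @param mask a [brain_mask()].
#' @return A `feature_matrix`: numeric matrix with attributes `feature`,
#'   `subject_ids`, `dims` and `vox` (the voxel order).
#' @export
vectorize <- function(maps, mask) {
  feats <- unique(purrr::map_chr(maps, "feature"))
  if (length(feats) != 1L) stop_neuromkl("all maps must share one feature name")
  vox <- voxel_order(mask)
  rows <- purrr::map(maps, function(mp) {
    if (!all(dim(mp$values) == dim(mask))) stop_neuromkl("map dims do not match mask")
    mp$values[vox]
  })
  X <- do.call(rbind, rows)
  structure(X, feature = feats, subject_ids = purrr::map_chr(maps, "subject_id"),
            dims = dim(mask), vox = vox, class = c("feature_matrix", "matrix", "array"))
}

#' Scatter a voxel vector back into a 3D volume
#'
#' Inverse of the in-mask vectorization: out-of-mask voxels are 0.
#'
#' @param v numeric vector of length `D`.
#' @param mask a [brain_mask()].
#' @return 3D array.
#' @export
map_from_vector <- function(v, mask) {
  vox <- voxel_order(mask)
  if (length(v) != length(vox)) {
    stop_neuromkl(sprintf("vector length %d does not match mask D = %d",
                          length(v), length(vox)))
  }
  out <- array(0, dim = dim(mask))
  out[vox] <- v
  out
}

#' Fit per-voxel z-score normalization on designated training rows
#'
#' Means and standard deviations (population convention, divide by n) are
#' estimated from `train_rows` only, so held-out subjects are transformed
#' with training statistics and no information leaks across
#' cross-validation folds. Columns that are constant on the training rows
#' are flagged and mapped to 0 everywhere.
#'
#' @param X a `feature_matrix` (or plain matrix).
#' @param train_rows integer row indices (>= 2 rows).
#' @return A `zscore_params` object (`mean`, `sd`, `constant` flags).
#' @export
zscore_fit <- function(X, train_rows = seq_len(nrow(X))) {
  if (length(train_rows) < 2L) stop_neuromkl("need at least 2 training rows")
  Xt <- X[train_rows, , drop = FALSE]
  mu <- colMeans(Xt)
  s <- sqrt(colMeans(Xt^2) - mu^2)
  s[s < 0] <- 0
  constant <- s <= 1e-12
  s[constant] <- 1
  structure(list(mean = mu, sd = s, constant = constant), class = "zscore_params")
}

#' Apply fitted z-score normalization
#'
#' @param X matrix with the same column count as the fitted matrix.
#' @param params a `zscore_params` from [zscore_fit()].
#' @return Matrix of z-scores; constant training columns are all 0.
#' @export
zscore_apply <- function(X, params) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(params$mean)) stop_neuromkl("column count does not match fitted params")
  Z <- sweep(sweep(X, 2, params$mean), 2, params$sd, `/`)
  if (any(params$constant)) Z[, params$constant] <- 0
  Z
}
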