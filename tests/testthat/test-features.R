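test_that("ALFF of simple spectra matches direct DFT summation", {
  n <- 190; tr <- 2
  # constant input has no fluctuation
  expect_identical(compute_alff(rep(3.7, n), tr), 0)
  # sinusoid at an exact in-band DFT bin, phased symmetrically about the
  # series midpoint so linear detrending is an exact no-op: amplitude A at
  # one in-band bin, zero elsewhere, so the band average is A / n_bins
  A <- 2.5
  t_idx <- 0:(n - 1)
  k <- 19                       # 19 / (190 * 2) = 0.05 Hz
  x <- A * cos(2 * pi * k * (t_idx - (n - 1) / 2) / n)
  bins <- which(vapply(1:95, function(j) {
    f <- j / (n * tr); f >= 0.01 - 1e-12 && f <= 0.08 + 1e-12
  }, TRUE))
  expected <- mean(vapply(bins, function(j) oracle_dft_amplitude(x, j), 0))
  expect_equal(compute_alff(x, tr), expected, tolerance = 1e-10)
  expect_equal(expected, A / length(bins), tolerance = 1e-8)
  # out-of-band sinusoid at an exact bin leaks nothing into the band
  x_out <- A * cos(2 * pi * 76 * (t_idx - (n - 1) / 2) / n)  # 76/380 = 0.2 Hz
  expect_lt(compute_alff(x_out, tr), 1e-8 * A)
})

test_that("ALFF is offset-invariant and amplitude-linear", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(100)
    a <- compute_alff(x, 2)
    expect_equal(compute_alff(x + 17.3, 2), a, tolerance = 1e-10)
    expect_equal(compute_alff(3 * x, 2), 3 * a, tolerance = 1e-10)
  }
})

test_that("ALFF rejects bands without bins or beyond Nyquist", {
  expect_error(compute_alff(rnorm(20), tr = 2, band = c(0.001, 0.005)),
               "frequency resolution")
  expect_error(compute_alff(rnorm(20), tr = 2, band = c(0.01, 0.3)), "Nyquist")
})

test_that("ReHo matches a brute-force concordance oracle and its exact cases", {
  # perfect concordance: 27 identical non-constant series
  s <- sin(seq(0, 3, length.out = 15))
  expect_equal(compute_reho(matrix(rep(s, 27), nrow = 27, byrow = TRUE)), 1,
               tolerance = 1e-12)
  # perfectly anti-ordered pair: rank sums constant over time
  expect_equal(compute_reho(rbind(c(1, 2, 3), c(3, 2, 1))), 0)
  # all-constant neighborhood has no concordance signal
  expect_equal(compute_reho(matrix(1, 5, 8)), 0)
  set.seed(7)
  for (i in 1:50) {
    K <- sample(2:10, 1); n <- sample(3:20, 1)
    m <- matrix(rnorm(K * n), K, n)
    if (i %% 3 == 0) m[1, ] <- round(m[1, ])   # inject ties
    expect_equal(compute_reho(m), oracle_kendall_w(m), tolerance = 1e-12)
  }
})

test_that("ReHo map equals neighborhood-gathered Kendall's W, then unit mean", {
  set.seed(21)
  dims <- c(4L, 4L, 4L); n <- 12L
  fun <- array(rnorm(prod(dims) * n), dim = c(dims, n))
  mask <- brain_mask(array(TRUE, dim = dims))
  got <- reho_map(fun, mask)
  W <- array(0, dim = dims)
  for (x in 1:4) for (y in 1:4) for (z in 1:4) {
    xs <- max(1, x - 1):min(4, x + 1); ys <- max(1, y - 1):min(4, y + 1)
    zs <- max(1, z - 1):min(4, z + 1)
    nb <- matrix(fun[xs, ys, zs, ], ncol = n)
    W[x, y, z] <- oracle_kendall_w(nb)
  }
  expect_equal(got$values, W / mean(W), tolerance = 1e-12)
  expect_equal(mean(got$values), 1, tolerance = 1e-9)
})

test_that("ReHo map handles partial masks and identical-series fields", {
  dims <- c(5L, 5L, 5L); n <- 10L
  s <- cumsum(rnorm(n))
  fun <- array(rep(s, each = prod(dims)), dim = c(dims, n))
  mask <- brain_mask(array(TRUE, dim = dims))
  got <- reho_map(fun, mask)
  expect_equal(got$values[3, 3, 3], 1, tolerance = 1e-12)  # W=1 pre and post scaling
  # a mask leaving one voxel alone: no neighbor -> 0
  lone <- array(FALSE, dim = dims); lone[1, 1, 1] <- TRUE; lone[5, 5, 5] <- TRUE
  set.seed(1)
  fun2 <- array(rnorm(prod(dims) * n), dim = c(dims, n))
  got2 <- reho_map(fun2, brain_mask(lone))
  expect_equal(unname(got2$values[1, 1, 1]), 0)
  expect_error(reho_map(fun2, brain_mask(array(FALSE, dims))), "at least one voxel")
})

test_that("voxelwise ALFF map is consistent with the scalar operation", {
  set.seed(5)
  dims <- c(4L, 3L, 3L); n <- 32L
  fun <- array(rnorm(prod(dims) * n), dim = c(dims, n))
  mask <- brain_mask(array(TRUE, dim = dims))
  got <- alff_map(fun, tr = 2, mask = mask)
  ref <- array(0, dim = dims)
  for (x in 1:4) for (y in 1:3) for (z in 1:3) {
    ref[x, y, z] <- compute_alff(fun[x, y, z, ], tr = 2)
  }
  expect_equal(got$values, ref / mean(ref), tolerance = 1e-10)
  expect_equal(mean(got$values), 1, tolerance = 1e-9)
})

test_that("ALFF map noise level drops as the series lengthens", {
  dims <- c(6L, 6L, 6L)
  mask <- brain_mask(array(TRUE, dim = dims))
  cv <- function(n, seed) {
    set.seed(seed)
    fun <- array(rnorm(prod(dims) * n), dim = c(dims, n))
    v <- alff_map(fun, tr = 2, mask = mask)$values
    sd(v) / mean(v)
  }
  cv64 <- mean(vapply(1:20, function(s) cv(64, s), 0))
  cv256 <- mean(vapply(1:20, function(s) cv(256, s + 1000), 0))
  expect_lt(cv256, cv64)
})

test_that("Gaussian smoothing preserves mass, constants, and the kernel peak", {
  set.seed(9)
  vol <- array(runif(10 * 11 * 9), dim = c(10, 11, 9))
  expect_identical(smooth_gaussian(vol, 0, 3), vol)
  expect_error(smooth_gaussian(vol, -1, 3), "fwhm")
  sm <- smooth_gaussian(vol, 4, 3)
  expect_equal(sum(sm), sum(vol), tolerance = 1e-6)
  cst <- array(2.5, dim = c(6, 6, 6))
  expect_equal(smooth_gaussian(cst, 4, 3), cst, tolerance = 1e-12)
  # delta image: center value is the cubed peak of the normalized 1D kernel
  delta <- array(0, dim = c(11, 11, 11)); delta[6, 6, 6] <- 1
  sigma <- 4 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1, ceiling(4 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  got <- smooth_gaussian(delta, 4, 3)
  expect_equal(got[6, 6, 6], max(w)^3, tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)
})

test_that("leading-volume discarding preserves order and validates input", {
  fun <- array(seq_len(2 * 2 * 2 * 200), dim = c(2, 2, 2, 200))
  out <- discard_volumes(fun, 10)
  expect_equal(dim(out)[4], 190)
  expect_identical(out[, , , 1], fun[, , , 11])
  expect_identical(discard_volumes(fun, 0), fun)
  expect_error(discard_volumes(fun, 200), "cannot discard")
})

test_that("vectorization uses the shared in-mask order and inverts exactly", {
  grid <- array(c(3, 5), dim = c(2, 1, 1))
  mask_full <- brain_mask(array(TRUE, dim = c(2, 1, 1)))
  mp <- neuromkl:::new_feature_map(grid, "GMV", "s1")
  X <- vectorize(list(mp), mask_full)
  expect_equal(unname(X[1, ]), c(3, 5))
  mask_part <- brain_mask(array(c(FALSE, TRUE), dim = c(2, 1, 1)))
  Xp <- vectorize(list(mp), mask_part)
  expect_equal(unname(Xp[1, ]), 5)
  # round-trip through the volume and back
  set.seed(2)
  m3 <- array(runif(60), dim = c(5, 4, 3))
  msk <- brain_mask(array(runif(60) > 0.3, dim = c(5, 4, 3)))
  v <- m3[which(as.logical(msk))]
  expect_identical(map_from_vector(v, msk)[which(as.logical(msk))], v)
  mp2 <- neuromkl:::new_feature_map(map_from_vector(v, msk), "GMV", "s1")
  expect_identical(unname(vectorize(list(mp2), msk)[1, ]), v)
})

test_that("z-score normalization is train-fitted, population-scaled, leak-free", {
  X <- rbind(c(1, 7, 4), c(3, 7, 8), c(100, 7, -100))
  p <- zscore_fit(X, train_rows = 1:2)
  Z <- zscore_apply(X[1:2, ], p)
  expect_equal(colMeans(Z), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(Z[, 1]), c(-1, 1))   # population SD of (1,3) is 1
  expect_true(p$constant[2])
  expect_equal(unname(Z[, 2]), c(0, 0))
  # held-out row transformed with training statistics only
  z3 <- zscore_apply(X[3, , drop = FALSE], p)
  expect_equal(unname(z3[1, 1]), (100 - 2) / 1)
  expect_equal(unname(z3[1, 2]), 0)
  expect_error(zscore_fit(X, train_rows = 1), "2 training rows")
})
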