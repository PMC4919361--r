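test_that("linear Gram matrices are exact pairwise inner products", {
  X <- rbind(c(1, 0), c(0, 1))
  expect_equal(linear_gram(X), diag(2))
  set.seed(4)
  M <- matrix(rnorm(35), 5, 7)
  G <- linear_gram(M)
  ref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) ref[i, j] <- sum(M[i, ] * M[j, ])
  expect_equal(G, ref, tolerance = 1e-12)
  expect_equal(G, t(G))
  expect_true(all(diag(G) >= 0))
})

test_that("kernel combination is the entrywise simplex-weighted sum", {
  set.seed(8)
  ks <- lapply(1:3, function(i) { A <- matrix(rnorm(16), 4); A %*% t(A) })
  expect_equal(combine_kernels(kernel_set(ks, c(1, 0, 0))), ks[[1]])
  # identical kernels: any simplex weighting returns that kernel
  same <- kernel_set(list(ks[[1]], ks[[1]], ks[[1]]), c(0.2, 0.5, 0.3))
  expect_equal(combine_kernels(same), ks[[1]], tolerance = 1e-12)
  beta <- c(0.6, 0.1, 0.3)
  ref <- beta[1] * ks[[1]] + beta[2] * ks[[2]] + beta[3] * ks[[3]]
  expect_equal(combine_kernels(kernel_set(ks, beta)), ref, tolerance = 1e-12)
  expect_error(kernel_set(ks, c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("the SVM dual solves the separable two-point problem exactly", {
  X <- matrix(c(1, -1), ncol = 1)
  y <- c(1, -1)
  s <- solve_svm_dual(linear_gram(X), y, C = 100)
  expect_equal(s$alpha, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(s$b, 0, tolerance = 1e-8)
  # decision function is f(x) = x
  model <- fit_mkl(list(linear_gram(X)), y, C = 100, precondition = FALSE)
  for (x0 in c(-2, 0.3, 1.7)) {
    expect_equal(decision_function(model, list(drop(X) * x0)), x0,
                 tolerance = 1e-8)
  }
})

test_that("the SVM dual respects its constraints and matches a QP solver", {
  set.seed(10)
  for (i in 1:5) {
    n <- 10
    X <- matrix(rnorm(n * 3), n)
    y <- rep(c(1, -1), each = 5)
    K <- linear_gram(X)
    C <- 10
    s <- solve_svm_dual(K, y, C)
    expect_true(all(s$alpha >= -1e-10 & s$alpha <= C + 1e-10))
    expect_lt(abs(sum(s$alpha * y)), 1e-8 * C)
    o <- oracle_qp_svm(K, y, C)
    expect_equal(s$objective, o$objective, tolerance = 1e-6)
  }
  expect_error(solve_svm_dual(diag(3), c(1, 1, 1), 1), "both classes")
})

test_that("duplicating the training set leaves the decision function unchanged", {
  set.seed(11)
  n <- 8
  X <- matrix(rnorm(n * 2), n)
  y <- rep(c(1, -1), 4)
  Xtest <- matrix(rnorm(10), 5, 2)
  m1 <- fit_mkl(list(linear_gram(X)), y, C = 5, precondition = FALSE)
  m2 <- fit_mkl(list(linear_gram(rbind(X, X))), c(y, y), C = 5, precondition = FALSE)
  d1 <- apply(Xtest, 1, function(x0) decision_function(m1, list(drop(X %*% x0))))
  d2 <- apply(Xtest, 1, function(x0) decision_function(m2, list(drop(rbind(X, X) %*% x0))))
  expect_equal(d1, d2, tolerance = 1e-5)
})

test_that("degenerate and duplicated-kernel multi-kernel fits behave", {
  set.seed(12)
  X <- matrix(rnorm(20 * 6), 20)
  y <- rep(c(1, -1), 10)
  K <- linear_gram(X)
  single <- solve_svm_dual(K / mean(diag(K)), y, C = 100)
  m1 <- fit_mkl(list(K), y, C = 100)
  expect_equal(m1$beta, 1)
  expect_equal(m1$diagnostics$objective, single$objective, tolerance = 1e-8)
  expect_equal(m1$alpha, single$alpha, tolerance = 1e-6)
  # identical kernels: the objective cannot depend on the split
  m2 <- fit_mkl(list(K, K), y, C = 100)
  expect_equal(m2$diagnostics$objective, single$objective, tolerance = 1e-6)
  expect_equal(sum(m2$beta), 1, tolerance = 1e-12)
})

test_that("the alternating fit descends, stays on the simplex, and closes the gap", {
  set.seed(13)
  n <- 24
  y <- rep(c(1, -1), n / 2)
  ks <- lapply(1:3, function(f) {
    Xf <- matrix(rnorm(n * 15), n) + if (f == 1) 0.8 * y else 0
    linear_gram(Xf)
  })
  m <- fit_mkl(ks, y, C = 100)
  tr <- m$diagnostics$trajectory
  expect_true(all(diff(tr) <= 1e-8))
  expect_true(all(m$beta >= 0))
  expect_equal(sum(m$beta), 1, tolerance = 1e-12)
  expect_lt(m$diagnostics$duality_gap, 1e-4)
  # unbounded support vectors sit on the margin
  free <- which(m$alpha > 1e-6 & m$alpha < m$C - 1e-6)
  expect_true(length(free) > 0)
  expect_equal(m$y[free] * m$fitted[free], rep(1, length(free)), tolerance = 1e-6)
})

test_that("the informative kernel wins the weight competition", {
  wins <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 30; D <- 50
    y <- rep(c(1, -1), 15)
    X_info <- matrix(rnorm(n * D), n) + 0.6 * y
    X_noise <- matrix(rnorm(n * D), n)
    m <- fit_mkl(list(info = linear_gram(X_info), noise = linear_gram(X_noise)),
                 y, C = 100)
    m$beta[1] > m$beta[2]
  }, TRUE)
  expect_gte(sum(wins), 18)
})

test_that("training is perfect on separable data at large C", {
  set.seed(14)
  n <- 16
  y <- rep(c(1, -1), 8)
  X <- matrix(rnorm(n * 4), n) + 3 * y
  m <- fit_mkl(list(linear_gram(X)), y, C = 1e4, precondition = FALSE)
  expect_equal(sign(m$fitted), y)
  expect_equal(max(m$slacks), 0, tolerance = 1e-6)
})

test_that("dual decisions equal the explicit primal form for linear kernels", {
  set.seed(15)
  n <- 18
  y <- rep(c(1, -1), 9)
  Xs <- list(a = matrix(rnorm(n * 7), n) + 0.5 * y, b = matrix(rnorm(n * 5), n))
  m <- fit_mkl(lapply(Xs, linear_gram), y, C = 50)
  w <- extract_weight_vectors(m, Xs)
  for (i in 1:n) {
    d_dual <- decision_function(m, lapply(Xs, function(X) drop(X %*% X[i, ])))
    d_primal <- sum(w$a * Xs$a[i, ]) + sum(w$b * Xs$b[i, ]) + m$b
    expect_equal(d_primal, d_dual, tolerance = 1e-8)
  }
  # a zero-weight kernel contributes an all-zero weight vector
  if (any(m$beta == 0)) {
    f0 <- which(m$beta == 0)[1]
    expect_true(all(w[[f0]] == 0))
  }
  mzero <- m; mzero$beta <- c(1, 0)
  wz <- extract_weight_vectors(mzero, Xs)
  expect_true(all(wz$b == 0))
  # two-point toy recovers the unit primal weight
  toy <- fit_mkl(list(linear_gram(matrix(c(1, -1), ncol = 1))), c(1, -1),
                 C = 100, precondition = FALSE)
  expect_equal(extract_weight_vectors(toy, list(matrix(c(1, -1), ncol = 1)))[[1]],
               1, tolerance = 1e-8)
})

test_that("decision values track an off-the-shelf SVM on the combined kernel", {
  skip_if_not_installed("kernlab")
  cors <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 14
    y <- rep(c(1, -1), 7)
    X <- matrix(rnorm(n * 6), n) + 0.7 * y
    K <- linear_gram(X)
    m <- fit_mkl(list(K), y, C = 10, precondition = FALSE)
    ks <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = 10,
                        scaled = FALSE)
    d_ref <- kernlab::predict(ks, kernlab::as.kernelMatrix(K[, kernlab::SVindex(ks), drop = FALSE]),
                              type = "decision")
    suppressWarnings(abs(cor(m$fitted, drop(d_ref))))
  }, 0)
  expect_true(all(cors > 0.999))
})
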