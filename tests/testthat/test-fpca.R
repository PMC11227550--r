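test_that("univariate FPCA recovers a rank-1 construction exactly", {
  grid <- seq(0, 1, length.out = 9)
  w <- funmorph:::trapezoid_weights(grid)
  phi <- sin(2 * pi * grid) + 0.3
  phi <- phi / sqrt(sum(w * phi^2))          # unit norm under quadrature
  a <- withr::with_seed(111, stats::rnorm(12, sd = 2))
  values <- outer(a, phi)
  fit <- ufpca(values, grid, pve_threshold = 1)
  expect_equal(fit$eigenvalues[1], stats::var(a), tolerance = 1e-10)
  expect_lt(sum(fit$all_eigenvalues[-1]), 1e-10)
  s <- if (sum(fit$eigenfunctions[, 1] * phi * w) > 0) 1 else -1
  expect_equal(fit$scores[, 1], s * (a - mean(a)), tolerance = 1e-10)
})

test_that("eigenfunctions are orthonormal under the quadrature inner product", {
  grid <- seq(0, 1, length.out = 11)
  values <- withr::with_seed(112, matrix(stats::rnorm(8 * 11), 8, 11))
  fit <- ufpca(values, grid, pve_threshold = 1)
  w <- fit$weights
  gram <- t(fit$eigenfunctions) %*% (w * fit$eigenfunctions)
  expect_equal(gram, diag(ncol(fit$eigenfunctions)), tolerance = 1e-8)
  # score sample means vanish
  expect_lt(max(abs(colMeans(fit$scores))), 1e-8)
})

test_that("univariate eigenvalues match a dense weighted-covariance oracle", {
  grid <- seq(0, 1, length.out = 5)
  w <- funmorph:::trapezoid_weights(grid)
  values <- withr::with_seed(113, matrix(stats::rnorm(8 * 5), 8, 5))
  fit <- ufpca(values, grid, pve_threshold = 1)
  xc <- sweep(values, 2, colMeans(values))
  k <- crossprod(xc) / 7
  oracle <- eigen(diag(sqrt(w)) %*% k %*% diag(sqrt(w)), symmetric = TRUE)$values
  expect_equal(fit$all_eigenvalues, pmax(oracle, 0), tolerance = 1e-10)
})

test_that("threshold and degenerate handling behave as specified", {
  grid <- seq(0, 1, length.out = 6)
  values <- withr::with_seed(114, matrix(stats::rnorm(30), 5, 6))
  expect_error(ufpca(values, grid, pve_threshold = 0), class = "fm_usage_error")
  expect_error(ufpca(values, grid, pve_threshold = 1.2), class = "fm_usage_error")
  flat <- matrix(1, 5, 6)
  expect_message(fit <- ufpca(flat, grid, pve_threshold = 0.99))
  expect_equal(fit$n_retained, 1L)
  expect_equal(fit$eigenvalues, 0)
})

test_that("a duplicated element doubles the multivariate eigenvalues", {
  grid <- seq(0, 1, length.out = 7)
  values <- withr::with_seed(115, matrix(stats::rnorm(10 * 7), 10, 7))
  fd <- manual_fd(list(e1 = values, e2 = values), grid)
  fit <- mfpca(fd, pve_threshold = 1)
  u <- ufpca(values, grid, pve_threshold = 1)
  j <- u$n_retained
  lam <- sort(fit$all_eigenvalues, decreasing = TRUE)
  expect_equal(lam[seq_len(j)], 2 * u$eigenvalues, tolerance = 1e-10)
  expect_lt(max(abs(lam[-seq_len(j)])), 1e-10)
  # block structure [[S, S], [S, S]] and the direct dense eigen oracle
  s <- crossprod(u$scores) / 9
  z_oracle <- rbind(cbind(s, s), cbind(s, s))
  expect_equal(fit$block_cov, z_oracle, tolerance = 1e-10)
  expect_equal(fit$all_eigenvalues, pmax(eigen(z_oracle, symmetric = TRUE)$values, 0),
               tolerance = 1e-10)
})

test_that("the block score-covariance is symmetric positive semidefinite", {
  d <- random_landmarks(7, 10, seed = 116)
  fd <- to_functional(gpa(d))
  fit <- mfpca(fd, pve_threshold = 1)
  expect_equal(fit$block_cov, t(fit$block_cov), tolerance = 1e-12)
  expect_gt(min(eigen(fit$block_cov, symmetric = TRUE)$values), -1e-10)
})

test_that("full retention reproduces quadrature-weighted PCA of the concatenated data", {
  grid <- seq(0, 1, length.out = 4)
  withr::with_seed(117, {
    e1 <- matrix(stats::rnorm(24), 6, 4)
    e2 <- matrix(stats::rnorm(24), 6, 4)
  })
  fd <- manual_fd(list(e1 = e1, e2 = e2), grid)
  fit <- mfpca(fd, pve_threshold = 1)
  oracle <- concat_weighted_pca(list(e1, e2), fd$weights)
  keep <- seq_along(fit$eigenvalues)
  expect_equal(fit$eigenvalues, oracle$eigenvalues[keep], tolerance = 1e-8)
  # scores agree columnwise up to sign
  for (jj in which(fit$eigenvalues > 1e-10)) {
    got <- fit$scores_matrix[, jj]
    want <- oracle$scores[, jj]
    expect_equal(abs(sum(got * want)) / sqrt(sum(got^2) * sum(want^2)), 1, tolerance = 1e-8)
    expect_equal(sort(abs(got)), sort(abs(want)), tolerance = 1e-8)
  }
})

test_that("the truncated expansion reconstructs centred curves at full retention", {
  d <- random_landmarks(9, 8, seed = 118)
  fd <- to_functional(gpa(d))
  fit <- mfpca(fd, pve_threshold = 1)
  for (p in seq_along(fd$values)) {
    xc <- sweep(fd$values[[p]], 2, colMeans(fd$values[[p]]))
    recon <- fit$scores_matrix %*% t(fit$eigenfunctions[[p]])
    expect_lt(sqrt(mean((recon - xc)^2)), 1e-8)
  }
  # score covariance is diagonal with the eigenvalues on the diagonal
  cov_scores <- crossprod(fit$scores_matrix) / (fit$n - 1)
  expect_equal(unname(cov_scores), diag(fit$eigenvalues, length(fit$eigenvalues)),
               tolerance = 1e-8)
})

test_that("repeated decomposition of the same data is bit-stable", {
  d <- random_landmarks(6, 9, seed = 119)
  fd <- to_functional(gpa(d))
  f1 <- mfpca(fd)
  f2 <- mfpca(fd)
  expect_identical(f1$scores_matrix, f2$scores_matrix)
  expect_identical(f1$eigenvalues, f2$eigenvalues)
})

test_that("the multivariate estimator agrees with plain PCA for one element under unit weights", {
  values <- withr::with_seed(120, matrix(stats::rnorm(10 * 6), 10, 6))
  grid <- seq(0, 1, length.out = 6)
  fd <- manual_fd(list(e1 = values), grid)
  fd$weights[[1]] <- rep(1, 6)        # substitute uniform unit weights
  fit <- mfpca(fd, pve_threshold = 1)
  ev <- stats::prcomp(values)$sdev^2
  keep <- seq_along(fit$eigenvalues)
  expect_equal(fit$eigenvalues, ev[keep], tolerance = 1e-8)
})

test_that("classical PCA matches an SVD oracle and respects the rank bound", {
  m <- withr::with_seed(121, matrix(stats::rnorm(80), 10, 8))
  fit <- classical_pca(m)
  xc <- sweep(m, 2, colMeans(m))
  oracle <- svd(xc)$d^2 / 9
  expect_equal(fit$all_eigenvalues, oracle[seq_along(fit$all_eigenvalues)], tolerance = 1e-10)

  # centred data with a single varying specimen has exactly one component
  base <- matrix(0, 6, 8)
  base[1, ] <- 1; base <- sweep(base, 2, colMeans(base))
  fit1 <- classical_pca(base)
  expect_equal(length(fit1$all_eigenvalues), 1L)

  # n - 1 bound: more coordinates than specimens
  wide <- withr::with_seed(122, matrix(stats::rnorm(9 * 20), 9, 20))
  expect_lte(length(classical_pca(wide)$all_eigenvalues), 8L)
})

test_that("proportion of variance explained follows the cumulative-share convention", {
  expect_equal(pve(c(3, 1), 1), 0.75)
  ev <- withr::with_seed(123, sort(stats::runif(6), decreasing = TRUE))
  expect_equal(pve(ev, length(ev)), 1.0)
  oracle <- cumsum(ev) / sum(ev)
  for (k in seq_along(ev)) expect_equal(pve(ev, k), oracle[k], tolerance = 1e-14)
  expect_error(pve(c(0, 0), 1), class = "fm_undefined_error")
  expect_error(pve(ev, 9), class = "fm_usage_error")
})
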