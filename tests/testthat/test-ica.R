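test_that("column centering removes means and is invertible", {
  cc <- center_columns(matrix(c(1, 3, 2, 4), 2))
  expect_equal(cc$x, matrix(c(-1, 1, -1, 1), 2))
  expect_equal(cc$mean, c(2, 3))
  # idempotence
  cc2 <- center_columns(cc$x)
  expect_lt(max(abs(cc2$x - cc$x)), 1e-12)
  set.seed(4)
  X <- matrix(rnorm(100 * 16), 100)
  out <- center_columns(X)
  expect_lt(max(abs(colMeans(out$x))), 1e-10)
  expect_equal(sweep(out$x, 2, out$mean, `+`), X)
  expect_error(center_columns(matrix(1, 1, 3)), "at least 2")
})

test_that("PCA reduction finds the dominant axis of collinear data", {
  set.seed(1)
  t <- rnorm(200)
  X <- cbind(3 * t, 4 * t)            # perfect line, direction (3,4)/5
  cc <- center_columns(X)
  pr <- pca_reduce(cc$x, 1, whiten = FALSE)
  expect_equal(abs(sum(pr$K_pca * c(3, 4) / 5)), 1, tolerance = 1e-10)
  proj_var <- stats::var(drop(cc$x %*% t(pr$K_pca)))
  expect_equal(proj_var, sum(apply(X, 2, stats::var)), tolerance = 1e-10)
})

test_that("isotropic Gaussian eigenvalues agree within sampling tolerance", {
  set.seed(2)
  n <- 1e4
  X <- matrix(rnorm(2 * n), n)
  pr <- pca_reduce(center_columns(X)$x, 2, whiten = FALSE)
  expect_lt(abs(diff(pr$eigvals)), 3 * sqrt(2 / n) * pr$eigvals[1] * 2)
  expect_true(all(diff(pr$eigvals) <= 0))
})

test_that("whitening yields identity covariance of the projected data", {
  set.seed(3)
  X <- matrix(rnorm(500 * 8), 500) %*% matrix(rnorm(64), 8)
  cc <- center_columns(X)
  pr <- pca_reduce(cc$x, 5, whiten = TRUE)
  Z <- pr$K_pca %*% t(cc$x)
  cov_z <- Z %*% t(Z) / (ncol(Z) - 1)
  expect_lt(max(abs(cov_z - diag(5))), 1e-8)
  expect_error(pca_reduce(cc$x, 100), "q must be")
})

test_that("FastICA recovers a known two-source mixture up to signed permutation", {
  set.seed(5)
  n <- 1e4
  S <- rbind(runif(n, -sqrt(3), sqrt(3)), runif(n, -sqrt(3), sqrt(3)))
  A <- matrix(c(2, 1, 1, -1), 2)
  X <- t(A %*% S)                      # n x 2 observations
  cc <- center_columns(X)
  pr <- pca_reduce(cc$x, 2, whiten = TRUE)
  W <- fastica(pr$K_pca %*% t(cc$x), seed = 6)
  expect_true(attr(W, "converged"))
  expect_lt(max(abs(W %*% t(W) - diag(2))), 1e-6)
  P <- W %*% pr$K_pca %*% A
  expect_lt(amari_index(P), 0.05)
})

test_that("FastICA handles the trivial and the unidentifiable cases", {
  set.seed(7)
  z1 <- matrix(runif(5000, -sqrt(3), sqrt(3)), 1)
  W <- fastica(z1 / sd(z1), seed = 1)
  expect_equal(abs(W[1, 1]), 1, tolerance = 1e-6)
  # Gaussian input: no rotation is identifiable; must not crash
  zg <- matrix(rnorm(2000), 2)
  expect_no_error(suppressWarnings(fastica(zg, max_iter = 20, seed = 2)))
})

test_that("the combined basis W_T is t(K_pca) %*% W with consistent shapes", {
  b <- build_basis(rep(0, 4), diag(4), diag(4), rep(1, 4))
  expect_equal(b$W_T, diag(4))
  set.seed(8)
  K <- matrix(rnorm(3 * 16), 3)
  W <- qr.Q(qr(matrix(rnorm(9), 3)))
  b2 <- build_basis(rnorm(16), K, W, c(3, 2, 1))
  expect_equal(b2$W_T, t(K) %*% W, tolerance = 1e-12)
  expect_identical(ncol(b2$W_T), 3L)
  expect_error(build_basis(rnorm(16), K, diag(2), c(3, 2, 1)), "q x q")
})

test_that("feature extraction is the centered projection onto W_T", {
  toy <- make_toy_protos(30, 30, side = 8, seed = 9)
  basis <- train_ica_basis(toy, q = 4, seed = 10)
  # training mean patch maps to the zero feature vector
  mean_patch <- matrix(basis$mean, 8, byrow = TRUE)
  expect_lt(max(abs(extract_features(mean_patch, basis))), 1e-10)
  # explicit dot-product oracle on a random patch
  set.seed(11)
  patch <- matrix(rnorm(64), 8)
  v <- as.vector(t(patch)) - basis$mean
  want <- vapply(seq_len(4), function(j) sum(v * basis$W_T[, j]), numeric(1))
  expect_lt(max(abs(extract_features(patch, basis) - want)), 1e-12)
  # identity basis: features are the centered flattened patch
  idb <- build_basis(rep(0, 64), diag(64), diag(64), rep(1, 64))
  expect_equal(extract_features(patch, idb), as.vector(t(patch)),
               tolerance = 1e-12)
})

test_that("reconstruction inverts extraction on the feature subspace", {
  toy <- make_toy_protos(40, 40, side = 8, seed = 12)
  basis <- train_ica_basis(toy, q = 6, seed = 13)
  expect_equal(reconstruct(rep(0, 6), basis),
               matrix(basis$mean, 8, byrow = TRUE), tolerance = 1e-12)
  s <- rnorm(6)
  expect_lt(max(abs(extract_features(reconstruct(s, basis), basis) - s)),
            1e-8)
})

test_that("rank-q reconstruction equals the PCA truncation oracle", {
  toy <- make_toy_protos(50, 50, side = 8, seed = 14)
  basis <- suppressWarnings(train_ica_basis(toy, q = 5, seed = 15))
  set.seed(16)
  patch <- matrix(rnorm(64), 8)
  got <- reconstruct(extract_features(patch, basis), basis)
  # oracle: project the centered patch onto the top-5 eigenvectors
  cc <- center_columns(toy$x)
  V <- svd(cc$x, nu = 0, nv = 5)$v
  v <- as.vector(t(patch)) - basis$mean
  want <- matrix(basis$mean + drop(V %*% crossprod(V, v)), 8, byrow = TRUE)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("full-rank basis reconstructs patches exactly", {
  set.seed(17)
  X2 <- matrix(rnorm(100 * 9), 100)
  b2 <- suppressWarnings(train_ica_basis(X2, q = 9, seed = 19))
  p2 <- matrix(X2[5, ], 3, byrow = TRUE)
  expect_lt(max(abs(reconstruct(extract_features(p2, b2), b2) - p2)), 1e-8)
})

test_that("reconstruction error is non-increasing in q", {
  toy <- make_toy_protos(80, 80, side = 8, seed = 20)
  set.seed(21)
  patches <- lapply(1:5, function(i) matrix(toy$x[i * 7, ], 8, byrow = TRUE))
  err <- vapply(c(5, 10, 15), function(q) {
    b <- suppressWarnings(train_ica_basis(toy, q = q, seed = 22))
    mean(vapply(patches, function(p)
      sqrt(sum((p - reconstruct(extract_features(p, b), b))^2)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-8))
})

test_that("basis training is deterministic under a fixed seed", {
  toy <- make_toy_protos(30, 30, side = 8, seed = 23)
  b1 <- train_ica_basis(toy, q = 4, seed = 24)
  b2 <- train_ica_basis(toy, q = 4, seed = 24)
  expect_equal(b1$W_T, b2$W_T, tolerance = 0)
})
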