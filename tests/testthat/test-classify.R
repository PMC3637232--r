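test_that("Rprop with backtracking minimizes a convex quadratic", {
  gr <- function(w) c(2 * (w[1] - 1), 4 * (w[2] + 0.5))
  cfg <- rprop_config(delta_min = 1e-9)
  for (start in list(c(5, -3), c(-10, 10), c(0.01, 0.01))) {
    out <- rprop_minimize(start, gr, cfg, max_iter = 200, grad_tol = 1e-6)
    expect_lt(out$grad_norm, 1e-6)
    expect_lte(out$iterations, 200)
    expect_equal(out$par, c(1, -0.5), tolerance = 1e-5)
  }
})

test_that("rprop_config enforces its invariants", {
  expect_error(rprop_config(eta_plus = 0.9), "eta")
  expect_error(rprop_config(delta0 = 100), "delta")
})

make_blobs <- function(n_per, sep = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per, 0, 0.6), ncol = 2),
             matrix(rnorm(2 * n_per, sep, 0.6), ncol = 2))
  labels <- rep(c("normal", "mass"), each = n_per)
  list(x = x, labels = labels,
       split = split_learning(seq_len(2 * n_per), labels, 0.8, seed))
}

test_that("the Rprop MLP separates linearly separable blobs", {
  b <- make_blobs(200, seed = 2)
  m <- train_mlp(b$x, b$split, H = 8,
                 rprop_config(max_epochs = 300, patience = 50),
                 seed = 3, labels = b$labels)
  expect_gte(m$val_success, 99)
  # training error decreased from its initial value
  expect_lt(m$trace$train_sse[nrow(m$trace)], m$trace$train_sse[1])
})

test_that("zero-epoch training returns the initial model with empty trace", {
  b <- make_blobs(20, seed = 4)
  m <- train_mlp(b$x, b$split, H = 4, rprop_config(max_epochs = 0),
                 seed = 5, labels = b$labels)
  expect_identical(nrow(m$trace), 0L)
  w0 <- icamam:::mlp_init(2, 4, 5)
  expect_equal(m$W1, w0$W1)
})

test_that("MLP training and selection are deterministic under a seed", {
  b <- make_blobs(40, seed = 6)
  cfg <- rprop_config(max_epochs = 50, patience = 20)
  m1 <- train_mlp(b$x, b$split, H = 6, cfg, seed = 7, labels = b$labels)
  m2 <- train_mlp(b$x, b$split, H = 6, cfg, seed = 7, labels = b$labels)
  expect_identical(m1$W1, m2$W1)
  s1 <- select_mlp(b$x, b$split, cfg, H_grid = c(4, 8), restarts = 2,
                   seed = 8, labels = b$labels)
  s2 <- select_mlp(b$x, b$split, cfg, H_grid = c(4, 8), restarts = 2,
                   seed = 8, labels = b$labels)
  expect_identical(s1$W1, s2$W1)
  expect_identical(nrow(attr(s1, "selection")), 4L)
})

test_that("a degenerate single-H selection equals direct training", {
  b <- make_blobs(30, seed = 9)
  cfg <- rprop_config(max_epochs = 30, patience = 10)
  s <- select_mlp(b$x, b$split, cfg, H_grid = 6, restarts = 1, seed = 10,
                  labels = b$labels)
  d <- train_mlp(b$x, b$split, 6, cfg,
                 seed = (10 + 997 + 1) %% .Machine$integer.max,
                 labels = b$labels)
  expect_identical(s$W1, d$W1)
})

test_that("two opposite points are classified symmetrically by the SVM", {
  x <- rbind(c(1, 1), c(-1, -1))
  m <- train_svm_rbf(x, list(train = 1:2), 0, 2,
                     labels = c("mass", "normal"))
  d <- predict(m, x)
  expect_gt(d[1], 0)
  expect_lt(d[2], 0)
  expect_equal(d[1], -d[2], tolerance = 1e-10)
})

test_that("stored-model SVM decision values match the libsvm trainer", {
  b <- make_blobs(60, sep = 2, seed = 11)
  m <- train_svm_rbf(b$x, b$split, log2_gamma = -1, log2_C = 3,
                     labels = b$labels)
  fit <- e1071::svm(b$x[b$split$train, ],
                    factor(b$labels[b$split$train],
                           levels = c("mass", "normal")),
                    type = "C-classification", kernel = "radial",
                    gamma = 0.5, cost = 8, scale = FALSE)
  ref <- attr(predict(fit, b$x, decision.values = TRUE),
              "decision.values")[, 1]
  got <- predict(m, b$x)
  # orientation chosen so mass scores high; compare up to that sign
  expect_lt(max(abs(abs(got) - abs(ref))), 1e-8)
  expect_equal(cor(got, ref * m$sign), 1, tolerance = 1e-12)
})

test_that("a free support vector sits on the unit margin", {
  b <- make_blobs(60, sep = 3, seed = 12)
  m <- train_svm_rbf(b$x, b$split, log2_gamma = -2, log2_C = 0,
                     labels = b$labels)
  free <- abs(m$coefs) < m$cost - 1e-6
  expect_true(any(free))
  d <- predict(m, m$sv[free, , drop = FALSE])
  expect_lt(max(abs(abs(d) - 1)), 0.02)
})

test_that("the RBF kernel separates the XOR pattern", {
  x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  lab <- c("mass", "mass", "normal", "normal")
  m <- train_svm_rbf(x, list(train = 1:4), log2_gamma = 1, log2_C = 10,
                     labels = lab)
  expect_equal(decide(predict(m, x), 0), lab)
})

test_that("SVM grid search selects by validation success with documented ties", {
  toy <- make_toy_protos(50, 50, side = 8, amp = 2, seed = 13)
  basis <- train_ica_basis(toy, q = 4, seed = 14)
  feats <- featurize(toy, basis)
  sp <- split_learning(seq_len(100), toy$meta$label, 0.8, seed = 15)
  g <- grid_search_svm(feats, sp, log2_gamma_grid = c(-3, -1),
                       log2_C_grid = c(0, 2, 4))
  tab <- attr(g, "grid")
  expect_identical(nrow(tab), 6L)
  best_val <- max(tab$val_success)
  sc <- predict(g, feats$x[sp$val, , drop = FALSE])
  expect_equal(success_rate(decide(sc, 0), toy$meta$label[sp$val]),
               best_val)
  # a 1x1 grid is plain training
  g1 <- grid_search_svm(feats, sp, -1, 2)
  d1 <- train_svm_rbf(feats, sp, -1, 2)
  expect_equal(predict(g1, feats$x), predict(d1, feats$x))
})

test_that("scores behave as documented at and around the threshold", {
  expect_identical(decide(c(0.4, 0.6), 0.5), c("normal", "mass"))
  expect_identical(decide(0.5, 0.5), "normal")   # tie -> normal
  expect_identical(decide(c(-5, 0, 3), -Inf), rep("mass", 3))
  # row-order invariance
  b <- make_blobs(30, seed = 16)
  m <- train_svm_rbf(b$x, b$split, -1, 1, labels = b$labels)
  perm <- sample(nrow(b$x))
  expect_equal(predict_scores(m, b$x[perm, ]), predict_scores(m, b$x)[perm])
  # MLP scores live strictly inside (0, 1)
  mm <- train_mlp(b$x, b$split, H = 4, rprop_config(max_epochs = 20),
                  seed = 17, labels = b$labels)
  s <- predict_scores(mm, colMeans(b$x))
  expect_true(s > 0 && s < 1)
})
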