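# RBF-kernel support vector machine (soft margin, libsvm via e1071) with a
# stored-model decision function and the base-2 exponent grid search.

#' Train a soft-margin RBF SVM
#'
#' Fits `min ||w||^2 + C * sum(xi)` subject to
#' `y_i (w' phi(x_i) + b) >= 1 - xi_i` with the Gaussian kernel
#' `K(x, y) = exp(-gamma ||x - y||^2)` through libsvm (e1071), with
#' `gamma = 2^log2_gamma` and `C = 2^log2_C`.  The returned model stores the
#' support vectors, dual coefficients and bias, and its decision values are
#' recomputed from those stored fields (oriented so that higher = more
#' mass-like); no feature scaling is applied beyond the ICA projection.
#'
#' @param features A `feature_set` or numeric matrix.
#' @param split List with integer index vector `train` (rows used for
#'   fitting); pass `list(train = seq_len(nrow(x)))` to use everything.
#' @param log2_gamma,log2_C Base-2 exponents of the kernel width and
#'   penalty.
#' @param labels Optional label vector (`"mass"` / `"normal"`) for
#'   bare-matrix features.
#' @return An object of class `icamam_svm`: `sv` (support vectors),
#'   `coefs` (dual coefficients times labels), `rho` (bias), `gamma`,
#'   `cost`, `sign` (orientation), decision `threshold` (0).
#' @export
train_svm_rbf <- function(features, split, log2_gamma, log2_C,
                          labels = NULL) {
  X <- if (inherits(features, "feature_set")) features$x else features
  lab <- if (!is.null(labels)) labels
         else if (inherits(features, "feature_set")) features$meta$label
         else stop("labels required when features is a bare matrix")
  if (!all(is.finite(X))) stop("features must be finite")
  tr <- split$train
  y <- factor(lab[tr], levels = c("mass", "normal"))
  if (nlevels(droplevels(y)) < 2) stop("training set needs both classes")
  fit <- e1071::svm(X[tr, , drop = FALSE], y, type = "C-classification",
                    kernel = "radial", gamma = 2 ^ log2_gamma,
                    cost = 2 ^ log2_C, scale = FALSE)
  model <- structure(list(sv = fit$SV, coefs = drop(fit$coefs),
                          rho = fit$rho, gamma = 2 ^ log2_gamma,
                          cost = 2 ^ log2_C, log2_gamma = log2_gamma,
                          log2_C = log2_C, sign = 1, threshold = 0),
                     class = "icamam_svm")
  # orient the decision axis so mass prototypes score high
  d <- predict(model, X[tr, , drop = FALSE])
  if (mean(d[y == "mass"]) < mean(d[y == "normal"])) model$sign <- -1
  model
}

#' @export
print.icamam_svm <- function(x, ...) {
  cat(sprintf("icamam_svm: RBF kernel, gamma = 2^%g, C = 2^%g, %d support vectors\n",
              x$log2_gamma, x$log2_C, nrow(x$sv)))
  invisible(x)
}

#' @export
predict.icamam_svm <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_set")) newdata$x else newdata
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(object$sv)) stop("feature dimension mismatch")
  # ||sv - x||^2 via the expansion of the squared norm
  d2 <- outer(rowSums(object$sv^2), rowSums(X^2), `+`) -
    2 * object$sv %*% t(X)
  k <- exp(-object$gamma * pmax(d2, 0))
  object$sign * drop(crossprod(k, object$coefs) - object$rho)
}

#' Exhaustive (gamma, C) grid search for the RBF SVM
#'
#' Trains one SVM per exponent pair over the base-2 grids (defaults: gamma
#' exponents -5 to 20 by 0.5, C exponents -5 to 10 by 0.5) and selects the
#' highest validation success at the intermediate threshold 0.  Ties go to
#' the smaller C exponent, then the smaller gamma exponent.
#'
#' @param features A `feature_set` or numeric matrix.
#' @param split List with index vectors `train` and `val`.
#' @param log2_gamma_grid,log2_C_grid Exponent grids.
#' @param labels Optional labels for bare-matrix features.
#' @return The best `icamam_svm`, with attribute `grid` (data frame:
#'   log2_gamma, log2_C, val_success for every setting).
#' @export
grid_search_svm <- function(features, split,
                            log2_gamma_grid = seq(-5, 20, 0.5),
                            log2_C_grid = seq(-5, 10, 0.5),
                            labels = NULL) {
  if (!length(log2_gamma_grid) || !length(log2_C_grid))
    stop("grids must be non-empty")
  X <- if (inherits(features, "feature_set")) features$x else features
  lab <- if (!is.null(labels)) labels else features$meta$label
  truth <- ifelse(lab[split$val] == "mass", "mass", "normal")
  grid <- expand.grid(log2_gamma = log2_gamma_grid, log2_C = log2_C_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$val_success <- NA_real_
  for (i in seq_len(nrow(grid))) {
    m <- train_svm_rbf(X, split, grid$log2_gamma[i], grid$log2_C[i],
                       labels = lab)
    sc <- predict(m, X[split$val, , drop = FALSE])
    grid$val_success[i] <- success_rate(decide(sc, 0), truth)
  }
  best_i <- order(-grid$val_success, grid$log2_C, grid$log2_gamma)[1]
  best <- train_svm_rbf(X, split, grid$log2_gamma[best_i],
                        grid$log2_C[best_i], labels = lab)
  attr(best, "grid") <- grid
  best
}

#' Classifier scores for a feature matrix
#'
#' Dispatches to the model's score: the sigmoid output in (0, 1) for an MLP
#' and the (oriented) raw decision value for an SVM.  Higher means more
#' mass-like.
#'
#' @param model An `icamam_mlp` or `icamam_svm`.
#' @param features A `feature_set` or numeric matrix.
#' @return Numeric score per row.
#' @export
predict_scores <- function(model, features) predict(model, features)

#' Threshold scores into class labels
#'
#' A prototype is called a mass iff its score strictly exceeds the
#' threshold (a score exactly at the threshold is called normal).  The
#' intermediate thresholds are 0.5 for MLP sigmoid outputs and 0 for SVM
#' decision values — the midpoints of the respective score ranges.
#'
#' @param scores Numeric scores.
#' @param threshold Decision threshold.
#' @return Character vector of `"mass"` / `"normal"`.
#' @export
decide <- function(scores, threshold) {
  ifelse(scores > threshold, "mass", "normal")
}
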