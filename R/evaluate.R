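# Evaluation: success rates, ROC/AUC (Mann-Whitney tie convention),
# stratified k-fold cross-validation and extractor-configuration sweeps.

#' Classification success rate
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Percentage of agreeing entries, `100 * #correct / #total`.
#' @export
success_rate <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth))
    stop("predicted and truth must be non-empty and of equal length")
  100 * mean(predicted == truth)
}

#' ROC curve and area under it
#'
#' Sweeps every distinct score as a threshold (predicted mass iff score >=
#' threshold along the curve) and integrates trapezoidally, which equals
#' the Mann-Whitney statistic P(s+ > s-) + 0.5 P(s+ = s-).
#'
#' @param scores Numeric scores, higher = more mass-like.
#' @param truth Labels; `positive` marks the positive class.
#' @param positive Positive-class label (default `"mass"`).
#' @return An object of class `roc_curve`: `thresholds` (descending,
#'   starting at `Inf`), `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, truth, positive = "mass") {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[last_of_tie]), tpr = tpr, fpr = fpr,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", length(x$tpr), x$auc))
  invisible(x)
}

#' Stratified k-fold cross-validation indices
#'
#' Partitions indices into `k` folds stratified by class and, within class,
#' by site: each stratum is shuffled and dealt cyclically so per-fold class
#' counts differ by at most one (and per-fold site-within-class counts by
#' at most one).
#'
#' @param labels Class label per index.
#' @param sites Optional site label per index.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train =, test =)`; the test
#'   sets partition `seq_along(labels)`.
#' @export
kfold_cv <- function(labels, sites = NULL, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  n <- length(labels)
  if (is.null(sites)) sites <- rep("all", n)
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    pos <- 0L                        # cycle position continues across sites
    cl_n <- sum(labels == cl)
    if (cl_n < k)
      warning("class '", cl, "' has fewer members (", cl_n,
              ") than folds; stratification relaxed")
    start <- sample.int(k, 1) - 1L
    for (st in unique(sites[labels == cl])) {
      idx <- which(labels == cl & sites == st)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((start + pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Stratified train/validation split of a learning set
#'
#' @param learn_idx Indices of the learning set.
#' @param labels Class labels aligned with the full index space.
#' @param train_frac Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `val` index vectors (disjoint, union =
#'   `learn_idx`).
#' @export
split_learning <- function(learn_idx, labels, train_frac = 0.8, seed = 1L) {
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(labels[learn_idx])) {
    idx <- learn_idx[labels[learn_idx] == cl]
    n_tr <- round(train_frac * length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  list(train = sort(train), val = sort(setdiff(learn_idx, train)))
}

#' Sweep feature-extractor configurations by cross-validation
#'
#' For each patch size and number of ICA components `q`, estimates the
#' k-fold cross-validated test success: per fold, an ICA basis is trained
#' on the fold's training prototypes only, all prototypes are featurized,
#' a classifier is trained (with an inner 80/20 train/validation split of
#' the fold-training set) and scored on the held-out fold.
#'
#' @param protos_by_size Named list of `prototype_set` (as returned by
#'   [extract_prototypes()]).
#' @param q_grid Numbers of components to try (default 10 to 65 by 5).
#' @param sizes Patch sizes to try (default those present).
#' @param kind `"svm"` or `"mlp"`.
#' @param k Folds (default 10).
#' @param seed Integer seed.
#' @param svm_grid List with `log2_gamma` and `log2_C` exponent grids for
#'   the inner SVM search.
#' @param mlp_opts List with `H_grid`, `restarts` and `cfg` for the inner
#'   MLP selection.
#' @return List with `table` (size, q, mean_test_success) and `best`
#'   (list(size, q)); ties favor smaller q, then smaller size.
#' @export
optimize_extractor <- function(protos_by_size, q_grid = seq(10L, 65L, 5L),
                               sizes = NULL, kind = c("svm", "mlp"),
                               k = 10L, seed = 1L,
                               svm_grid = list(log2_gamma = seq(-9, 3, 2),
                                               log2_C = seq(-1, 7, 2)),
                               mlp_opts = list(H_grid = c(25L, 50L),
                                               restarts = 2L,
                                               cfg = rprop_config(
                                                 max_epochs = 200L,
                                                 patience = 30L))) {
  kind <- match.arg(kind)
  if (!length(q_grid)) stop("q_grid must be non-empty")
  avail <- vapply(protos_by_size, function(p) p$size, integer(1))
  if (is.null(sizes)) sizes <- unname(avail)
  rows <- list()
  for (sz in sizes) {
    protos <- protos_by_size[[which(avail == sz)[1]]]
    folds <- kfold_cv(protos$meta$label, protos$meta$site, k = k, seed = seed)
    for (q in q_grid) {
      succ <- vapply(seq_along(folds), function(fi) {
        fold <- folds[[fi]]
        fit <- fit_fold(protos, fold$train, q, kind,
                        seed = (seed + 13L * fi) %% .Machine$integer.max,
                        svm_grid = svm_grid, mlp_opts = mlp_opts)
        sc <- predict(fit$model, fit$features$x[fold$test, , drop = FALSE])
        success_rate(decide(sc, fit$model$threshold),
                     protos$meta$label[fold$test])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(size = sz, q = q,
                                              mean_test_success = mean(succ))
    }
  }
  tab <- do.call(rbind, rows)
  best_i <- order(-tab$mean_test_success, tab$q, tab$size)[1]
  list(table = tab, best = list(size = tab$size[best_i], q = tab$q[best_i]))
}

# train basis + classifier on a learning index set; returns model, basis
# and the featurized full prototype set
fit_fold <- function(protos, learn_idx, q, kind, seed, svm_grid, mlp_opts,
                     train_frac = 0.8) {
  inner <- split_learning(learn_idx, protos$meta$label, train_frac, seed)
  basis <- train_ica_basis(protos$x[inner$train, , drop = FALSE], q,
                           seed = seed)
  feats <- featurize(protos, basis)
  model <- if (kind == "svm") {
    grid_search_svm(feats, inner, svm_grid$log2_gamma, svm_grid$log2_C)
  } else {
    select_mlp(feats, inner, mlp_opts$cfg, mlp_opts$H_grid,
               mlp_opts$restarts, seed)
  }
  list(model = model, basis = basis, features = feats, split = inner)
}
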