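# Resilient backpropagation (Rprop with weight backtracking) and the
# single-hidden-layer perceptron trained with it.

#' Rprop configuration
#'
#' Hyperparameters of resilient backpropagation with weight backtracking.
#' Defaults are the classic values (increase 1.2, decrease 0.5, initial
#' step 0.1, step bounds 1e-6 and 50).
#'
#' @param eta_plus Step increase factor (> 1).
#' @param eta_minus Step decrease factor (in (0, 1)).
#' @param delta0 Initial per-weight update value.
#' @param delta_min,delta_max Update-value bounds.
#' @param max_epochs Maximum training epochs.
#' @param patience Epochs without validation improvement before stopping.
#' @param restarts Random restarts used by [select_mlp()].
#' @return An object of class `rprop_config`.
#' @export
rprop_config <- function(eta_plus = 1.2, eta_minus = 0.5, delta0 = 0.1,
                         delta_min = 1e-6, delta_max = 50,
                         max_epochs = 1000L, patience = 50L, restarts = 4L) {
  if (!(0 < eta_minus && eta_minus < 1 && eta_plus > 1))
    stop("need 0 < eta_minus < 1 < eta_plus")
  if (!(delta_min < delta0 && delta0 < delta_max))
    stop("need delta_min < delta0 < delta_max")
  structure(list(eta_plus = eta_plus, eta_minus = eta_minus, delta0 = delta0,
                 delta_min = delta_min, delta_max = delta_max,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 restarts = as.integer(restarts)),
            class = "rprop_config")
}

# One Rprop update. state: list(delta, prev_grad, prev_step).  On gradient
# sign agreement the per-weight step grows (capped); on disagreement the
# previous step is reverted (backtracking), the step shrinks and the
# gradient is masked for the next comparison.
rprop_step <- function(state, grad) {
  agree <- sign(grad) * sign(state$prev_grad)
  up <- agree > 0; down <- agree < 0
  state$delta[up] <- pmin(state$delta[up] * state$eta_plus, state$delta_max)
  state$delta[down] <- pmax(state$delta[down] * state$eta_minus,
                            state$delta_min)
  step <- -sign(grad) * state$delta
  step[down] <- -state$prev_step[down]   # backtrack
  grad[down] <- 0
  state$prev_grad <- grad
  state$prev_step <- step
  state
}

#' Minimize a function with Rprop
#'
#' Batch resilient backpropagation as a generic gradient-sign optimizer:
#' only the sign of each partial derivative steers its per-weight adaptive
#' step.  Useful for verifying the optimizer independently of the network.
#'
#' @param par Initial parameter vector.
#' @param gr Gradient function of the objective.
#' @param cfg An [rprop_config()].
#' @param max_iter Iteration cap (default `cfg$max_epochs`).
#' @param grad_tol Stop when the gradient infinity norm drops below this.
#' @return List with `par`, `iterations`, `grad_norm`.
#' @export
rprop_minimize <- function(par, gr, cfg = rprop_config(),
                           max_iter = cfg$max_epochs, grad_tol = 0) {
  state <- list(delta = rep(cfg$delta0, length(par)),
                prev_grad = numeric(length(par)),
                prev_step = numeric(length(par)),
                eta_plus = cfg$eta_plus, eta_minus = cfg$eta_minus,
                delta_min = cfg$delta_min, delta_max = cfg$delta_max)
  g <- gr(par)
  it <- 0L
  while (it < max_iter && max(abs(g)) > grad_tol) {
    it <- it + 1L
    state <- rprop_step(state, g)
    par <- par + state$prev_step
    g <- gr(par)
  }
  list(par = par, iterations = it, grad_norm = max(abs(g)))
}

# ---- multilayer perceptron ----

mlp_init <- function(q, H, seed) {
  set.seed(seed)
  list(W1 = matrix(stats::rnorm(H * (q + 1), sd = 0.5), H, q + 1),
       w2 = stats::rnorm(H + 1, sd = 0.5))
}

mlp_flatten <- function(w) c(as.vector(w$W1), w$w2)

mlp_unflatten <- function(v, q, H) {
  list(W1 = matrix(v[seq_len(H * (q + 1))], H, q + 1),
       w2 = v[H * (q + 1) + seq_len(H + 1)])
}

mlp_forward <- function(w, X) {
  A <- stats::plogis(cbind(1, X) %*% t(w$W1))
  yhat <- stats::plogis(drop(cbind(1, A) %*% w$w2))
  list(A = A, yhat = yhat)
}

# gradient of the sum-of-squares error
mlp_gradient <- function(w, X, y) {
  fw <- mlp_forward(w, X)
  d2 <- 2 * (fw$yhat - y) * fw$yhat * (1 - fw$yhat)
  g2 <- drop(crossprod(cbind(1, fw$A), d2))
  dA <- (d2 %o% w$w2[-1]) * fw$A * (1 - fw$A)
  g1 <- crossprod(dA, cbind(1, X))
  list(grad = c(as.vector(g1), g2),
       sse = sum((fw$yhat - y)^2))
}

#' Train a single-hidden-layer perceptron with Rprop
#'
#' Batch Rprop on the sum-of-squares error of a logistic-sigmoid network
#' with one hidden layer and a single sigmoid output unit (targets: mass =
#' 1, normal = 0).  Validation success is evaluated every epoch at the
#' intermediate threshold 0.5 and the weights with the best validation
#' success seen are returned (early stop after `cfg$patience` epochs
#' without improvement).
#'
#' @param features A `feature_set` (see [featurize()]) or numeric matrix.
#' @param split List with integer index vectors `train` and `val` into the
#'   feature rows.
#' @param H Hidden units.
#' @param cfg An [rprop_config()].
#' @param seed Integer seed for the weight initialization.
#' @param labels Optional label vector when `features` is a bare matrix.
#' @return An object of class `icamam_mlp`: weights, `H`, `val_success`,
#'   per-epoch `trace` (data frame: epoch, train_sse, val_success) and the
#'   decision `threshold` (0.5).
#' @export
train_mlp <- function(features, split, H, cfg = rprop_config(), seed = 1L,
                      labels = NULL) {
  X <- if (inherits(features, "feature_set")) features$x else features
  y <- mlp_targets(features, labels)
  if (!length(split$train) || !length(split$val))
    stop("split must have non-empty train and val index sets")
  Xt <- X[split$train, , drop = FALSE]; yt <- y[split$train]
  Xv <- X[split$val, , drop = FALSE]; yv <- y[split$val]
  q <- ncol(X)
  w <- mlp_init(q, H, seed)
  par <- mlp_flatten(w)
  state <- list(delta = rep(cfg$delta0, length(par)),
                prev_grad = numeric(length(par)),
                prev_step = numeric(length(par)),
                eta_plus = cfg$eta_plus, eta_minus = cfg$eta_minus,
                delta_min = cfg$delta_min, delta_max = cfg$delta_max)
  best <- list(par = par, val = mlp_success(par, q, H, Xv, yv), epoch = 0L)
  trace <- vector("list", cfg$max_epochs)
  since_improve <- 0L
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    gs <- mlp_gradient(mlp_unflatten(par, q, H), Xt, yt)
    state <- rprop_step(state, gs$grad)
    par <- par + state$prev_step
    val <- mlp_success(par, q, H, Xv, yv)
    trace[[epoch]] <- data.frame(epoch = epoch, train_sse = gs$sse,
                                 val_success = val)
    if (val > best$val) {
      best <- list(par = par, val = val, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= cfg$patience) break
    }
  }
  w <- mlp_unflatten(best$par, q, H)
  structure(list(W1 = w$W1, w2 = w$w2, H = H, q = q, cfg = cfg, seed = seed,
                 val_success = best$val, best_epoch = best$epoch,
                 trace = if (epoch > 0) do.call(rbind, trace[seq_len(epoch)])
                         else data.frame(),
                 threshold = 0.5),
            class = "icamam_mlp")
}

mlp_targets <- function(features, labels) {
  lab <- if (!is.null(labels)) labels
         else if (inherits(features, "feature_set")) features$meta$label
         else stop("labels required when features is a bare matrix")
  as.numeric(lab == "mass")
}

mlp_success <- function(par, q, H, X, y) {
  yhat <- mlp_forward(mlp_unflatten(par, q, H), X)$yhat
  100 * mean((yhat > 0.5) == (y == 1))
}

#' @export
print.icamam_mlp <- function(x, ...) {
  cat(sprintf("icamam_mlp: %d-%d-1 sigmoid network, validation success %.2f%% (epoch %d)\n",
              x$q, x$H, x$val_success, x$best_epoch))
  invisible(x)
}

#' @export
predict.icamam_mlp <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_set")) newdata$x else newdata
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != object$q) stop("feature dimension mismatch")
  mlp_forward(list(W1 = object$W1, w2 = object$w2), X)$yhat
}

#' Model selection over hidden-layer sizes with random restarts
#'
#' Trains `restarts` networks per hidden-layer size with different random
#' initial weights and returns the one with the highest validation success.
#' Ties go to the smaller hidden layer, then the lower restart index.
#'
#' @param features,split,cfg,seed As in [train_mlp()].
#' @param H_grid Hidden-layer sizes to sweep (default 50 to 650 by 50).
#' @param restarts Random restarts per size (default `cfg$restarts`).
#' @param labels Optional labels for bare-matrix features.
#' @return The best `icamam_mlp`, with a `selection` data frame attribute
#'   (H, restart, val_success).
#' @export
select_mlp <- function(features, split, cfg = rprop_config(),
                       H_grid = seq(50L, 650L, 50L),
                       restarts = cfg$restarts, seed = 1L, labels = NULL) {
  if (!length(H_grid)) stop("H_grid must be non-empty")
  best <- NULL
  rows <- list()
  for (hi in seq_along(H_grid)) {
    for (r in seq_len(restarts)) {
      m <- train_mlp(features, split, H_grid[hi], cfg,
                     seed = (seed + 997L * hi + r) %% .Machine$integer.max,
                     labels = labels)
      rows[[length(rows) + 1L]] <- data.frame(H = H_grid[hi], restart = r,
                                              val_success = m$val_success)
      if (is.null(best) || m$val_success > best$val_success) best <- m
    }
  }
  attr(best, "selection") <- do.call(rbind, rows)
  best
}
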