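# Shared oracles and small fixture builders (everything generated in code).

# Amari permutation/scale-invariant error of P = W_est %*% A_true;
# 0 iff P is a signed scaled permutation, ~1 for unrelated matrices.
amari_index <- function(P) {
  q <- nrow(P)
  A <- abs(P)
  r <- sum(rowSums(A / apply(A, 1, max)) - 1)
  c <- sum(colSums(A / apply(A, 2, max)) - 1)
  (r + c) / (2 * q * (q - 1))
}

# O(n^2) pairwise Mann-Whitney AUC with ties counted 0.5
auc_pairwise <- function(scores, truth, positive = "mass") {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent re-derivation of the centered enclosing square: scan all
# origins whose square contains the bounding box, pick the one closest to
# the box center (ties toward smaller indices), then apply the bounds rule
bounding_square_oracle <- function(boundary, image_shape) {
  r0 <- min(boundary[, 1]); r1 <- max(boundary[, 1])
  c0 <- min(boundary[, 2]); c1 <- max(boundary[, 2])
  side <- max(r1 - r0 + 1L, c1 - c0 + 1L)
  pick <- function(lo, hi, ctr) {
    cand <- (hi - side + 1L):lo
    d <- abs(cand + (side - 1) / 2 - ctr)
    cand <- cand[order(d, cand)]
    cand[1]
  }
  ro <- pick(r0, r1, (r0 + r1) / 2)
  co <- pick(c0, c1, (c0 + c1) / 2)
  if (ro < 1 || co < 1 || ro + side - 1 > image_shape[1] ||
      co + side - 1 > image_shape[2]) return(NULL)
  list(row0 = ro, col0 = co, side = side)
}

# three independent non-Gaussian sources recoverable by the log-cosh
# contrast: uniform (sub-Gaussian), Laplace and a bimodal mixture
make_sources <- function(n, seed) {
  set.seed(seed)
  rbind(stats::runif(n, -sqrt(3), sqrt(3)),
        ifelse(stats::runif(n) < 0.5, 1, -1) * stats::rexp(n) / sqrt(2),
        sample(c(-1, 1), n, replace = TRUE) + stats::rnorm(n, sd = 0.3))
}

# small labelled patch set: "mass" patches carry class-dependent weight on
# n_signal orthogonal cosine patterns, everything plus white noise
make_toy_protos <- function(n_mass = 60, n_normal = 60, side = 8,
                            n_signal = 5, amp = 2, seed = 1) {
  set.seed(seed)
  p <- side^2
  basis <- sapply(seq_len(n_signal), function(k) {
    v <- as.vector(outer(cos(pi * k * (1:side) / side), rep(1, side)))
    v / sqrt(sum(v^2))
  })
  n <- n_mass + n_normal
  lab <- rep(c("mass", "normal"), c(n_mass, n_normal))
  coef <- matrix(stats::rnorm(n * n_signal), n) +
    amp * (lab == "mass")
  x <- coef %*% t(basis) + matrix(stats::rnorm(n * p, sd = 0.5), n)
  meta <- data.frame(id = sprintf("t%03d", 1:n), label = lab,
                     pathology = ifelse(lab == "mass", "malignant", "normal"),
                     site = rep(c("a", "b"), length.out = n),
                     source_case = "toy", side_px = side)
  structure(list(x = x, meta = meta, size = as.integer(side),
                 n_discarded = 0L),
            class = "prototype_set")
}

# fast small study design for pipeline-level tests
tiny_design <- function() default_study_design(scale = 0.12)
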