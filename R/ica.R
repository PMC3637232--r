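# Blind feature extraction: centering, PCA truncation/whitening, symmetric
# log-cosh FastICA, and projection/reconstruction through the combined
# basis W_T = t(K_pca) %*% W.

#' Center the columns of a data matrix
#'
#' @param X Numeric N x p matrix, N >= 2; rows are flattened patches.
#' @return List with `x` (centered matrix) and `mean` (length-p column
#'   means).
#' @export
center_columns <- function(X) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2) stop("need at least 2 rows to center")
  mu <- colMeans(X)
  list(x = sweep(X, 2, mu), mean = mu)
}

#' PCA truncation and whitening matrix
#'
#' Computes the top `q` covariance eigenvectors of centered data, ordered by
#' descending eigenvalue (ties broken by original index), returned as the
#' rows of a `q x p` projection matrix.  With `whiten = TRUE` row `j` is
#' scaled by `1 / sqrt(eigval_j)` so the projected data have unit variance
#' per component — the form FastICA requires.  Each eigenvector's sign is
#' fixed so its largest-magnitude element is positive.
#'
#' @param Xc Centered N x p matrix.
#' @param q Number of components, `1 <= q <= min(N - 1, p)`.
#' @param whiten Scale rows to unit projected variance (default `TRUE`).
#' @return List with `K_pca` (q x p) and `eigvals` (length q, descending).
#' @export
pca_reduce <- function(Xc, q, whiten = TRUE) {
  n <- nrow(Xc); p <- ncol(Xc)
  if (q < 1 || q > min(n - 1, p))
    stop("q must be between 1 and min(N - 1, p) = ", min(n - 1, p))
  sv <- svd(Xc, nu = 0, nv = q)
  eig <- sv$d[seq_len(q)]^2 / (n - 1)
  V <- sv$v
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2, flip, `*`)
  if (whiten) {
    if (any(eig <= 1e-12 * max(eig, 1)))
      stop("degenerate component: eigenvalue ~ 0 with whitening on")
    V <- sweep(V, 2, sqrt(eig), `/`)
  }
  list(K_pca = t(V), eigvals = eig)
}

#' Symmetric FastICA with the log-cosh contrast
#'
#' Parallel fixed-point FastICA on whitened data with g(u) = tanh(u) (the
#' derivative of log cosh): each row update is
#' `w <- E[z g(w'z)] - E[g'(w'z)] w`, followed by symmetric decorrelation
#' `W <- (W W')^{-1/2} W`.  Iteration stops when
#' `max_j |1 - |<w_j_new, w_j_old>||` drops below `tol`.  Components are
#' then ordered by descending |excess kurtosis| and their signs fixed to
#' positive skewness, purely for reproducibility (ICA itself leaves order
#' and sign indeterminate).
#'
#' @param Z Whitened q x N data matrix (unit covariance).
#' @param tol Convergence tolerance on the rotation change (default 1e-4).
#' @param max_iter Maximum iterations (default 400).
#' @param seed Integer seed for the random initial rotation.
#' @return q x q unmixing matrix `W` (orthonormal rows) with attributes
#'   `converged` (logical) and `iterations`.  On non-convergence a warning
#'   is issued and the current estimate returned.
#' @export
fastica <- function(Z, tol = 1e-4, max_iter = 400L, seed = 1L) {
  stopifnot(is.matrix(Z))
  q <- nrow(Z); n <- ncol(Z)
  set.seed(seed)
  W <- matrix(stats::rnorm(q * q), q, q)
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Z
    G <- tanh(U)
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(1 - G^2), q) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("FastICA did not converge in ", max_iter, " iterations")
  # deterministic order (descending non-Gaussianity) and sign (positive skew)
  S <- W %*% Z
  kur <- rowMeans(S^4) - 3
  ord <- order(abs(kur), decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  sk <- rowMeans((W %*% Z)^3)
  flip <- ifelse(sk < 0, -1, 1)
  W <- W * flip
  structure(W, converged = converged, iterations = it)
}

# (W W')^{-1/2} W via symmetric eigendecomposition
sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
}

#' Assemble an ICA basis
#'
#' Combines the centering vector, PCA/whitening matrix and ICA rotation
#' into the feature-extraction basis `W_T = t(K_pca) %*% W` (p x q), whose
#' columns span the learned feature directions.
#'
#' @param mean Length-p training column means.
#' @param K_pca q x p PCA/whitening matrix (see [pca_reduce()]).
#' @param W q x q ICA unmixing matrix (see [fastica()]).
#' @param eigvals Length-q descending eigenvalues.
#' @return An object of class `ica_basis` with fields `p`, `q`, `mean`,
#'   `K_pca`, `W`, `W_T`, `eigvals`.
#' @export
build_basis <- function(mean, K_pca, W, eigvals) {
  q <- nrow(K_pca); p <- ncol(K_pca)
  if (!is.matrix(W) || nrow(W) != q || ncol(W) != q)
    stop("W must be q x q with q = nrow(K_pca)")
  if (length(mean) != p) stop("mean length must equal ncol(K_pca)")
  if (length(eigvals) != q) stop("eigvals length must equal q")
  structure(list(p = p, q = q, mean = as.numeric(mean), K_pca = K_pca,
                 W = unclass_matrix(W), W_T = t(K_pca) %*% W,
                 eigvals = as.numeric(eigvals)),
            class = "ica_basis")
}

unclass_matrix <- function(W) {
  attributes(W) <- list(dim = dim(W))
  W
}

#' @export
print.ica_basis <- function(x, ...) {
  cat(sprintf("ica_basis: p = %d (patch %dx%d), q = %d components\n",
              x$p, round(sqrt(x$p)), round(sqrt(x$p)), x$q))
  invisible(x)
}

#' Train an ICA basis from prototype patches
#'
#' Convenience wrapper running [center_columns()], [pca_reduce()] (with
#' whitening) and [fastica()] on an N x p patch matrix or `prototype_set`.
#'
#' @param x N x p numeric matrix of flattened patches, or a `prototype_set`.
#' @param q Number of independent components.
#' @param tol,max_iter,seed Passed to [fastica()].
#' @return An [build_basis()] `ica_basis`.
#' @export
train_ica_basis <- function(x, q, tol = 1e-4, max_iter = 400L, seed = 1L) {
  X <- if (inherits(x, "prototype_set")) x$x else x
  cc <- center_columns(X)
  pr <- pca_reduce(cc$x, q, whiten = TRUE)
  Z <- pr$K_pca %*% t(cc$x)
  W <- fastica(Z, tol = tol, max_iter = max_iter, seed = seed)
  build_basis(cc$mean, pr$K_pca, W, pr$eigvals)
}

#' Project patches onto an ICA basis
#'
#' Computes the feature vector `s = (flatten(patch) - mean) %*% W_T` for one
#' patch (row-major flattening) or for every row of a patch matrix /
#' `prototype_set`.
#'
#' @param x An S x S patch matrix (with `S^2 = p`), an N x p matrix of
#'   flattened patches, or a `prototype_set`.
#' @param basis An `ica_basis`.
#' @return A length-q vector for a single patch, otherwise an N x q matrix.
#' @export
extract_features <- function(x, basis) {
  stopifnot(inherits(basis, "ica_basis"))
  if (inherits(x, "prototype_set")) x <- x$x
  if (is.matrix(x) && nrow(x) == ncol(x) && nrow(x)^2 == basis$p) {
    v <- as.vector(t(x))            # row-major flatten
    return(drop((v - basis$mean) %*% basis$W_T))
  }
  if (!is.matrix(x) || ncol(x) != basis$p)
    stop("patch size does not match basis dimension p = ", basis$p)
  sweep(x, 2, basis$mean) %*% basis$W_T
}

#' Reconstruct a patch from its ICA coefficients
#'
#' Returns `mean + s %*% pinv(W_T)` reshaped to S x S: the patch expressed
#' as a linear superposition of the basis images (the rows of the
#' pseudo-inverse of `W_T`) plus the training mean.  For `q < p` this equals
#' the rank-q PCA reconstruction, since the ICA rotation is invertible
#' within the whitened subspace.
#'
#' @param s Length-q coefficient vector.
#' @param basis An `ica_basis`.
#' @return S x S numeric matrix, `S = sqrt(p)`.
#' @export
reconstruct <- function(s, basis) {
  stopifnot(inherits(basis, "ica_basis"), length(s) == basis$q)
  pinv <- basis_pinv(basis)
  v <- basis$mean + drop(s %*% pinv)
  matrix(v, nrow = sqrt(basis$p), byrow = TRUE)  # undo row-major flatten
}

# q x p pseudo-inverse of W_T, cached on the basis environment-free object
basis_pinv <- function(basis) {
  wt <- basis$W_T
  solve(crossprod(wt), t(wt))
}

#' Featurize a prototype set
#'
#' @param protos A `prototype_set`.
#' @param basis An `ica_basis` trained on patches of the same size.
#' @return An object of class `feature_set`: list with `x` (N x q feature
#'   matrix) and `meta` (the prototype metadata).
#' @export
featurize <- function(protos, basis) {
  stopifnot(inherits(protos, "prototype_set"))
  structure(list(x = extract_features(protos$x, basis), meta = protos$meta,
                 q = basis$q, size = protos$size),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d prototypes x %d ICA features (patch %dx%d)\n",
              nrow(x$x), x$q, x$size, x$size))
  invisible(x)
}
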