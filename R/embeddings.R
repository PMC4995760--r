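#' FastICA with symmetric decorrelation
#'
#' Independent component analysis by the fixed-point FastICA iteration with
#' the logcosh contrast. The data are centered and whitened by SVD; the
#' unmixing matrix is initialized from the seeded RNG and symmetrically
#' re-orthogonalized each step. Deterministic given the seed.
#'
#' @param data numeric matrix (observations x features).
#' @param n_comp number of components (default 2).
#' @param seed RNG seed.
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on the unmixing matrix.
#' @return observations x `n_comp` matrix of independent component scores.
#' @export
fast_ica <- function(data, n_comp = 2, seed = 1, max_iter = 200, tol = 1e-6) {
  set.seed(seed)
  Xc <- scale(data, center = TRUE, scale = FALSE)
  n <- nrow(Xc)
  sv <- svd(Xc, nu = 0, nv = min(dim(Xc)))
  pos <- sv$d > max(sv$d) * 1e-9
  if (sum(pos) < n_comp) stop("data rank below requested ICA components", call. = FALSE)
  K <- sv$v[, pos, drop = FALSE] %*% diag(sqrt(n - 1) / sv$d[pos], sum(pos))
  Z <- Xc %*% K # whitened: cov(Z) = I
  p <- ncol(Z)
  W <- matrix(stats::rnorm(n_comp * p), n_comp, p)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)            # n x n_comp
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- crossprod(G, Z) / n - diag(colMeans(Gp), n_comp) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- Z %*% t(W)
  rownames(S) <- rownames(data)
  S
}

#' Spectral embedding of a nearest-neighbor graph
#'
#' Builds a symmetrized k-nearest-neighbor graph on the rows of `data`,
#' forms the symmetric normalized graph Laplacian and returns the
#' eigenvectors of its two smallest non-trivial eigenvalues.
#'
#' @param data numeric matrix (observations x features).
#' @param k_neighbors neighbors per point.
#' @return observations x 2 coordinate matrix.
#' @export
spectral_embedding <- function(data, k_neighbors) {
  n <- nrow(data)
  stopifnot(k_neighbors >= 1, k_neighbors < n)
  d <- as.matrix(stats::dist(data))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[2:(k_neighbors + 1)]
    A[i, nn] <- 1
  }
  A <- pmax(A, t(A)) # mutual or one-sided neighbors both connect
  deg <- rowSums(A)
  deg[deg == 0] <- 1
  Dh <- 1 / sqrt(deg)
  L <- diag(n) - (Dh * A) %*% diag(Dh)
  ed <- eigen((L + t(L)) / 2, symmetric = TRUE)
  # smallest eigenvalue(s) are the trivial component indicators
  idx <- order(ed$values)
  co <- ed$vectors[, idx[2:3], drop = FALSE]
  rownames(co) <- rownames(data)
  co
}
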