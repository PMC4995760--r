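#' Per-cell dropout sigmoid
#'
#' Probability that an expressed gene with mean detected log-expression `x`
#' is missed by cell `j`: `1 / (1 + exp(alpha * (x - beta)))`. Decreasing in
#' `x` for `alpha > 0`; equals 0.5 at `x = beta`.
#'
#' @param x mean detected log-expression (vector ok).
#' @param alpha,beta sigmoid parameters.
#' @return dropout probability in (0, 1).
#' @export
dropout_sigmoid <- function(x, alpha, beta) {
  1 / (1 + exp(alpha * (x - beta)))
}

#' Build the housekeeping quantile scaffold
#'
#' Housekeeping genes are assumed constitutively expressed, so their zeros
#' are technical dropouts. Each housekeeping gene's abundance is summarized
#' by the mean of its non-zero log-expression values; genes are ranked by
#' that mean and split into `n_quantiles` equal-count bins. `mu[q]` is the
#' mean of gene means in bin `q`, and `F[j, q]` the fraction of bin-q genes
#' with zero expression in cell `j` -- the empirical dropout rate.
#'
#' @param X log-scale expression matrix (genes x cells).
#' @param housekeeping character vector of housekeeping gene ids.
#' @param n_quantiles number of abundance bins (default 30).
#' @return object of class `quantile_scaffold` with fields `mu` (length
#'   `n_quantiles`, non-decreasing), `F` (cells x `n_quantiles`) and `genes`.
#' @export
build_quantile_scaffold <- function(X, housekeeping, n_quantiles = 30) {
  check_expression_matrix(X)
  hk <- intersect(toupper(housekeeping), rownames(X))
  det <- rowSums(X[hk, , drop = FALSE] > 0)
  hk <- hk[det > 0]
  if (length(hk) < n_quantiles) {
    stop("only ", length(hk), " usable housekeeping genes found in the matrix; ",
         "need >= ", n_quantiles, ". Supply a housekeeping list matched to ",
         "this dataset's gene identifiers.", call. = FALSE)
  }
  sub <- X[hk, , drop = FALSE]
  nz <- sub > 0
  mu_gene <- rowSums(sub) / rowSums(nz)
  ord <- order(mu_gene, hk)   # ties broken by gene-id order
  ng <- length(hk)
  bin <- ceiling(n_quantiles * seq_len(ng) / ng)
  mu_q <- as.vector(tapply(mu_gene[ord], bin, mean))
  Fm <- matrix(0, ncol(X), n_quantiles,
               dimnames = list(colnames(X), NULL))
  zero <- !nz
  for (q in seq_len(n_quantiles)) {
    genes_q <- hk[ord[bin == q]]
    Fm[, q] <- colMeans(zero[genes_q, , drop = FALSE])
  }
  structure(list(mu = mu_q, F = Fm, genes = hk[ord], bin = bin),
            class = "quantile_scaffold")
}

# internal: RSS of the sigmoid against one cell's empirical dropout fractions
sigmoid_rss <- function(par, mu, fjq) {
  sum((dropout_sigmoid(mu, par[1], par[2]) - fjq)^2)
}

#' Fit a dropout curve for one cell
#'
#' Finds `(alpha, beta)` minimizing the residual sum of squares between the
#' sigmoid evaluated at the scaffold abundances `mu[q]` and the cell's
#' empirical dropout fractions `F[j, q]`. Multi-start L-BFGS-B over
#' `alpha0` in {0.5, 1, 4} with `beta0 = median(mu)`; `alpha` bounded to
#' (0, 100].
#'
#' @param scaffold a `quantile_scaffold`.
#' @param cell cell index or id.
#' @return list with `alpha`, `beta`, `rss`, `converged`.
#' @export
fit_dropout_curve <- function(scaffold, cell) {
  mu <- scaffold$mu
  f <- scaffold$F[cell, ]
  best <- NULL
  conv <- FALSE
  for (a0 in c(0.5, 1, 4)) {
    fit <- tryCatch(
      stats::optim(c(a0, stats::median(mu)), sigmoid_rss, mu = mu, fjq = f,
                   method = "L-BFGS-B", lower = c(1e-4, -Inf), upper = c(100, Inf),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("sigmoid fit failed for cell ", cell, call. = FALSE)
  if (!conv) warning("dropout-curve fit did not converge for cell ", cell,
                     "; keeping best candidate", call. = FALSE)
  list(alpha = best$par[1], beta = best$par[2], rss = best$value,
       converged = conv)
}

#' Fit dropout curves for every cell
#'
#' @param scaffold a `quantile_scaffold`.
#' @return data.frame with one row per cell: `alpha`, `beta`, `rss`,
#'   `converged`; rownames are cell ids.
#' @export
fit_dropout_curves <- function(scaffold) {
  cells <- rownames(scaffold$F)
  fits <- lapply(cells, function(j) fit_dropout_curve(scaffold, j))
  data.frame(alpha = vapply(fits, `[[`, 0, "alpha"),
             beta = vapply(fits, `[[`, 0, "beta"),
             rss = vapply(fits, `[[`, 0, "rss"),
             converged = vapply(fits, `[[`, TRUE, "converged"),
             row.names = cells)
}

#' Per-gene detection statistics
#'
#' @param X log-scale expression matrix.
#' @return list with `detect_rate` (fraction of cells detecting each gene),
#'   `mu_detected` (mean log-expression over non-zero entries; `NaN` for
#'   never-detected genes) and `n_cells`.
#' @export
detection_stats <- function(X) {
  nz <- X > 0
  ndet <- rowSums(nz)
  list(detect_rate = ndet / ncol(X),
       mu_detected = rowSums(X) / ndet,
       n_cells = ncol(X))
}

#' Convert dropout curves into per-entry false-negative weights
#'
#' For a zero entry the posterior probability that the gene was expressed but
#' dropped is estimated from the cell's dropout curve evaluated at the gene's
#' detected mean, a detection prior equal to the gene's detection rate, and
#' the population mean of the per-cell detection probabilities; the estimate
#' is clipped to \[0, 1\] and the weight is its complement (the true-negative
#' probability). Non-zero entries have weight 1, as do genes never detected
#' anywhere (no information to call a dropout).
#'
#' @param X log-scale expression matrix (genes x cells).
#' @param curves data.frame from [fit_dropout_curves()].
#' @param stats list from [detection_stats()] (computed from `X` if missing).
#' @return weight matrix in \[0, 1\], same shape and dimnames as `X`.
#' @export
compute_false_negative_weights <- function(X, curves, stats = NULL) {
  check_expression_matrix(X)
  if (nrow(curves) != ncol(X)) stop("need one dropout curve per cell", call. = FALSE)
  if (is.null(stats)) stats <- detection_stats(X)
  dbar <- stats$detect_rate
  mu <- stats$mu_detected
  W <- matrix(1, nrow(X), ncol(X), dimnames = dimnames(X))
  est <- dbar > 0 & dbar < 1            # genes with both zeros and detections
  if (any(dbar == 1 & rowSums(X == 0) > 0)) {
    stop("internal corruption: gene with detection rate 1 has zero entries",
         call. = FALSE)
  }
  if (!any(est)) return(W)
  mu_e <- mu[est]
  # fhat[j, i]: dropout probability of gene i (at its detected mean) in cell j
  arg <- outer(curves$alpha, mu_e) - curves$alpha * curves$beta
  fhat <- 1 / (1 + exp(arg))
  p_detect_mean <- colMeans(1 - fhat)   # population mean of P(D | E) per gene
  prior_ratio <- dbar[est] / p_detect_mean / (1 - dbar[est])
  p_fn <- sweep(fhat, 2, prior_ratio, `*`)   # P(expressed | not detected)
  p_fn <- pmin(pmax(p_fn, 0), 1)
  w_sub <- 1 - p_fn                          # cells x genes(est)
  zero_sub <- t(X[est, , drop = FALSE] == 0) # cells x genes(est)
  w_full <- matrix(1, ncol(X), sum(est))
  w_full[zero_sub] <- w_sub[zero_sub]
  W[est, ] <- t(w_full)
  W
}

#' Per-cell quality scores from fitted dropout curves
#'
#' The area under a cell's dropout curve over the scaffold abundance range
#' measures how much of the expression spectrum the cell tends to miss; the
#' score is the negated, numerically integrated area so that higher is
#' better (0 is the best possible).
#'
#' @param curves data.frame from [fit_dropout_curves()].
#' @param scaffold the `quantile_scaffold` the curves were fitted to.
#' @return named numeric vector of scores (one per cell).
#' @export
compute_quality_scores <- function(curves, scaffold) {
  lo <- min(scaffold$mu)
  hi <- max(scaffold$mu)
  if (hi <= lo) stop("degenerate scaffold abundance range", call. = FALSE)
  scores <- vapply(seq_len(nrow(curves)), function(j) {
    -stats::integrate(dropout_sigmoid, lo, hi, alpha = curves$alpha[j],
                      beta = curves$beta[j], rel.tol = 1e-9)$value
  }, 0)
  stats::setNames(scores, rownames(curves))
}

#' QC filter on cell quality scores
#'
#' Removes cells scoring more than `n_mad` raw MAD units below the median
#' quality score (strict inequality, so identical scores keep every cell).
#' Off by default in the pipeline; enable via the config.
#'
#' @param scores named per-cell quality scores.
#' @param n_mad threshold multiplier (default 1.6).
#' @return character vector of kept cell ids.
#' @export
qc_filter_cells <- function(scores, n_mad = 1.6) {
  if (length(scores) < 3) stop("QC filter needs >= 3 cells", call. = FALSE)
  thr <- stats::median(scores) - n_mad * mad_raw(scores)
  kept <- names(scores)[scores >= thr]
  if (length(kept) == 0) {
    stop("QC filter removed every cell; review the threshold (", n_mad,
         " MAD)", call. = FALSE)
  }
  kept
}
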