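#' Z-normalize each gene across cells
#'
#' Subtracts the per-gene mean and divides by the per-gene standard
#' deviation. Zero-variance genes become all-zero rows (with a warning) so
#' they contribute nothing to signature scores.
#'
#' @param X log-scale expression matrix (genes x cells).
#' @return standardized matrix, same shape and dimnames.
#' @export
znormalize_genes <- function(X) {
  mu <- rowMeans(X)
  sdev <- apply(X, 1, stats::sd)
  flat <- sdev == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) set to all-zero rows", call. = FALSE)
    sdev[flat] <- 1
  }
  Xp <- (X - mu) / sdev
  Xp[flat, ] <- 0
  Xp
}

#' Score one signature against every cell
#'
#' The signature score of cell `j` is the weighted, signed average of the
#' standardized expression of the signature's genes:
#' `R_s(j) = sum_i sign(i) X'_ij w_ij / sum_i w_ij` over the signature genes
#' present in the matrix. Ranks use average-rank tie handling.
#'
#' @param Xp standardized matrix from [znormalize_genes()].
#' @param w weight matrix, same shape.
#' @param sig a `signature` object.
#' @return list with `name`, `scores` (per cell), `ranks` (average ranks in
#'   `[1, N]`), and `n_genes` (signature genes present), or `NULL` when no
#'   signature gene is present (with a warning).
#' @export
score_signature <- function(Xp, w, sig) {
  present <- intersect(names(sig$genes), rownames(Xp))
  if (length(present) == 0) {
    warning("signature '", sig$name, "' has no genes in the matrix; skipped",
            call. = FALSE)
    return(NULL)
  }
  missing <- setdiff(names(sig$genes), present)
  if (length(missing) > 0) {
    message("signature '", sig$name, "': ", length(missing),
            " gene(s) absent from the matrix")
  }
  s <- sig$genes[present]
  num <- colSums(s * Xp[present, , drop = FALSE] * w[present, , drop = FALSE])
  den <- colSums(w[present, , drop = FALSE])
  scores <- ifelse(den > 0, num / den, 0)
  list(name = sig$name, scores = scores,
       ranks = rank(scores, ties.method = "average"),
       n_genes = length(present))
}

# Gaussian neighborhood kernel on standardized 2-D coordinates; diagonal
# zeroed so each cell is predicted from its neighbors only.
projection_kernel <- function(coords, alpha = 0.33) {
  d2 <- as.matrix(stats::dist(coords))^2
  K <- exp(-d2 / alpha^2)
  diag(K) <- 0
  K
}

# K %*% r with per-row normalization; a row whose kernel mass underflowed to
# zero (a point farther than ~16 standardized units from every other, which
# standardization makes practically impossible) falls back to the column mean
kernel_smooth <- function(K, r, coords = NULL) {
  r <- as.matrix(r)
  rs <- rowSums(K)
  dead <- rs == 0
  if (any(dead)) {
    K[dead, ] <- 1
    K[cbind(which(dead), which(dead))] <- 0
    rs[dead] <- rowSums(K[dead, , drop = FALSE])
  }
  (K %*% r) / rs
}

#' Signature-projection consistency score
#'
#' Predicts each cell's signature rank from its neighbors in the projection
#' with a Gaussian kernel of width `alpha` (the effective neighborhood
#' size), then scores the fit as one minus the median absolute prediction
#' error normalized by the number of cells:
#' `rhat(j) = sum_{k != j} r(k) exp(-D_jk^2/alpha^2) / sum_{k != j} exp(-D_jk^2/alpha^2)`,
#' `consistency = 1 - median(|rhat - r|) / N`.
#'
#' @param ranks per-cell signature ranks.
#' @param coords standardized cells x 2 coordinates.
#' @param alpha neighborhood width (default 0.33).
#' @param K optional pre-computed kernel from `projection_kernel(coords,
#'   alpha)`, reused across many signatures.
#' @return list with `predicted` (per-cell predicted ranks) and
#'   `consistency`.
#' @export
consistency_score <- function(ranks, coords, alpha = 0.33, K = NULL) {
  n <- length(ranks)
  if (n < 2) stop("consistency needs >= 2 cells", call. = FALSE)
  if (is.null(K)) K <- projection_kernel(coords, alpha)
  rhat <- as.vector(kernel_smooth(K, matrix(ranks, ncol = 1)))
  list(predicted = rhat,
       consistency = 1 - stats::median(abs(rhat - ranks)) / n)
}

#' Random-signature background model
#'
#' For each signature size bin, draws `n_draws` signatures of randomly
#' selected genes with random +/-1 signs, scores them, and records the mean
#' and standard deviation of their consistency under every projection. Size
#' bins larger than the gene pool are skipped with a warning.
#'
#' @param Xp standardized matrix.
#' @param w weight matrix.
#' @param projections named list of projection results (from
#'   [run_all_projections()]).
#' @param pool gene ids to draw from (default all matrix genes).
#' @param sizes signature size bins (default 10, 20, 50, 100, 200).
#' @param n_draws draws per bin (default 1000).
#' @param alpha neighborhood width.
#' @param seed RNG seed.
#' @return object of class `background_model`: list per projection name of a
#'   data.frame (size, mean, sd, n_draws).
#' @export
build_random_background <- function(Xp, w, projections, pool = rownames(Xp),
                                    sizes = c(10, 20, 50, 100, 200),
                                    n_draws = 1000, alpha = 0.33, seed = 1) {
  set.seed(seed)
  usable <- sizes[sizes <= length(pool)]
  skipped <- setdiff(sizes, usable)
  if (length(skipped) > 0) {
    warning("background size bin(s) larger than the gene pool skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  n <- ncol(Xp)
  kernels <- lapply(projections, function(p) projection_kernel(p$coords, alpha))
  out <- lapply(projections, function(p) {
    data.frame(size = numeric(0), mean = numeric(0), sd = numeric(0),
               n_draws = numeric(0))
  })
  for (size in usable) {
    ranks <- matrix(0, n, n_draws)
    for (b in seq_len(n_draws)) {
      genes <- sample(pool, size)
      signs <- sample(c(-1, 1), size, replace = TRUE)
      num <- colSums(signs * Xp[genes, , drop = FALSE] * w[genes, , drop = FALSE])
      den <- colSums(w[genes, , drop = FALSE])
      sc <- ifelse(den > 0, num / den, 0)
      ranks[, b] <- rank(sc, ties.method = "average")
    }
    for (nm in names(projections)) {
      rhat <- kernel_smooth(kernels[[nm]], ranks)
      cons <- 1 - apply(abs(rhat - ranks), 2, stats::median) / n
      out[[nm]] <- rbind(out[[nm]],
                         data.frame(size = size, mean = mean(cons),
                                    sd = stats::sd(cons), n_draws = n_draws))
    }
  }
  structure(out, class = "background_model")
}

#' Z-test significance of observed consistencies against the background
#'
#' Each observed consistency is compared against the background bin whose
#' signature size is nearest the signature's present-gene count (ties to the
#' smaller bin) with a one-sided upper-tail Z-test; BH correction is applied
#' across the full signature x projection grid.
#'
#' @param consistency signatures x projections matrix.
#' @param sig_sizes per-signature present-gene counts (row order).
#' @param background a `background_model`.
#' @return list with matrices `p` and `q` (same shape as `consistency`).
#' @export
significance_test <- function(consistency, sig_sizes, background) {
  p <- consistency
  p[] <- NA_real_
  for (j in colnames(consistency)) {
    bg <- background[[j]]
    if (is.null(bg) || nrow(bg) == 0) next
    for (i in seq_len(nrow(consistency))) {
      gap <- abs(bg$size - sig_sizes[i])
      row <- bg[order(gap, bg$size), ][1, ] # nearest size, ties -> smaller
      if (row$sd == 0) {
        warning("zero background sd for projection ", j, "; p set to 1",
                call. = FALSE)
        p[i, j] <- 1
      } else {
        p[i, j] <- stats::pnorm((consistency[i, j] - row$mean) / row$sd,
                                lower.tail = FALSE)
      }
    }
  }
  q <- p
  q[] <- stats::p.adjust(as.vector(p), method = "BH")
  list(p = p, q = q)
}

#' Consistency and shuffle-null significance for a numeric pre-computed signature
#'
#' The per-cell values are rank-transformed and scored with
#' [consistency_score()]; the null distribution comes from shuffling the
#' values among cells `n_shuffles` times, and the p-value from a Z-test
#' against that distribution. Constant values give consistency 1 and p 1.
#'
#' @param values named per-cell numeric values.
#' @param coords standardized cells x 2 coordinates.
#' @param alpha neighborhood width (default 0.33).
#' @param n_shuffles shuffle draws (default 1000).
#' @param seed RNG seed.
#' @param K optional pre-computed kernel.
#' @return list with `consistency` and `p`.
#' @export
numeric_precomputed_significance <- function(values, coords, alpha = 0.33,
                                             n_shuffles = 1000, seed = 1,
                                             K = NULL) {
  if (length(unique(values)) == 1) {
    return(list(consistency = 1, p = 1))
  }
  set.seed(seed)
  if (is.null(K)) K <- projection_kernel(coords, alpha)
  n <- length(values)
  r <- rank(values, ties.method = "average")
  obs <- consistency_score(r, coords, alpha, K = K)$consistency
  shuf <- matrix(0, n, n_shuffles)
  for (b in seq_len(n_shuffles)) shuf[, b] <- sample(r)
  rhat <- kernel_smooth(K, shuf)
  null <- 1 - apply(abs(rhat - shuf), 2, stats::median) / n
  sdev <- stats::sd(null)
  p <- if (sdev == 0) 1 else stats::pnorm((obs - mean(null)) / sdev, lower.tail = FALSE)
  list(consistency = obs, p = p)
}

#' Consistency and shuffle-null significance for a categorical signature
#'
#' Per cell, the neighborhood label agreement
#' `Lhat(j) = sum_{k != j} [label_k == label_j] exp(-D_jk^2/alpha^2) / sum_{k != j} exp(-D_jk^2/alpha^2)`
#' is computed; the consistency is the median of `Lhat` over cells. The null
#' comes from shuffling the labels; significance is a Z-test as for numeric
#' signatures. A single label gives consistency 1 and p 1.
#'
#' @param labels named per-cell labels (character or factor).
#' @param coords standardized cells x 2 coordinates.
#' @param alpha neighborhood width (default 0.33).
#' @param n_shuffles shuffle draws (default 1000).
#' @param seed RNG seed.
#' @param K optional pre-computed kernel.
#' @return list with `consistency` and `p`.
#' @export
categorical_consistency <- function(labels, coords, alpha = 0.33,
                                    n_shuffles = 1000, seed = 1, K = NULL) {
  n <- length(labels)
  if (n < 2) stop("categorical consistency needs >= 2 cells", call. = FALSE)
  labels <- as.character(labels)
  if (length(unique(labels)) == 1) {
    return(list(consistency = 1, p = 1))
  }
  set.seed(seed)
  if (is.null(K)) K <- projection_kernel(coords, alpha)
  lhat_median <- function(lab) {
    same <- outer(lab, lab, `==`) * 1
    num <- rowSums(K * same)
    den <- rowSums(K)
    stats::median(ifelse(den > 0, num / den, 1))
  }
  obs <- lhat_median(labels)
  null <- vapply(seq_len(n_shuffles), function(b) lhat_median(sample(labels)), 0)
  sdev <- stats::sd(null)
  p <- if (sdev == 0) 1 else stats::pnorm((obs - mean(null)) / sdev, lower.tail = FALSE)
  list(consistency = obs, p = p)
}
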