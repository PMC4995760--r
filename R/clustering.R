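#' Seeded k-means on 2-D projection coordinates
#'
#' k-means with k-means++ style center initialization drawn from the seeded
#' RNG, so assignments are deterministic per seed. `k = 1` is permitted as
#' the degenerate grid entry.
#'
#' @param coords standardized cells x 2 coordinates.
#' @param k number of clusters (1 <= k <= cells).
#' @param seed RNG seed.
#' @return integer vector of cluster labels in `1..k`, named by cell.
#' @export
kmeans_2d <- function(coords, k, seed = 1) {
  n <- nrow(coords)
  if (k > n) stop("k = ", k, " exceeds the number of cells (", n, ")", call. = FALSE)
  if (k == 1) return(stats::setNames(rep(1L, n), rownames(coords)))
  set.seed(seed)
  centers <- matrix(0, k, 2)
  centers[1, ] <- coords[sample.int(n, 1), ]
  for (c in 2:k) {
    d2 <- apply(coords, 1, function(p) {
      min(colSums((t(centers[seq_len(c - 1), , drop = FALSE]) - p)^2))
    })
    if (all(d2 == 0)) {
      centers[c, ] <- coords[sample.int(n, 1), ]
    } else {
      centers[c, ] <- coords[sample.int(n, 1, prob = d2), ]
    }
  }
  centers <- unique(centers)
  fit <- suppressWarnings(stats::kmeans(coords, centers = centers, iter.max = 50))
  stats::setNames(as.integer(fit$cluster), rownames(coords))
}

#' Per-cluster mean of standardized expression for signature genes
#'
#' @param Xp standardized matrix from [znormalize_genes()].
#' @param sig a `signature` object.
#' @param labels per-cell cluster labels (from [kmeans_2d()]).
#' @return clusters x genes matrix of mean z-scores; empty clusters give
#'   `NA` rows.
#' @export
cluster_expression_summary <- function(Xp, sig, labels) {
  genes <- intersect(names(sig$genes), rownames(Xp))
  if (length(genes) == 0) stop("no signature genes in the matrix", call. = FALSE)
  ks <- sort(unique(labels))
  out <- matrix(NA_real_, length(ks), length(genes),
                dimnames = list(paste0("cluster", ks), genes))
  for (i in seq_along(ks)) {
    cells <- names(labels)[labels == ks[i]]
    if (length(cells) > 0) {
      out[i, ] <- rowMeans(Xp[genes, cells, drop = FALSE])
    }
  }
  out
}
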