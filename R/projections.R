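#' Weighted covariance matrix
#'
#' Gene-by-gene covariance where each product term is down-weighted by the
#' false-negative weights of both entries:
#' `cov(a, b) = sum_j (X_aj - Xbar_a)(X_bj - Xbar_b) w_aj w_bj / sum_j w_aj w_bj`
#' with `Xbar_a` the w-weighted mean of gene `a`. With unit weights this is
#' the population covariance. A gene pair whose weight products sum to zero
#' gets entry 0 with a warning.
#'
#' @param X log-scale expression matrix (genes x cells).
#' @param w weight matrix, same shape.
#' @return symmetric genes x genes matrix.
#' @export
weighted_covariance <- function(X, w) {
  stopifnot(all(dim(X) == dim(w)))
  wm <- rowSums(X * w) / rowSums(w)
  Xc <- (X - wm) * w
  num <- tcrossprod(Xc)
  den <- tcrossprod(w)
  zero <- den == 0
  if (any(zero)) {
    warning(sum(zero), " gene pair(s) with no jointly weighted cells; ",
            "covariance entries set to 0", call. = FALSE)
    den[zero] <- 1
    num[zero] <- 0
  }
  cv <- num / den
  (cv + t(cv)) / 2
}

#' Weighted PCA
#'
#' Eigendecomposition of the weighted covariance matrix; cells are projected
#' onto the top `k` eigenvectors of the (weight-centered) expression. Each
#' component's sign is fixed so that its largest-magnitude gene loading is
#' positive, making results reproducible across platforms.
#'
#' @param X log-scale expression matrix (genes x cells).
#' @param w weight matrix, same shape.
#' @param k number of components.
#' @return list with `scores` (cells x k), `evals` (non-increasing),
#'   `loadings` (genes x k).
#' @export
weighted_pca <- function(X, w, k = 2) {
  k <- min(k, nrow(X), ncol(X))
  cv <- weighted_covariance(X, w)
  if (any(!is.finite(cv))) stop("non-finite weighted covariance", call. = FALSE)
  ed <- eigen(cv, symmetric = TRUE)
  vec <- ed$vectors[, seq_len(k), drop = FALSE]
  flip <- apply(vec, 2, function(v) sign(v[which.max(abs(v))]))
  vec <- sweep(vec, 2, flip, `*`)
  wm <- rowSums(X * w) / rowSums(w)
  scores <- crossprod(X - wm, vec)
  rownames(scores) <- colnames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, evals = ed$values[seq_len(k)], loadings = vec)
}

#' Number of significant principal components by randomization
#'
#' Each gene's values (jointly with its weights) are independently permuted
#' across cells `n_perm` times and the weighted-PCA eigenvalues recomputed.
#' Component `r` is significant when its observed eigenvalue exceeds the
#' `1 - p_cut` quantile of the permuted rank-`r` eigenvalues. The count of
#' leading significant components is returned, floored at `min_pc` (default
#' 5) and capped at `min(genes, cells)`.
#'
#' @param X log-scale expression matrix (genes x cells).
#' @param w weight matrix.
#' @param n_perm number of permutations (default 100).
#' @param p_cut significance level (default 0.05).
#' @param min_pc minimum retained count (default 5).
#' @param seed RNG seed.
#' @return integer count of retained components.
#' @export
count_significant_pcs <- function(X, w, n_perm = 100, p_cut = 0.05,
                                  min_pc = 5, seed = 1) {
  if (n_perm < 20) warning("n_perm < 20 gives poor p-value resolution", call. = FALSE)
  kmax <- min(dim(X))
  obs <- eigen(weighted_covariance(X, w), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  perm <- matrix(0, kmax, n_perm)
  n <- ncol(X)
  for (b in seq_len(n_perm)) {
    Xp <- X
    wp <- w
    for (i in seq_len(nrow(X))) {
      o <- sample.int(n)
      Xp[i, ] <- X[i, o]
      wp[i, ] <- w[i, o]
    }
    ev <- eigen(weighted_covariance(Xp, wp), symmetric = TRUE, only.values = TRUE)$values
    perm[, b] <- ev[seq_len(kmax)]
  }
  thr <- apply(perm, 1, stats::quantile, probs = 1 - p_cut)
  sig <- obs[seq_len(kmax)] > thr
  lead <- if (!sig[1]) 0L else if (all(sig)) kmax else which(!sig)[1] - 1L
  min(max(lead, min_pc), kmax)
}

#' The projection-method registry
#'
#' Eleven two-dimensional projection methods: three principal-component
#' pairs (1-2, 1-3, 2-3), ICA, t-SNE at perplexities 10 and 30, ISOMAP with
#' 4 nearest neighbors, classical MDS, spectral embedding on a
#' `floor(cells/10)`-nearest-neighbor graph, and kernel PCA with an RBF
#' kernel (coefficient `1/#features`) and with a linear kernel.
#'
#' @return character vector of the 11 registry keys.
#' @export
projection_registry <- function() {
  c("PCA_1_2", "PCA_1_3", "PCA_2_3", "ICA", "tSNE_10", "tSNE_30",
    "ISOMAP", "MDS", "SpectralEmbedding", "KernelPCA_RBF", "KernelPCA_linear")
}

pca_pair_methods <- function() c("PCA_1_2", "PCA_1_3", "PCA_2_3")

# methods that build a neighborhood graph and need a minimum cell count
neighborhood_methods <- function() c("tSNE_10", "tSNE_30", "ISOMAP", "SpectralEmbedding")

#' Run a single registry projection method
#'
#' @param data numeric matrix (cells x features); for the PCA pair methods a
#'   3-component decomposition of `data` is computed and the named pair
#'   returned.
#' @param method a key from [projection_registry()].
#' @param seed RNG seed; results are deterministic given the seed.
#' @return raw cells x 2 coordinate matrix (rownames = cells).
#' @export
run_projection_method <- function(data, method, seed = 1) {
  if (!method %in% projection_registry()) {
    stop("unknown projection method: ", method, call. = FALSE)
  }
  n <- nrow(data)
  if (n < 10 && method %in% neighborhood_methods()) {
    stop(method, " needs >= 10 cells to build a neighborhood graph (got ",
         n, ")", call. = FALSE)
  }
  set.seed(seed)
  co <- switch(method,
    PCA_1_2 = ,
    PCA_1_3 = ,
    PCA_2_3 = {
      pair <- as.integer(strsplit(method, "_")[[1]][2:3])
      k <- min(3, n - 1, ncol(data))
      p <- stats::prcomp(data, rank. = k)
      if (max(pair) > ncol(p$x)) stop("data rank too low for ", method, call. = FALSE)
      p$x[, pair]
    },
    ICA = fast_ica(data, n_comp = 2, seed = seed),
    tSNE_10 = run_tsne(data, perplexity = 10),
    tSNE_30 = run_tsne(data, perplexity = 30),
    ISOMAP = {
      fit <- vegan::isomap(stats::dist(data), ndim = 2, k = 4)
      fit$points[, 1:2]
    },
    MDS = stats::cmdscale(stats::dist(data), k = 2),
    SpectralEmbedding = spectral_embedding(data, k_neighbors = max(2L, floor(n / 10))),
    KernelPCA_RBF = {
      kp <- kernlab::kpca(data, kernel = "rbfdot",
                          kpar = list(sigma = 1 / ncol(data)), features = 2)
      kernlab::rotated(kp)
    },
    KernelPCA_linear = {
      kp <- kernlab::kpca(data, kernel = "vanilladot", kpar = list(), features = 2)
      kernlab::rotated(kp)
    })
  co <- as.matrix(co)
  if (ncol(co) < 2) stop(method, " returned fewer than 2 dimensions", call. = FALSE)
  co <- co[, 1:2, drop = FALSE]
  rownames(co) <- rownames(data)
  colnames(co) <- c("x", "y")
  co
}

# t-SNE with the perplexity capped to Rtsne's requirement 3*perp < n - 1
run_tsne <- function(data, perplexity) {
  n <- nrow(data)
  if (3 * perplexity >= n - 1) {
    stop("t-SNE perplexity ", perplexity, " too large for ", n, " cells",
         call. = FALSE)
  }
  fit <- Rtsne::Rtsne(data, dims = 2, perplexity = perplexity, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE)
  fit$Y
}

#' Standardize 2-D coordinates
#'
#' Mean-centers both columns and rescales so the mean squared radius
#' `mean(x^2 + y^2)` equals 1, making consistency scores comparable across
#' projections.
#'
#' @param raw cells x 2 coordinate matrix.
#' @return standardized cells x 2 matrix.
#' @export
standardize_coordinates <- function(raw) {
  stopifnot(ncol(raw) == 2)
  if (nrow(unique(raw)) < 2) {
    stop("all projected points coincide; cannot standardize", call. = FALSE)
  }
  co <- sweep(raw, 2, colMeans(raw))
  r2 <- mean(rowSums(co^2))
  co / sqrt(r2)
}

#' Enumerate the projection configuration grid
#'
#' For each gene-set option: all 11 registry methods on the non-reduced data
#' plus the 8 non-PCA-pair methods on the PCA-reduced data. With the default
#' four gene-set options this yields 76 configurations.
#'
#' @param gene_set_names names of the available gene-set options.
#' @param registry method registry (default [projection_registry()]).
#' @return data.frame with columns `gene_set`, `method`, `pca_first`, `name`.
#' @export
enumerate_configurations <- function(gene_set_names,
                                     registry = projection_registry()) {
  rows <- list()
  for (gs in gene_set_names) {
    for (m in registry) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_set = gs, method = m, pca_first = FALSE, stringsAsFactors = FALSE)
    }
    for (m in setdiff(registry, pca_pair_methods())) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_set = gs, method = m, pca_first = TRUE, stringsAsFactors = FALSE)
    }
  }
  cfg <- do.call(rbind, rows)
  cfg$name <- paste0(cfg$gene_set, "__", cfg$method, "__",
                     ifelse(cfg$pca_first, "pca", "nopca"))
  cfg
}

#' Run every projection configuration
#'
#' Per gene set, a weighted PCA is computed once; the PCA pair methods read
#' their component pairs from it, `pca_first` configurations run on the
#' reduced matrix (dimension chosen by [count_significant_pcs()]), and the
#' remaining configurations run on the full cells x genes matrix. Every
#' result is standardized. A failing method is skipped with a message; the
#' run continues.
#'
#' @param X log-scale expression matrix (genes x cells).
#' @param w weight matrix.
#' @param options named list of gene-set options (see
#'   [assemble_gene_set_options()]).
#' @param master_seed master seed; per-configuration seeds are derived from
#'   it and the configuration name.
#' @param n_perm,pc_p,pc_min significant-PC selection parameters.
#' @return named list of projection results, each with `config` (one-row
#'   data.frame) and `coords` (standardized cells x 2 matrix).
#' @export
run_all_projections <- function(X, w, options, master_seed = 1,
                                n_perm = 100, pc_p = 0.05, pc_min = 5) {
  cfg <- enumerate_configurations(names(options))
  results <- list()
  for (gs in names(options)) {
    genes <- options[[gs]]
    Xg <- X[genes, , drop = FALSE]
    wg <- w[genes, , drop = FALSE]
    npc <- count_significant_pcs(Xg, wg, n_perm = n_perm, p_cut = pc_p,
                                 min_pc = pc_min,
                                 seed = derive_seed(master_seed, paste0("npc:", gs)))
    wp <- weighted_pca(Xg, wg, k = max(3, npc))
    full <- t(Xg)
    reduced <- wp$scores[, seq_len(min(npc, ncol(wp$scores))), drop = FALSE]
    for (i in which(cfg$gene_set == gs)) {
      row <- cfg[i, ]
      seed_i <- derive_seed(master_seed, row$name)
      res <- tryCatch({
        raw <- if (row$method %in% pca_pair_methods()) {
          pair <- as.integer(strsplit(row$method, "_")[[1]][2:3])
          wp$scores[, pair, drop = FALSE]
        } else {
          run_projection_method(if (row$pca_first) reduced else full,
                                row$method, seed = seed_i)
        }
        co <- standardize_coordinates(raw)
        rownames(co) <- colnames(X)
        colnames(co) <- c("x", "y")
        list(config = row, coords = co)
      }, error = function(e) {
        message("projection ", row$name, " failed: ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) results[[row$name]] <- res
    }
  }
  results
}
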