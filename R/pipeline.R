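#' Pipeline configuration
#'
#' Collects every tunable default of the analysis in one place.
#'
#' @param prefilter_fraction detection pre-filter fraction (default 0.20).
#' @param dip_p dip-test p cutoff (default 0.05).
#' @param dip_draws Monte-Carlo draws for the dip null (default 1000).
#' @param fano_mad Fano-filter MAD multiplier (default 2).
#' @param neighborhood_alpha Gaussian neighborhood width for consistency
#'   (default 0.33).
#' @param qc_enabled apply the cell QC filter (default `FALSE`).
#' @param qc_mad QC MAD multiplier (default 1.6).
#' @param pc_p significant-PC p cutoff (default 0.05).
#' @param pc_min minimum retained components (default 5).
#' @param n_perm permutations for significant-PC selection (default 100).
#' @param background_draws random signatures per size bin (default 1000).
#' @param size_bins background signature sizes (default 10, 20, 50, 100, 200).
#' @param precomputed_shuffles shuffle draws for pre-computed signature
#'   nulls (default 1000).
#' @param fdr significance threshold on BH q-values (default 0.05).
#' @param kmeans_ks cluster-count grid (default 2:7).
#' @param master_seed master RNG seed (default 1).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(prefilter_fraction = 0.20, dip_p = 0.05,
                            dip_draws = 1000, fano_mad = 2,
                            neighborhood_alpha = 0.33, qc_enabled = FALSE,
                            qc_mad = 1.6, pc_p = 0.05, pc_min = 5,
                            n_perm = 100, background_draws = 1000,
                            size_bins = c(10, 20, 50, 100, 200),
                            precomputed_shuffles = 1000, fdr = 0.05,
                            kmeans_ks = 2:7, master_seed = 1) {
  cfg <- list(prefilter_fraction = prefilter_fraction, dip_p = dip_p,
              dip_draws = dip_draws, fano_mad = fano_mad,
              neighborhood_alpha = neighborhood_alpha, qc_enabled = qc_enabled,
              qc_mad = qc_mad, pc_p = pc_p, pc_min = pc_min, n_perm = n_perm,
              background_draws = background_draws, size_bins = size_bins,
              precomputed_shuffles = precomputed_shuffles, fdr = fdr,
              kmeans_ks = kmeans_ks, master_seed = master_seed)
  probs <- c(cfg$prefilter_fraction, cfg$dip_p, cfg$pc_p, cfg$fdr)
  stopifnot(all(probs > 0), all(probs <= 1),
            cfg$dip_draws > 0, cfg$n_perm > 0, cfg$background_draws > 0,
            cfg$pc_min > 0, all(cfg$size_bins > 0), all(cfg$kmeans_ks >= 1))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates: housekeeping quantile scaffold -> per-cell dropout curves
#' -> false-negative weights (-> optional cell QC) -> gene-set options ->
#' projection grid -> signature scores -> random-signature backgrounds ->
#' consistency, Z-test p-values and BH q-values -> k-means clustering.
#' Two numeric pre-computed signatures are always injected: the per-cell
#' quality score ("QUALITY_SCORE") and the per-cell fraction of undetected
#' genes ("ZERO_FRACTION"), so the association of every projection with data
#' quality is reported alongside the biology.
#'
#' @param X log-scale expression matrix (genes x cells), e.g. from
#'   [read_expression_matrix()].
#' @param signatures list of `signature` objects (from [read_gmt()]).
#' @param housekeeping character vector of housekeeping gene ids; when
#'   `NULL`, genes detected in at least 95 percent of cells are used.
#' @param precomputed optional list of `precomputed_signature` objects.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, [write_outputs()]
#'   is called on the results.
#' @param report write the HTML report when writing outputs.
#' @return a results bundle (list) with elements `weights`, `quality`,
#'   `gene_sets`, `projections`, `signature_scores`, `consistency`,
#'   `p_values`, `q_values`, `significant`, `clusters`, `background`,
#'   `config`, and `manifest` when `out_dir` is given.
#' @export
run_pipeline <- function(X, signatures, housekeeping = NULL,
                         precomputed = NULL, config = pipeline_config(),
                         out_dir = NULL, report = TRUE) {
  check_expression_matrix(X)
  seed <- config$master_seed

  if (is.null(housekeeping)) {
    housekeeping <- rownames(X)[rowMeans(X > 0) >= 0.95]
    message("no housekeeping list supplied; using ", length(housekeeping),
            " genes detected in >= 95% of cells")
  }
  scaffold <- build_quantile_scaffold(X, housekeeping)
  curves <- fit_dropout_curves(scaffold)
  quality <- compute_quality_scores(curves, scaffold)

  if (config$qc_enabled) {
    kept <- qc_filter_cells(quality, n_mad = config$qc_mad)
    if (length(kept) < ncol(X)) {
      message("QC filter removed ", ncol(X) - length(kept), " cell(s)")
      X <- X[, kept, drop = FALSE]
      scaffold <- build_quantile_scaffold(X, housekeeping)
      curves <- fit_dropout_curves(scaffold)
      quality <- compute_quality_scores(curves, scaffold)
    }
  }

  W <- compute_false_negative_weights(X, curves)

  gene_sets <- assemble_gene_set_options(
    X, prefilter_fraction = config$prefilter_fraction, dip_p = config$dip_p,
    dip_draws = config$dip_draws, fano_mad = config$fano_mad,
    seed = derive_seed(seed, "dip_null"))

  projections <- run_all_projections(X, W, gene_sets, master_seed = seed,
                                     n_perm = config$n_perm,
                                     pc_p = config$pc_p, pc_min = config$pc_min)
  if (length(projections) == 0) stop("every projection failed", call. = FALSE)

  Xp <- znormalize_genes(X)
  scored <- Filter(Negate(is.null),
                   lapply(signatures, function(s) score_signature(Xp, W, s)))
  score_mat <- if (length(scored) > 0) {
    do.call(rbind, lapply(scored, `[[`, "scores"))
  } else {
    matrix(0, 0, ncol(X), dimnames = list(NULL, colnames(X)))
  }
  rownames(score_mat) <- vapply(scored, `[[`, "", "name")

  alpha <- config$neighborhood_alpha
  pool <- gene_sets$Threshold
  if (is.null(pool)) pool <- rownames(X)
  background <- build_random_background(
    Xp, W, projections, pool = pool, sizes = config$size_bins,
    n_draws = config$background_draws, alpha = alpha,
    seed = derive_seed(seed, "background"))

  proj_names <- names(projections)
  kernels <- lapply(projections, function(p) projection_kernel(p$coords, alpha))
  cons <- matrix(NA_real_, length(scored), length(proj_names),
                 dimnames = list(rownames(score_mat), proj_names))
  for (i in seq_along(scored)) {
    for (j in proj_names) {
      cons[i, j] <- consistency_score(scored[[i]]$ranks,
                                      projections[[j]]$coords, alpha,
                                      K = kernels[[j]])$consistency
    }
  }
  sig_sizes <- vapply(scored, `[[`, 0, "n_genes")
  sig_test <- significance_test(cons, sig_sizes, background)

  # pre-computed signatures: injected quality metrics plus any user-supplied
  zero_frac <- colMeans(X == 0)
  injected <- list(
    structure(list(name = "QUALITY_SCORE", kind = "numeric", values = quality),
              class = "precomputed_signature"),
    structure(list(name = "ZERO_FRACTION", kind = "numeric", values = zero_frac),
              class = "precomputed_signature"))
  pre_all <- c(injected, precomputed)
  pre_cons <- matrix(NA_real_, length(pre_all), length(proj_names),
                     dimnames = list(vapply(pre_all, `[[`, "", "name"), proj_names))
  pre_p <- pre_cons
  pre_scores <- matrix(NA_real_, length(pre_all), ncol(X),
                       dimnames = list(rownames(pre_cons), colnames(X)))
  for (i in seq_along(pre_all)) {
    ps <- pre_all[[i]]
    v <- ps$values[colnames(X)]
    names(v) <- colnames(X)
    if (anyNA(v)) {
      warning("pre-computed signature '", ps$name, "' missing ",
              sum(is.na(v)), " cell(s); skipped", call. = FALSE)
      next
    }
    if (ps$kind == "numeric") pre_scores[i, ] <- as.numeric(v)
    for (j in proj_names) {
      r <- if (ps$kind == "numeric") {
        numeric_precomputed_significance(
          as.numeric(v), projections[[j]]$coords, alpha,
          n_shuffles = config$precomputed_shuffles,
          seed = derive_seed(seed, paste0("pre:", ps$name, ":", j)),
          K = kernels[[j]])
      } else {
        categorical_consistency(
          v, projections[[j]]$coords, alpha,
          n_shuffles = config$precomputed_shuffles,
          seed = derive_seed(seed, paste0("pre:", ps$name, ":", j)),
          K = kernels[[j]])
      }
      pre_cons[i, j] <- r$consistency
      pre_p[i, j] <- r$p
    }
  }
  keep_pre <- !apply(pre_cons, 1, anyNA)
  pre_cons <- pre_cons[keep_pre, , drop = FALSE]
  pre_p <- pre_p[keep_pre, , drop = FALSE]
  pre_scores <- pre_scores[keep_pre, , drop = FALSE]

  all_cons <- rbind(cons, pre_cons)
  all_p <- rbind(sig_test$p, pre_p)
  all_q <- all_p
  all_q[] <- stats::p.adjust(as.vector(all_p), method = "BH")
  numeric_pre <- !apply(pre_scores, 1, anyNA)
  all_scores <- rbind(score_mat, pre_scores[numeric_pre, , drop = FALSE])

  clusters <- list()
  for (j in proj_names) {
    rows <- list()
    for (k in config$kmeans_ks) {
      if (k > ncol(X)) next
      lab <- kmeans_2d(projections[[j]]$coords, k,
                       seed = derive_seed(seed, paste0("kmeans:", j, ":", k)))
      rows[[length(rows) + 1]] <- data.frame(cell_id = names(lab), k = k,
                                             label = as.integer(lab))
    }
    clusters[[j]] <- do.call(rbind, rows)
  }

  results <- list(
    weights = W, quality = quality, gene_sets = gene_sets,
    projections = projections, signature_scores = all_scores,
    consistency = all_cons, p_values = all_p, q_values = all_q,
    significant = rownames(all_q)[apply(all_q < config$fdr, 1, any)],
    clusters = clusters, background = background, signatures = signatures,
    expression = X, config = unclass(config))
  if (!is.null(out_dir)) {
    results$manifest <- write_outputs(results, out_dir, report = report)
  }
  results
}
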