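#' Detection pre-filter
#'
#' Keeps genes detected (expression > 0) in at least `ceiling(fraction * N)`
#' cells. The default fraction is 0.20 of the input cells.
#'
#' @param X log-scale expression matrix (genes x cells).
#' @param fraction minimum detection fraction in (0, 1].
#' @return character vector of kept gene ids (matrix order).
#' @export
detection_prefilter <- function(X, fraction = 0.20) {
  stopifnot(fraction > 0, fraction <= 1)
  ndet <- rowSums(X > 0)
  need <- ceiling(fraction * ncol(X))
  keep <- rownames(X)[ndet >= need]
  if (length(keep) == 0) {
    h <- table(ndet)
    stop("detection pre-filter removed every gene (need >= ", need,
         " detecting cells). Genes per detection count: ",
         paste(names(h), h, sep = " cells:", collapse = ", "), call. = FALSE)
  }
  keep
}

#' Bimodal gene selection by Hartigan's dip test
#'
#' Computes the dip statistic of each gene's expression values across cells
#' and a Monte-Carlo p-value from `B` same-size uniform null samples (the dip
#' is rank-based, so the uniform is the canonical unimodal null and one null
#' table serves every gene). Genes with p below the cutoff are retained;
#' constant genes are excluded with a warning.
#'
#' @param X log-scale expression matrix.
#' @param genes gene subset to test (default all).
#' @param p_cut p-value cutoff (default 0.05).
#' @param B Monte-Carlo null draws (default 1000).
#' @param seed RNG seed for the null draws.
#' @return character vector of retained gene ids.
#' @export
dip_filter <- function(X, genes = rownames(X), p_cut = 0.05, B = 1000, seed = 1) {
  if (ncol(X) < 10) stop("dip filter needs >= 10 cells", call. = FALSE)
  constant <- genes[apply(X[genes, , drop = FALSE], 1, function(v) max(v) == min(v))]
  if (length(constant) > 0) {
    warning(length(constant), " constant gene(s) excluded from the dip filter",
            call. = FALSE)
    genes <- setdiff(genes, constant)
  }
  if (length(genes) == 0) return(character(0))
  null <- dip_null_distribution(ncol(X), B = B, seed = seed)
  stats <- apply(X[genes, , drop = FALSE], 1, dip_statistic)
  p <- (1 + vapply(stats, function(s) sum(null >= s), 0L)) / (1 + B)
  genes[p < p_cut]
}

#' Highly-variable gene selection by stratified Fano factor
#'
#' The Fano factor (variance over mean) exceeds 1 when a gene is more
#' variable than a Poisson steady state. Genes are stratified into
#' equal-count quantile bins by mean expression and, within each bin, kept
#' when their Fano factor exceeds the bin median by more than `n_mad` raw
#' MADs. Genes with zero mean are excluded before stratification. 30 bins
#' are used, shrinking to `min(30, floor(#genes / 5))` below 150 genes.
#'
#' @param X log-scale expression matrix.
#' @param genes gene subset to consider (default all).
#' @param n_mad MAD multiplier (default 2).
#' @return character vector of selected gene ids.
#' @export
fano_filter <- function(X, genes = rownames(X), n_mad = 2) {
  if (length(genes) < 30) stop("Fano filter needs >= 30 genes", call. = FALSE)
  sub <- X[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  genes <- genes[mu > 0]
  mu <- mu[mu > 0]
  v <- apply(sub[genes, , drop = FALSE], 1, stats::var)
  fano <- v / mu
  ng <- length(genes)
  nbins <- if (ng < 150) max(1, min(30, floor(ng / 5))) else 30
  ord <- order(mu, genes)
  bin <- integer(ng)
  bin[ord] <- ceiling(nbins * seq_len(ng) / ng)
  keep <- logical(ng)
  for (q in seq_len(nbins)) {
    idx <- which(bin == q)
    thr <- stats::median(fano[idx]) + n_mad * mad_raw(fano[idx])
    keep[idx] <- fano[idx] > thr
  }
  genes[keep]
}

#' Assemble the gene-set options for the projection grid
#'
#' Returns the four nested gene sets that parameterize projections:
#' `None` (all input genes), `Threshold` (detection pre-filter), `Bimodal`
#' (dip filter applied to `Threshold`) and `HighFano` (Fano filter applied to
#' `Threshold`). Empty subsets are dropped with a warning, shrinking the
#' configuration grid.
#'
#' @param X log-scale expression matrix.
#' @param prefilter_fraction detection fraction (default 0.20).
#' @param dip_p dip-test cutoff (default 0.05).
#' @param dip_draws Monte-Carlo null draws for the dip test.
#' @param fano_mad MAD multiplier for the Fano filter (default 2).
#' @param seed RNG seed for the dip null.
#' @return named list of gene-id vectors.
#' @export
assemble_gene_set_options <- function(X, prefilter_fraction = 0.20,
                                      dip_p = 0.05, dip_draws = 1000,
                                      fano_mad = 2, seed = 1) {
  thr <- detection_prefilter(X, prefilter_fraction)
  opts <- list(None = rownames(X), Threshold = thr)
  opts$Bimodal <- tryCatch(
    dip_filter(X, thr, p_cut = dip_p, B = dip_draws, seed = seed),
    error = function(e) character(0))
  opts$HighFano <- tryCatch(fano_filter(X, thr, n_mad = fano_mad),
                            error = function(e) character(0))
  empty <- names(opts)[vapply(opts, length, 0L) == 0]
  if (length(empty) > 0) {
    warning("gene-set option(s) dropped (empty selection): ",
            paste(empty, collapse = ", "), call. = FALSE)
    opts <- opts[vapply(opts, length, 0L) > 0]
  }
  opts
}
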