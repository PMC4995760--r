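#' Simulate zero-inflated single-cell expression with known ground truth
#'
#' Each gene has an expression probability `P_i` (1 for the leading
#' housekeeping block, uniform on \[0, 1\] otherwise), a negative-binomial
#' mean `mu_i` drawn from an exponential with mean 75, and a dispersion
#' `gamma_i` uniform on \[0, 4\] (variance `mu + gamma * mu^2`). Each entry
#' is zero with probability `1 - P_i`, otherwise a negative-binomial draw.
#' Counts are `log(x + 1)` transformed. Per-cell dropout sigmoid parameters
#' are drawn here too (`alpha` uniform on \[2, 6\], `beta` on \[1, 3\]) and
#' applied by [apply_dropout()].
#'
#' @param n_genes,n_cells,n_housekeeping matrix dimensions and the size of
#'   the leading constitutive block (defaults 3000, 2000, 500).
#' @param seed RNG seed.
#' @return list with `X` (log-transformed true matrix) and `truth` (list:
#'   `P`, `mu`, `gamma`, `alpha`, `beta`, `true_zero_mask`,
#'   `housekeeping` ids).
#' @export
simulate_true_expression <- function(n_genes = 3000, n_cells = 2000,
                                     n_housekeeping = 500, seed = 1) {
  if (n_genes < n_housekeeping || n_genes < 1 || n_cells < 1) {
    stop("invalid simulation sizes", call. = FALSE)
  }
  set.seed(seed)
  gene_ids <- c(sprintf("HK%05d", seq_len(n_housekeeping)),
                sprintf("GENE%05d", seq_len(n_genes - n_housekeeping)))
  cell_ids <- sprintf("CELL%05d", seq_len(n_cells))
  P <- c(rep(1, n_housekeeping), stats::runif(n_genes - n_housekeeping))
  mu <- stats::rexp(n_genes, rate = 1 / 75)
  gamma <- stats::runif(n_genes, 0, 4)
  counts <- matrix(0, n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
  for (i in seq_len(n_genes)) {
    expressed <- stats::runif(n_cells) < P[i]
    ne <- sum(expressed)
    if (ne > 0) {
      counts[i, expressed] <- if (gamma[i] > 0) {
        stats::rnbinom(ne, mu = mu[i], size = 1 / gamma[i])
      } else {
        stats::rpois(ne, mu[i])
      }
    }
  }
  alpha <- stats::runif(n_cells, 2, 6)
  beta <- stats::runif(n_cells, 1, 3)
  list(X = log1p(counts),
       truth = list(P = P, mu = mu, gamma = gamma,
                    alpha = stats::setNames(alpha, cell_ids),
                    beta = stats::setNames(beta, cell_ids),
                    true_zero_mask = counts == 0,
                    housekeeping = gene_ids[seq_len(n_housekeeping)]))
}

#' Apply per-cell sigmoidal dropout to a simulated matrix
#'
#' Every non-zero entry of the true matrix is set to zero independently with
#' probability given by the cell's dropout sigmoid evaluated at the gene's
#' mean non-zero log expression.
#'
#' @param X log-transformed true matrix from [simulate_true_expression()].
#' @param truth the matching `truth` list.
#' @param seed RNG seed.
#' @return list with `X` (measured matrix) and `dropout_mask` (logical
#'   matrix of dropped entries; disjoint from `true_zero_mask`).
#' @export
apply_dropout <- function(X, truth, seed = 1) {
  set.seed(seed)
  nz <- X > 0
  mu_det <- rowSums(X) / pmax(rowSums(nz), 1)
  arg <- outer(mu_det, truth$alpha[colnames(X)], function(m, a) a * m) -
    matrix(truth$alpha * truth$beta, nrow(X), ncol(X), byrow = TRUE)
  pdrop <- 1 / (1 + exp(arg))
  drop <- nz & (matrix(stats::runif(length(X)), nrow(X)) < pdrop)
  Xm <- X
  Xm[drop] <- 0
  list(X = Xm, dropout_mask = drop)
}

#' Shuffle expression values within each cell
#'
#' Independently permutes every column, preserving each cell's value multiset
#' (and hence its zero fraction) while destroying gene-level structure. Used
#' as the negative control for consistency analysis.
#'
#' @param X expression matrix (genes x cells).
#' @param seed RNG seed.
#' @return shuffled matrix, same dimnames.
#' @export
shuffle_within_cells <- function(X, seed = 1) {
  set.seed(seed)
  out <- apply(X, 2, sample)
  dimnames(out) <- dimnames(X)
  out
}

#' Weight-recovery experiment on simulated dropouts
#'
#' Runs simulate -> dropout -> scaffold -> curve fits -> weights and
#' compares the mean false-negative weight over true negatives (entries zero
#' in the true matrix) against dropped-out entries. An effective weighting
#' scheme assigns higher weights to the true negatives.
#'
#' @param n_genes,n_cells,n_housekeeping simulation scale (defaults
#'   300 x 200 with 50 housekeeping genes).
#' @param seed RNG seed.
#' @return list with `mean_weight_true_negative`,
#'   `mean_weight_false_negative`, and their difference.
#' @export
weight_recovery_experiment <- function(n_genes = 300, n_cells = 200,
                                       n_housekeeping = 50, seed = 1) {
  sim <- simulate_true_expression(n_genes, n_cells, n_housekeeping, seed = seed)
  meas <- apply_dropout(sim$X, sim$truth, seed = seed + 1)
  scaffold <- build_quantile_scaffold(meas$X, sim$truth$housekeeping)
  curves <- fit_dropout_curves(scaffold)
  W <- compute_false_negative_weights(meas$X, curves)
  tn <- sim$truth$true_zero_mask
  fn <- meas$dropout_mask
  list(mean_weight_true_negative = mean(W[tn]),
       mean_weight_false_negative = mean(W[fn]),
       difference = mean(W[tn]) - mean(W[fn]))
}

#' Simulate structured expression with planted signature modules
#'
#' Builds on [simulate_true_expression()]: cells are split into two
#' populations and `n_modules` disjoint gene modules (drawn from the
#' non-housekeeping genes) are made differentially expressed by scaling
#' their negative-binomial mean by `effect` in the second population.
#' Module genes are always expressed (`P_i = 1`) so the planted signal is
#' not masked by structural zeros. The module gene sets are the planted
#' signatures; dropout can be applied afterwards with [apply_dropout()].
#'
#' @param n_genes,n_cells,n_housekeeping as in [simulate_true_expression()].
#' @param n_modules number of planted modules (default 10).
#' @param module_size genes per module (default 20).
#' @param effect fold change of the module NB mean in population 2.
#' @param seed RNG seed.
#' @return list with `X`, `truth` (as in the base simulator), `modules`
#'   (named list of gene-id vectors) and `groups` (per-cell population
#'   labels 1/2).
#' @export
simulate_structured_expression <- function(n_genes = 300, n_cells = 200,
                                           n_housekeeping = 50,
                                           n_modules = 10, module_size = 20,
                                           effect = 3, seed = 1) {
  sim <- simulate_true_expression(n_genes, n_cells, n_housekeeping, seed = seed)
  gene_ids <- rownames(sim$X)
  cell_ids <- colnames(sim$X)
  free <- setdiff(gene_ids, sim$truth$housekeeping)
  if (length(free) < n_modules * module_size) {
    stop("not enough non-housekeeping genes for the requested modules", call. = FALSE)
  }
  set.seed(derive_seed(seed, "modules"))
  picked <- sample(free, n_modules * module_size)
  modules <- split(picked, rep(seq_len(n_modules), each = module_size))
  names(modules) <- sprintf("MODULE%02d", seq_len(n_modules))
  groups <- stats::setNames(rep(1:2, length.out = n_cells), cell_ids)
  counts <- round(expm1(sim$X))
  for (g in picked) {
    i <- match(g, gene_ids)
    mu1 <- sim$truth$mu[i]
    gam <- max(sim$truth$gamma[i], 1e-8)
    sim$truth$P[i] <- 1
    counts[g, groups == 1] <- stats::rnbinom(sum(groups == 1), mu = mu1,
                                             size = 1 / gam)
    counts[g, groups == 2] <- stats::rnbinom(sum(groups == 2),
                                             mu = mu1 * effect, size = 1 / gam)
  }
  sim$X <- log1p(counts)
  sim$truth$true_zero_mask <- counts == 0
  list(X = sim$X, truth = sim$truth, modules = modules, groups = groups)
}
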