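test_that("weighted covariance reduces to the population covariance at unit weights", {
  set.seed(41)
  X <- toy_matrix(rnorm(40), 4, 10)
  W <- unit_weights(X)
  cv <- weighted_covariance(X, W)
  pop <- cov(t(X)) * (ncol(X) - 1) / ncol(X)
  expect_lt(max(abs(cv - pop)), 1e-10)
  expect_equal(cv, t(cv))
})

test_that("weighted covariance matches the brute-force double loop exactly", {
  set.seed(42)
  X <- toy_matrix(rexp(12), 3, 4)
  W <- toy_matrix(runif(12, 0.2, 1), 3, 4)
  expect_equal(weighted_covariance(X, W), brute_weighted_cov(X, W),
               tolerance = 1e-12)
})

test_that("weighted PCA reduces to standard PCA and sorts eigenvalues", {
  set.seed(43)
  X <- toy_matrix(rnorm(200), 10, 20)
  W <- unit_weights(X)
  wp <- weighted_pca(X, W, k = 3)
  expect_true(all(diff(wp$evals) <= 1e-12))
  ref <- prcomp(t(X))$x[, 1:3]
  for (k in 1:3) { # agreement up to sign, componentwise
    expect_lt(min(max(abs(wp$scores[, k] - ref[, k])),
                  max(abs(wp$scores[, k] + ref[, k]))), 1e-8)
  }
})

test_that("rank-1 structure dominates the weighted-PCA spectrum", {
  set.seed(44)
  u <- rnorm(30)
  v <- rnorm(50)
  X <- outer(u, v) + matrix(rnorm(1500, sd = 0.01), 30, 50)
  dimnames(X) <- list(sprintf("G%02d", 1:30), sprintf("C%02d", 1:50))
  wp <- weighted_pca(X, unit_weights(X), k = 2)
  expect_gt(wp$evals[1], 100 * wp$evals[2])
})

test_that("significant-PC selection floors at 5 on pure noise", {
  set.seed(45)
  X <- toy_matrix(rnorm(200 * 100), 200, 100)
  npc <- count_significant_pcs(X, unit_weights(X), n_perm = 50, seed = 9)
  expect_equal(npc, 5)
})

test_that("significant-PC selection recovers planted factors", {
  hits <- vapply(1:3, function(s) {
    set.seed(100 + s)
    n_f <- 8
    L <- matrix(rnorm(100 * n_f), 100, n_f)
    F <- matrix(rnorm(n_f * 80), n_f, 80)
    X <- L %*% F * 3 + matrix(rnorm(8000), 100, 80)
    dimnames(X) <- list(sprintf("G%03d", 1:100), sprintf("C%02d", 1:80))
    count_significant_pcs(X, unit_weights(X), n_perm = 50, seed = s)
  }, 0)
  expect_true(all(hits >= 8))
  expect_true(all(hits <= 80))
})

test_that("the registry holds 11 methods and they are deterministic", {
  expect_length(projection_registry(), 11)
  set.seed(46)
  data <- matrix(rnorm(40 * 6), 40, 6,
                 dimnames = list(sprintf("C%02d", 1:40), NULL))
  for (m in c("PCA_1_2", "ICA", "MDS", "ISOMAP", "SpectralEmbedding",
              "KernelPCA_RBF", "KernelPCA_linear", "tSNE_10")) {
    a <- run_projection_method(data, m, seed = 7)
    b <- run_projection_method(data, m, seed = 7)
    expect_identical(a, b)
    expect_equal(dim(a), c(40, 2))
  }
})

test_that("neighborhood methods refuse tiny inputs", {
  data <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("c", 1:6), NULL))
  expect_error(run_projection_method(data, "ISOMAP"), ">= 10 cells")
  expect_error(run_projection_method(data, "tSNE_10"), ">= 10 cells")
  expect_error(run_projection_method(data, "NOPE"), "unknown")
})

test_that("coordinate standardization centers and fixes the mean squared radius", {
  set.seed(47)
  raw <- matrix(rnorm(60, sd = 5) + 3, 30, 2)
  co <- standardize_coordinates(raw)
  expect_lt(max(abs(colMeans(co))), 1e-9)
  expect_lt(abs(mean(rowSums(co^2)) - 1), 1e-9)
  # idempotence
  expect_lt(max(abs(standardize_coordinates(co) - co)), 1e-9)
  # hand case
  expect_equal(standardize_coordinates(rbind(c(0, 0), c(2, 0))),
               rbind(c(-1, 0), c(1, 0)))
  expect_error(standardize_coordinates(rbind(c(1, 1), c(1, 1))), "coincide")
})

test_that("the configuration grid is 19 per gene set, 76 for four", {
  cfg4 <- enumerate_configurations(c("None", "Threshold", "Bimodal", "HighFano"))
  expect_equal(nrow(cfg4), 76)
  cfg1 <- enumerate_configurations("None")
  expect_equal(nrow(cfg1), 19)
  # PCA pair methods never run on pre-reduced data
  expect_false(any(cfg4$pca_first & cfg4$method %in%
                     c("PCA_1_2", "PCA_1_3", "PCA_2_3")))
  expect_false(anyDuplicated(cfg4$name) > 0)
})

test_that("run_all_projections standardizes every result and contrasts pca_first", {
  set.seed(48)
  sim <- simulate_structured_expression(n_genes = 80, n_cells = 40,
                                        n_housekeeping = 30, n_modules = 2,
                                        module_size = 10, seed = 6)
  X <- sim$X
  W <- unit_weights(X)
  opts <- list(All = rownames(X))
  res <- run_all_projections(X, W, opts, master_seed = 5, n_perm = 25)
  expect_gt(length(res), 10)
  for (r in res) {
    expect_lt(max(abs(colMeans(r$coords))), 1e-9)
    expect_lt(abs(mean(rowSums(r$coords^2)) - 1), 1e-9)
  }
  # reducing first changes the embedding on noisy data
  expect_gt(max(abs(res[["All__MDS__nopca"]]$coords -
                    res[["All__MDS__pca"]]$coords)), 0.01)
})
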