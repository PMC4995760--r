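test_that("quantile scaffold bins housekeeping genes by detected mean", {
  set.seed(11)
  n_hk <- 60
  n_cells <- 20
  X <- toy_matrix(rexp(n_hk * n_cells) + 0.5, n_hk, n_cells)
  zero_idx <- cbind(sample(n_hk, 40, replace = TRUE), sample(n_cells, 40, replace = TRUE))
  X[zero_idx] <- 0
  sc <- build_quantile_scaffold(X, rownames(X))
  expect_length(sc$mu, 30)
  expect_true(all(diff(sc$mu) >= 0))
  expect_true(all(sc$F >= 0 & sc$F <= 1))

  # brute-force oracle: rank genes by non-zero mean, 2 genes per bin
  mu_gene <- apply(X, 1, function(v) mean(v[v > 0]))
  ord <- order(mu_gene, rownames(X))
  for (q in c(1, 15, 30)) {
    genes_q <- rownames(X)[ord[(2 * q - 1):(2 * q)]]
    expect_equal(sc$mu[q], mean(mu_gene[genes_q]))
    expect_equal(unname(sc$F[3, q]), mean(X[genes_q, 3] == 0))
  }

  # a cell with no zeros has F = 0 everywhere; all zeros gives F = 1
  Xz <- X
  Xz[, 1] <- 1
  Xz[, 2] <- 0
  scz <- build_quantile_scaffold(Xz, rownames(Xz))
  expect_true(all(scz$F[1, ] == 0))
  expect_true(all(scz$F[2, ] == 1))
})

test_that("too few usable housekeeping genes is an instructive error", {
  X <- toy_matrix(1, 10, 5)
  expect_error(build_quantile_scaffold(X, rownames(X)), "housekeeping")
})

test_that("sigmoid fit recovers noiseless parameters and basic properties", {
  mu <- seq(0.5, 5, length.out = 30)
  f <- dropout_sigmoid(mu, alpha = 4, beta = 2)
  sc <- structure(list(mu = mu, F = matrix(f, 1, 30, dimnames = list("c1", NULL))),
                  class = "quantile_scaffold")
  fit <- fit_dropout_curve(sc, "c1")
  expect_lt(abs(fit$alpha - 4), 1e-3)
  expect_lt(abs(fit$beta - 2), 1e-3)
  expect_lt(fit$rss, 1e-8)

  # midpoint and monotonicity of the fitted curve
  expect_equal(dropout_sigmoid(fit$beta, fit$alpha, fit$beta), 0.5)
  grid <- seq(0, 6, length.out = 50)
  expect_true(all(diff(dropout_sigmoid(grid, fit$alpha, fit$beta)) < 0))
})

test_that("sigmoid fit is scale-stable under abundance shifts", {
  mu <- seq(1, 4, length.out = 30)
  f <- dropout_sigmoid(mu, alpha = 3, beta = 2.2) + 0.01 * sin(seq_len(30))
  f <- pmin(pmax(f, 0), 1)
  fit1 <- fit_dropout_curve(structure(list(mu = mu, F = rbind(c1 = f)),
                                      class = "quantile_scaffold"), "c1")
  shift <- 1.7
  fit2 <- fit_dropout_curve(structure(list(mu = mu + shift, F = rbind(c1 = f)),
                                      class = "quantile_scaffold"), "c1")
  expect_lt(abs(fit2$beta - fit1$beta - shift), 1e-6)
  expect_lt(abs(fit2$alpha - fit1$alpha), 1e-6)
})

test_that("false-negative weights follow the posterior formula", {
  # hand case: detection rate 0.5, dropout curve value 0.5 at the gene mean
  # for every cell -> P(expressed | not detected) = 1 -> weight 0
  X <- rbind(G01 = c(2, 2, 0, 0), # mu_detected = 2, detection rate 0.5
             G02 = c(3, 3, 3, 0))
  colnames(X) <- sprintf("C%02d", 1:4)
  # choose curves with F(2) = 0.5 for all cells: alpha any, beta = 2
  curves <- data.frame(alpha = rep(2, 4), beta = rep(2, 4), rss = 0,
                       converged = TRUE, row.names = colnames(X))
  W <- compute_false_negative_weights(X, curves)
  expect_true(all(W[X != 0] == 1))
  expect_equal(unname(W["G01", 3]), 0) # P(E|notD) = (0.5 * 0.5/0.5) / 0.5 = 1
  expect_true(all(W >= 0 & W <= 1))
})

test_that("weight estimates are clipped into [0, 1]", {
  # a configuration where the posterior numerator exceeds its denominator
  X <- rbind(G01 = c(4, 4, 4, 0), G02 = c(1, 1, 1, 1))
  colnames(X) <- sprintf("C%02d", 1:4)
  curves <- data.frame(alpha = rep(0.5, 4), beta = rep(8, 4), rss = 0,
                       converged = TRUE, row.names = colnames(X))
  # F(4) = 1/(1+exp(0.5*(4-8))) ~= 0.88; D = 0.75 -> ratio > 1 before clipping
  W <- compute_false_negative_weights(X, curves)
  expect_true(all(W >= 0 & W <= 1))
  expect_equal(unname(W["G01", 4]), 0) # clipped at the lower weight bound
})

test_that("never-detected genes keep weight 1", {
  X <- rbind(G01 = c(0, 0, 0), G02 = c(1, 2, 3))
  colnames(X) <- sprintf("C%02d", 1:3)
  curves <- data.frame(alpha = rep(2, 3), beta = rep(2, 3), rss = 0,
                       converged = TRUE, row.names = colnames(X))
  W <- compute_false_negative_weights(X, curves)
  expect_true(all(W["G01", ] == 1))
})

test_that("quality scores order cells by dropout burden", {
  mu <- seq(1, 4, length.out = 30)
  sc <- structure(list(mu = mu, F = matrix(0, 3, 30)), class = "quantile_scaffold")
  curves <- data.frame(alpha = c(3, 3, 50), beta = c(2.8, 2, 0.2), rss = 0,
                       converged = TRUE,
                       row.names = c("worse", "better", "near_perfect"))
  q <- compute_quality_scores(curves, sc)
  # identical parameters give identical scores
  curves2 <- curves[c(1, 1), ]
  expect_equal(compute_quality_scores(curves2, sc)[[1]],
               compute_quality_scores(curves2, sc)[[2]])
  # the beta = 2.8 dropout curve lies above the beta = 2 curve everywhere
  # (more dropout at every abundance), so its quality score is lower
  expect_gt(q[["better"]], q[["worse"]])
  # steep curve far below the range: area ~ 0, the best possible
  expect_gt(q[["near_perfect"]], -1e-3)
  expect_lte(q[["near_perfect"]], 0)
})

test_that("QC filter removes cells 1.6 raw MADs below the median", {
  same <- setNames(rep(5, 5), paste0("c", 1:5))
  expect_equal(qc_filter_cells(same), names(same)) # MAD 0, strict inequality
  scores <- setNames(c(10, 10, 10, 10, 0), paste0("c", 1:5))
  expect_setequal(qc_filter_cells(scores), paste0("c", 1:4))
  # multiplier is configurable
  spread <- setNames(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9), paste0("c", 1:10))
  expect_lt(length(qc_filter_cells(spread, n_mad = 0.5)),
            length(qc_filter_cells(spread, n_mad = 10)))
  expect_error(qc_filter_cells(setNames(1:2, c("a", "b"))), ">= 3")
})
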