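test_that("z-normalization standardizes genes and zeroes constant rows", {
  set.seed(51)
  X <- toy_matrix(rexp(20), 5, 4)
  Xp <- znormalize_genes(X)
  expect_lt(max(abs(rowMeans(Xp))), 1e-9)
  expect_lt(max(abs(apply(Xp, 1, sd) - 1)), 1e-9)
  # brute-force oracle on the same toy
  for (i in 1:5) {
    expect_equal(unname(Xp[i, ]), unname((X[i, ] - mean(X[i, ])) / sd(X[i, ])))
  }
  Xc <- X
  Xc[2, ] <- 7
  expect_warning(Xpc <- znormalize_genes(Xc), "zero-variance")
  expect_true(all(Xpc[2, ] == 0))
})

test_that("signature scores follow the weighted signed average", {
  set.seed(52)
  X <- toy_matrix(rexp(12), 3, 4)
  Xp <- znormalize_genes(X)
  W <- unit_weights(X)

  # single-gene undirected signature at unit weights is that gene's z-score
  s1 <- score_signature(Xp, W, sig_of("S1", "G01"))
  expect_equal(unname(s1$scores), unname(Xp["G01", ]))

  # identical rows with opposite signs cancel
  Xc <- rbind(X, G04 = X[1, ])
  Wc <- unit_weights(Xc)
  Xpc <- znormalize_genes(Xc)
  s2 <- score_signature(Xpc, Wc, sig_of("S2", c("G01", "G04"), c(1, -1)))
  expect_lt(max(abs(s2$scores)), 1e-12)

  # mixed weights match the brute-force evaluation
  Wm <- toy_matrix(runif(12, 0.1, 1), 3, 4)
  signs <- c(G01 = 1, G02 = -1, G03 = 1)
  s3 <- score_signature(Xp, Wm, make_signature("S3", signs, directed = TRUE))
  expect_equal(unname(s3$scores), brute_signature_score(Xp, Wm, signs),
               tolerance = 1e-12)
  expect_equal(sort(unname(s3$ranks)), 1:4)

  expect_warning(s4 <- score_signature(Xp, W, sig_of("S4", "ABSENT")), "skipped")
  expect_null(s4)
})

test_that("consistency score matches hand arithmetic and the brute force", {
  # two cells: each is predicted by the other, error 1, consistency 0.5
  co <- rbind(c(0, 0), c(1, 0))
  r <- consistency_score(c(1, 2), co)
  expect_equal(r$predicted, c(2, 1))
  expect_identical(r$consistency, 0.5)

  # constant ranks predict themselves exactly
  co5 <- matrix(rnorm(10), 5, 2)
  expect_equal(consistency_score(rep(3, 5), co5)$consistency, 1)

  # 5-cell toy against the double loop
  set.seed(53)
  ranks <- rank(rnorm(5))
  cons <- consistency_score(ranks, co5, alpha = 0.33)
  oracle <- brute_consistency(ranks, co5, alpha = 0.33)
  expect_equal(cons$predicted, oracle$predicted, tolerance = 1e-12)
  expect_equal(cons$consistency, oracle$consistency, tolerance = 1e-12)
  expect_error(consistency_score(1, rbind(c(0, 0))), ">= 2")
})

test_that("random background is deterministic and populates size bins", {
  set.seed(54)
  X <- toy_matrix(rexp(300 * 30), 300, 30)
  Xp <- suppressWarnings(znormalize_genes(X))
  W <- unit_weights(X)
  co <- standardize_coordinates(matrix(rnorm(60), 30, 2))
  projs <- list(p1 = list(config = data.frame(name = "p1"), coords = co))
  bg1 <- build_random_background(Xp, W, projs, n_draws = 25, seed = 8)
  bg2 <- build_random_background(Xp, W, projs, n_draws = 25, seed = 8)
  expect_identical(bg1, bg2)
  expect_equal(bg1$p1$size, c(10, 20, 50, 100, 200))
  expect_true(all(bg1$p1$sd >= 0))
  # structureless coordinates: background means stable across bins
  spread <- max(bg1$p1$mean) - min(bg1$p1$mean)
  expect_lt(spread, 3 * max(bg1$p1$sd))
  # pool smaller than a bin: bin skipped with warning
  expect_warning(bg3 <- build_random_background(Xp[1:60, ], W[1:60, ], projs,
                                                pool = rownames(Xp)[1:60],
                                                n_draws = 10, seed = 8),
                 "skipped")
  expect_equal(bg3$p1$size, c(10, 20, 50))
})

test_that("Z-test significance and BH correction behave canonically", {
  bg <- structure(list(p1 = data.frame(size = c(10, 20), mean = c(0.5, 0.5),
                                       sd = c(0.1, 0.1), n_draws = 100)),
                  class = "background_model")
  cons <- matrix(c(0.5, 1.0), 2, 1, dimnames = list(c("at_mean", "high"), "p1"))
  st <- significance_test(cons, c(10, 10), bg)
  expect_equal(st$p["at_mean", "p1"], 0.5)
  expect_lt(st$p["high", "p1"], 3e-7) # 5 sd above the mean
  expect_true(all(st$q >= st$p - 1e-15))

  # BH oracle
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.05), method = "BH"),
               c(0.04, 0.04, 0.05, 0.05))

  bg0 <- structure(list(p1 = data.frame(size = 10, mean = 0.5, sd = 0,
                                        n_draws = 100)),
                   class = "background_model")
  w <- capture_warnings(st0 <- significance_test(cons, c(10, 10), bg0))
  expect_true(all(grepl("zero", w)))
  expect_true(all(st0$p == 1))
})

test_that("background bin choice is nearest size with ties to the smaller", {
  bg <- structure(list(p1 = data.frame(size = c(10, 20, 50),
                                       mean = c(0.1, 0.5, 0.9),
                                       sd = c(0.1, 0.1, 0.1), n_draws = 10)),
                  class = "background_model")
  cons <- matrix(0.5, 1, 1, dimnames = list("s", "p1"))
  # 15 genes ties between 10 and 20 -> smaller bin (mean 0.1) -> small p
  p_tie <- significance_test(cons, 15, bg)$p[1, 1]
  expect_lt(p_tie, 0.01)
  # 19 genes -> bin 20 (mean 0.5) -> p = 0.5
  p_20 <- significance_test(cons, 19, bg)$p[1, 1]
  expect_equal(p_20, 0.5)
})

test_that("numeric pre-computed significance detects coordinate concordance", {
  set.seed(55)
  n <- 40
  co <- standardize_coordinates(cbind(seq_len(n), rnorm(n, sd = 0.05)))
  values <- seq_len(n) + rnorm(n, sd = 0.1) # concordant with x
  r <- numeric_precomputed_significance(values, co, n_shuffles = 300, seed = 5)
  expect_gt(r$consistency, 0.85)
  expect_lt(r$p, 0.05)
  expect_equal(numeric_precomputed_significance(rep(2, n), co)$p, 1)
})

test_that("numeric pre-computed null calibration stays near nominal", {
  set.seed(56)
  n <- 30
  co <- standardize_coordinates(matrix(rnorm(2 * n), n, 2))
  rej <- sum(vapply(1:60, function(i) {
    v <- rnorm(n)
    numeric_precomputed_significance(v, co, n_shuffles = 150, seed = i)$p < 0.05
  }, TRUE))
  expect_lte(rej / 60, 0.10)
})

test_that("categorical consistency matches the brute force and separates blobs", {
  co4 <- rbind(c(0, 0), c(0.1, 0), c(3, 3), c(3.1, 3))
  labs <- c("a", "a", "b", "b")
  r <- categorical_consistency(labs, co4, n_shuffles = 50, seed = 2)
  expect_equal(r$consistency, brute_categorical(labs, co4), tolerance = 1e-12)
  expect_gt(r$consistency, 0.95)
  expect_equal(categorical_consistency(rep("x", 4), co4)$consistency, 1)

  set.seed(57)
  blob <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                matrix(rnorm(40, 4, 0.1), 20, 2))
  blab <- rep(c("L", "R"), each = 20)
  rb <- categorical_consistency(blab, standardize_coordinates(blob),
                                n_shuffles = 100, seed = 3)
  expect_gt(rb$consistency, 0.95)
  expect_lt(rb$p, 0.05)
})
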