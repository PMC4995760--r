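# small deterministic fixtures shared across test files

# a tiny log-scale matrix with dimnames
toy_matrix <- function(values, n_genes, n_cells) {
  matrix(values, n_genes, n_cells,
         dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                         sprintf("C%02d", seq_len(n_cells))))
}

unit_weights <- function(X) {
  W <- X
  W[] <- 1
  W
}

# write a tab-delimited expression file and return its path
write_expr_file <- function(m, path = tempfile(fileext = ".txt")) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_lines_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

sig_of <- function(name, ids, signs = rep(1, length(ids)), directed = any(signs < 0)) {
  make_signature(name, stats::setNames(signs, ids), directed = directed)
}

# brute-force weighted covariance (double loop), the independent oracle
brute_weighted_cov <- function(X, w) {
  g <- nrow(X)
  out <- matrix(0, g, g, dimnames = list(rownames(X), rownames(X)))
  for (a in seq_len(g)) {
    xa_bar <- sum(X[a, ] * w[a, ]) / sum(w[a, ])
    for (b in seq_len(g)) {
      xb_bar <- sum(X[b, ] * w[b, ]) / sum(w[b, ])
      num <- den <- 0
      for (j in seq_len(ncol(X))) {
        num <- num + (X[a, j] - xa_bar) * (X[b, j] - xb_bar) * w[a, j] * w[b, j]
        den <- den + w[a, j] * w[b, j]
      }
      out[a, b] <- num / den
    }
  }
  out
}

# brute-force signature score (explicit sums)
brute_signature_score <- function(Xp, w, signs) {
  ids <- names(signs)
  vapply(seq_len(ncol(Xp)), function(j) {
    num <- den <- 0
    for (i in ids) {
      num <- num + signs[[i]] * Xp[i, j] * w[i, j]
      den <- den + w[i, j]
    }
    num / den
  }, 0)
}

# brute-force consistency (explicit double loop over cells)
brute_consistency <- function(ranks, coords, alpha = 0.33) {
  n <- length(ranks)
  rhat <- numeric(n)
  for (j in seq_len(n)) {
    num <- den <- 0
    for (k in seq_len(n)) {
      if (k == j) next
      d2 <- sum((coords[j, ] - coords[k, ])^2)
      wgt <- exp(-d2 / alpha^2)
      num <- num + ranks[k] * wgt
      den <- den + wgt
    }
    rhat[j] <- num / den
  }
  list(predicted = rhat, consistency = 1 - median(abs(rhat - ranks)) / n)
}

# brute-force categorical neighborhood consistency
brute_categorical <- function(labels, coords, alpha = 0.33) {
  n <- length(labels)
  lhat <- numeric(n)
  for (j in seq_len(n)) {
    num <- den <- 0
    for (k in seq_len(n)) {
      if (k == j) next
      d2 <- sum((coords[j, ] - coords[k, ])^2)
      wgt <- exp(-d2 / alpha^2)
      num <- num + (labels[k] == labels[j]) * wgt
      den <- den + wgt
    }
    lhat[j] <- num / den
  }
  median(lhat)
}
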