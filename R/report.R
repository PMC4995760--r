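#' Write a self-contained static HTML report
#'
#' One page, no external assets: the signature x projection consistency
#' table with q-value shading, a scatter plot (inline SVG) of the most
#' significant signature-projection pair colored by signature score, and a
#' cluster mean-expression table for that projection.
#'
#' @param results a results bundle from [run_pipeline()].
#' @param path output file path.
#' @return invisible `path`.
#' @export
write_report <- function(results, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>projsig report</title><style>",
            "body{font-family:sans-serif;margin:2em;} table{border-collapse:collapse;}",
            "td,th{border:1px solid #ccc;padding:2px 6px;font-size:12px;}",
            ".sig{background:#fdd;} h2{margin-top:1.5em;}",
            "</style></head><body>",
            "<h1>Signature-projection consistency report</h1>",
            sprintf("<p>%d projections, %d signature rows; FDR threshold %.3g.</p>",
                    length(results$projections), nrow(results$consistency),
                    results$config$fdr))

  q <- results$q_values
  cons <- results$consistency
  if (!is.null(cons) && nrow(cons) > 0) {
    html <- c(html, "<h2>Consistency (shaded: q &lt; FDR)</h2>", "<table><tr><th></th>",
              paste0("<th>", esc(colnames(cons)), "</th>", collapse = ""), "</tr>")
    for (i in seq_len(nrow(cons))) {
      cells <- vapply(seq_len(ncol(cons)), function(j) {
        cls <- if (!is.na(q[i, j]) && q[i, j] < results$config$fdr) " class='sig'" else ""
        sprintf("<td%s>%.3f (q=%.2g)</td>", cls, cons[i, j], q[i, j])
      }, "")
      html <- c(html, paste0("<tr><th>", esc(rownames(cons)[i]), "</th>",
                             paste0(cells, collapse = ""), "</tr>"))
    }
    html <- c(html, "</table>")

    # scatter of the best pair
    best <- arrayInd(which.min(q), dim(q))
    bsig <- rownames(q)[best[1]]
    bproj <- colnames(q)[best[2]]
    co <- results$projections[[bproj]]$coords
    sc <- results$signature_scores
    if (bsig %in% rownames(sc)) {
      v <- sc[bsig, rownames(co)]
      col <- grDevices::rgb(grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))(
        (rank(v) - 1) / max(1, length(v) - 1)) / 255)
      lim <- max(abs(co)) * 1.05
      pts <- sprintf("<circle cx='%.1f' cy='%.1f' r='3' fill='%s'/>",
                     200 + 190 * co[, 1] / lim, 200 - 190 * co[, 2] / lim, col)
      html <- c(html,
                sprintf("<h2>%s on %s</h2>", esc(bsig), esc(bproj)),
                "<svg width='400' height='400' style='border:1px solid #999'>",
                pts, "</svg>",
                "<p>Color: signature score rank (blue low, red high).</p>")
    }

    cl <- results$clusters[[bproj]]
    sig_obj <- NULL
    for (s in results$signatures) if (s$name == bsig) sig_obj <- s
    if (!is.null(cl) && !is.null(sig_obj)) {
      k0 <- min(cl$k)
      lab <- stats::setNames(cl$label[cl$k == k0], cl$cell_id[cl$k == k0])
      Xp <- znormalize_genes(results$expression)
      summ <- cluster_expression_summary(Xp, sig_obj, lab)
      show <- summ[, seq_len(min(12, ncol(summ))), drop = FALSE]
      html <- c(html, sprintf("<h2>Cluster mean z-scores (k=%d, %s)</h2>", k0,
                              esc(bproj)),
                "<table><tr><th></th>",
                paste0("<th>", esc(colnames(show)), "</th>", collapse = ""), "</tr>")
      for (i in seq_len(nrow(show))) {
        html <- c(html, paste0("<tr><th>", esc(rownames(show)[i]), "</th>",
                               paste0(sprintf("<td>%.2f</td>", show[i, ]),
                                      collapse = ""), "</tr>"))
      }
      html <- c(html, "</table>")
    }
  }
  html <- c(html, "<h2>Projections computed</h2><ul>",
            paste0("<li>", esc(names(results$projections)), "</li>"),
            "</ul></body></html>")
  writeLines(html, path)
  invisible(path)
}
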