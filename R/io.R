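#' Read a tab-delimited expression matrix
#'
#' Expects genes in rows and cells in columns: the first row holds cell ids,
#' the first column gene ids, and the body is numeric and non-negative.
#' Gene ids are upper-cased so that signature and housekeeping lookups are
#' case-insensitive. Duplicate gene rows are collapsed by the entry-wise
#' maximum. Missing values are rejected: the downstream model reasons about
#' zeros, not NAs.
#'
#' @param path path to the tab-delimited file.
#' @param already_logged if `FALSE` (default) every entry is transformed with
#'   `log(x + 1)`; set `TRUE` when the input is already on a log scale.
#' @return numeric matrix (genes x cells) with gene/cell dimnames.
#' @export
read_expression_matrix <- function(path, already_logged = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2) stop("expression matrix needs a header row and at least one gene row", call. = FALSE)
  # header may or may not carry a label for the gene-id column
  body_nf <- nf[-1]
  if (length(unique(body_nf)) != 1) {
    bad <- which(body_nf != body_nf[1])[1] + 1
    stop("ragged expression matrix: line ", bad, " has ", body_nf[bad - 1],
         " fields, expected ", body_nf[1], call. = FALSE)
  }
  if (!nf[1] %in% c(body_nf[1], body_nf[1] - 1)) {
    stop("ragged expression matrix: header line has ", nf[1],
         " fields, body lines have ", body_nf[1], call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) == body_nf[1]) header <- header[-1] # corner label present
  df <- utils::read.delim(path, header = FALSE, skip = 1, check.names = FALSE,
                          quote = "", comment.char = "")
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  colnames(df) <- header
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1]
    stop("non-numeric values in expression matrix (column '",
         colnames(df)[bad], "')", call. = FALSE)
  }
  m <- as.matrix(df)
  if (anyNA(m)) stop("expression matrix contains missing values; zeros, not NAs, are modeled", call. = FALSE)
  if (any(m < 0)) stop("expression matrix contains negative values", call. = FALSE)
  rownames(m) <- toupper(ids)
  if (anyDuplicated(rownames(m))) {
    ids <- rownames(m)
    keep <- !duplicated(ids)
    out <- m[keep, , drop = FALSE]
    for (id in unique(ids[duplicated(ids)])) {
      out[id, ] <- apply(m[ids == id, , drop = FALSE], 2, max)
    }
    m <- out
  }
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids in header", call. = FALSE)
  if (!already_logged) m <- log1p(m)
  check_expression_matrix(m)
  m
}

#' Create a gene signature object
#'
#' @param name signature name.
#' @param genes named numeric vector of signs (+1 / -1), names are gene ids.
#' @param directed whether the signature distinguishes up- and down-regulated
#'   genes. Undirected signatures must have all signs +1.
#' @return an object of class `signature`.
#' @export
make_signature <- function(name, genes, directed = FALSE) {
  stopifnot(length(genes) >= 1, !is.null(names(genes)))
  if (!all(genes %in% c(-1, 1))) stop("signs must be +1 or -1", call. = FALSE)
  if (!directed && any(genes == -1)) stop("undirected signature with -1 signs", call. = FALSE)
  names(genes) <- toupper(names(genes))
  structure(list(name = name, genes = genes, directed = directed),
            class = "signature")
}

#' Read gene signatures from a GMT file
#'
#' Each line is `name <tab> description <tab> gene1 <tab> gene2 ...`. Sets
#' whose names share a stem and end in `_UP` and `_DN` (or `_DOWN`) are merged
#' into one directed signature named by the stem, with +1 for the UP members
#' and -1 for the DN members; a gene listed on both sides keeps the UP sign
#' (with a warning). All other sets become undirected signatures.
#'
#' @param path path to the GMT file.
#' @return list of `signature` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  raw <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3) {
      stop("GMT parse error at line ", i, ": need name, description and >= 1 gene",
           call. = FALSE)
    }
    raw[[toupper(f[1])]] <- toupper(unique(f[-(1:2)]))
  }
  nm <- names(raw)
  stem <- sub("(_UP|_DN|_DOWN)$", "", nm)
  side <- rep("plain", length(nm))
  side[grepl("_UP$", nm)] <- "up"
  side[grepl("(_DN|_DOWN)$", nm)] <- "dn"
  out <- list()
  for (s in unique(stem)) {
    idx <- which(stem == s)
    has_up <- any(side[idx] == "up")
    has_dn <- any(side[idx] == "dn")
    if (has_up && has_dn) {
      up <- unique(unlist(raw[idx[side[idx] == "up"]]))
      dn <- unique(unlist(raw[idx[side[idx] == "dn"]]))
      both <- intersect(up, dn)
      if (length(both) > 0) {
        warning("signature '", s, "': gene(s) ", paste(both, collapse = ","),
                " listed in both _UP and _DN; keeping the _UP sign", call. = FALSE)
        dn <- setdiff(dn, both)
      }
      signs <- c(stats::setNames(rep(1, length(up)), up),
                 stats::setNames(rep(-1, length(dn)), dn))
      out[[s]] <- make_signature(s, signs, directed = TRUE)
      # any sideless set sharing the stem stays separate
      idx <- idx[side[idx] == "plain"]
    }
    for (j in idx) {
      if (side[j] %in% c("up", "dn") && has_up && has_dn) next
      g <- raw[[j]]
      out[[nm[j]]] <- make_signature(nm[j], stats::setNames(rep(1, length(g)), g),
                                     directed = FALSE)
    }
  }
  unname(out)
}

#' Read a plain-text gene list (one id per line)
#'
#' Identifiers are upper-cased and de-duplicated; blank lines are ignored.
#'
#' @param path path to the file.
#' @return character vector of unique, upper-cased gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- unique(toupper(x[nzchar(x)]))
  if (length(x) == 0) stop("gene list is empty: ", path, call. = FALSE)
  x
}

#' Read pre-computed signatures (cells x columns table)
#'
#' Tab-delimited, first column cell ids, one column per signature. A column
#' is numeric when every non-missing entry parses as a number, otherwise
#' categorical. All-missing columns are dropped with a warning.
#'
#' @param path path to the file.
#' @param cell_ids optional character vector of expression-matrix cell ids;
#'   unmatched table ids trigger a warning.
#' @return list of `precomputed_signature` objects, each with fields `name`,
#'   `kind` ("numeric" or "categorical") and `values` (named vector).
#' @export
read_precomputed <- function(path, cell_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2) stop("pre-computed table needs cell ids plus >= 1 column", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate cell ids in pre-computed table", call. = FALSE)
  if (!is.null(cell_ids)) {
    unmatched <- setdiff(ids, cell_ids)
    if (length(unmatched) > 0) {
      warning("pre-computed table ids not in expression matrix: ",
              paste(utils::head(unmatched, 5), collapse = ","),
              if (length(unmatched) > 5) " ..." else "", call. = FALSE)
    }
  }
  out <- list()
  for (col in colnames(df)[-1]) {
    v <- df[[col]]
    miss <- is.na(v) | !nzchar(trimws(v))
    if (all(miss)) {
      warning("pre-computed column '", col, "' is all-missing; dropped", call. = FALSE)
      next
    }
    num <- suppressWarnings(as.numeric(v[!miss]))
    if (!anyNA(num)) {
      values <- stats::setNames(num, ids[!miss])
      kind <- "numeric"
    } else {
      values <- stats::setNames(as.character(v[!miss]), ids[!miss])
      kind <- "categorical"
    }
    out[[col]] <- structure(list(name = col, kind = kind, values = values),
                            class = "precomputed_signature")
  }
  unname(out)
}

# internal: write a numeric matrix as a TSV with row-name first column
write_tsv_matrix <- function(m, path, row_label = "id") {
  df <- data.frame(row = rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- row_label
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the full results bundle to a directory
#'
#' Writes `SignatureScores.txt` (signatures x cells), one coordinates TSV per
#' projection configuration (`cell_id`, `x`, `y`), `ConsistencyMatrix.txt`,
#' `PValues.txt`, `QValues.txt` (signatures x projections), `Weights.txt`,
#' per-option gene lists, cluster assignments, a JSON run summary and a
#' self-contained HTML report. TSV round-trips are exact to at least six
#' decimal places.
#'
#' @param results a results bundle as returned by [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @param report write the static HTML report (default `TRUE`).
#' @return invisible character vector of files written (the manifest).
#' @export
write_outputs <- function(results, out_dir, report = TRUE) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  manifest <- character(0)
  put <- function(fname) {
    p <- file.path(out_dir, fname)
    manifest <<- c(manifest, p)
    p
  }
  if (!is.null(results$signature_scores) && nrow(results$signature_scores) > 0) {
    write_tsv_matrix(results$signature_scores, put("SignatureScores.txt"), "signature")
  } else {
    writeLines("signature", put("SignatureScores.txt"))
  }
  for (nm in c("consistency", "p_values", "q_values")) {
    fname <- c(consistency = "ConsistencyMatrix.txt", p_values = "PValues.txt",
               q_values = "QValues.txt")[[nm]]
    m <- results[[nm]]
    if (!is.null(m) && nrow(m) > 0) {
      write_tsv_matrix(m, put(fname), "signature")
    } else {
      cols <- if (!is.null(m)) colnames(m) else character(0)
      writeLines(paste(c("signature", cols), collapse = "\t"), put(fname))
    }
  }
  if (!is.null(results$weights)) {
    write_tsv_matrix(results$weights, put("Weights.txt"), "gene")
  }
  for (proj in results$projections) {
    co <- proj$coords
    df <- data.frame(cell_id = rownames(co), x = co[, 1], y = co[, 2])
    utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                       put(paste0(proj$config$name, ".coords.txt")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (opt_name in names(results$gene_sets)) {
    writeLines(results$gene_sets[[opt_name]],
               put(paste0(opt_name, ".genes.txt")))
  }
  for (cl_name in names(results$clusters)) {
    df <- results$clusters[[cl_name]]
    utils::write.table(df, put(paste0("Clusters_", cl_name, ".txt")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    package = "projsig",
    version = as.character(utils::packageVersion("projsig")),
    r_version = R.version.string,
    config = results$config,
    n_genes = if (!is.null(results$weights)) nrow(results$weights) else NA,
    n_cells = if (!is.null(results$weights)) ncol(results$weights) else NA,
    n_projections = length(results$projections),
    gene_set_sizes = lapply(results$gene_sets, length)
  )
  jsonlite::write_json(summary, put("run_summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (report) {
    write_report(results, put("report.html"))
  }
  invisible(manifest)
}
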