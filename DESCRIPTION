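Package: projsig
Title: Dropout-Aware Signature Scoring and Projection Evaluation for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyzes a single-cell gene expression matrix by estimating
    per-cell false-negative (dropout) curves from housekeeping genes,
    converting them into per-entry weights, scoring gene signatures with a
    weighted average of standardized expression, computing a grid of
    two-dimensional projections (weighted PCA, ICA, t-SNE, ISOMAP, MDS,
    spectral embedding, kernel PCA), and ranking signature-projection pairs
    by a neighborhood consistency statistic whose significance is assessed
    against random-signature backgrounds with a Z-test and
    Benjamini-Hochberg correction. Includes a zero-inflated
    negative-binomial simulator with known dropout ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    kernlab,
    vegan,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
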