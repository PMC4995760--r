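---
title: "Methods: dropout weighting, projection grids and signature consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dropout weighting, projection grids and signature consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Single-cell RNA-seq measurements are zero-inflated: a transcript present in a
cell is often recorded as zero because of limited capture and sequencing
efficiency (a *dropout* or false negative). Two-dimensional embeddings of such
data are popular but treacherous — different projection methods emphasize
different structure, and without care the dominant "structure" is simply each
cell's zero fraction. `projsig` addresses both issues: it models dropouts
explicitly, scores biological gene signatures in a dropout-aware way, computes
a large grid of projections, and ranks signature–projection pairs by how well
each projection's neighborhoods predict each signature's per-cell scores.

# The false-negative model

Housekeeping genes are assumed constitutively expressed, so their zeros are
technical. For each housekeeping gene we estimate abundance as the mean of its
*non-zero* log expression, rank genes by that mean and split them into 30
equal-count quantile bins; `mu[q]` is the mean of gene means in bin `q` and
`F[j, q]` the fraction of bin-`q` genes undetected in cell `j`. Each cell gets
a two-parameter logistic dropout curve

    Fhat_j(x) = 1 / (1 + exp(alpha_j * (x - beta_j)))

fitted by least squares to the 30 points `(mu[q], F[j, q])`. `beta_j` is the
abundance at which the cell misses half of expressed transcripts; `alpha_j`
controls how sharply detection improves with abundance. The fit uses
multi-start L-BFGS-B (`alpha0` in {0.5, 1, 4}, `beta0 = median(mu)`,
`alpha` bounded to (0, 100]); when no start converges the best candidate is
kept and flagged. The fit is shift-stable: translating the abundance scale
translates `beta` and leaves `alpha` unchanged.

For a zero entry the posterior probability that gene `i` was expressed in cell
`j` but missed combines the cell's curve evaluated at the gene's detected mean
with a detection prior equal to the gene's detection rate; for robustness the
per-cell detection probability is replaced by its population mean over cells.
The estimate is clipped to [0, 1] and complemented, so the entry's *weight* is
the probability it is a true negative. Non-zero entries have weight 1. Genes
never detected anywhere also get weight 1: there is no information to call a
dropout, and the detection pre-filter removes them from analysis anyway.

The area under a cell's dropout curve over the scaffold's abundance range
summarizes its dropout burden; the quality score is the negated,
numerically integrated area (via `stats::integrate`), so higher is better and
0 is perfect. An optional QC filter (off by default) removes cells scoring
more than 1.6 raw median-absolute-deviation units below the median quality.
We use the raw MAD, without the 1.4826 normal-consistency factor, in both the
QC rule and the Fano filter: the thresholds are stated in plain MAD units.

# Gene filtering

Four nested gene-set options parameterize the projections:

* **None** — all input genes.
* **Threshold** — genes detected in at least `ceiling(0.20 * N)` cells
  (fraction configurable).
* **Bimodal** — Threshold genes with Hartigan dip-test p < 0.05. The dip
  statistic is computed by the greatest-convex-minorant /
  least-concave-majorant narrowing algorithm; our implementation is validated
  in the test suite against reference values obtained from an exact
  linear-programming formulation of the dip's definition (the sup-norm
  distance to the nearest unimodal cdf). p-values come from `B = 1000` seeded
  Monte-Carlo draws of same-size uniform samples — the uniform being the
  least favorable unimodal null — and one null table is shared by all genes
  with the same cell count. Note the dip is affine-invariant but *not*
  rank-based: monotone transforms of expression change it.
* **HighFano** — Threshold genes whose Fano factor (variance/mean, computed on
  the log-scale matrix as analyzed) exceeds its 30-quantile stratum median by
  more than 2 raw MADs. Below 150 genes the stratum count shrinks to
  `min(30, floor(genes/5))` so strata keep at least ~5 genes.

# The projection grid

The registry holds 11 methods: three weighted-PCA component pairs (1–2, 1–3,
2–3), ICA, t-SNE at perplexities 10 and 30, ISOMAP (4 nearest neighbors),
classical MDS, spectral embedding on a `floor(N/10)`-nearest-neighbor graph,
and kernel PCA with an RBF kernel (coefficient `1/#features`) and with a
linear kernel. The linear-kernel PCA is our choice of eleventh method: the
other ten are forced by the grid arithmetic, and a linear-kernel PCA is the
most benign extension because it coincides with PCA up to scaling while
exercising the same kernel code path as the RBF variant.

Weighted PCA uses the weighted covariance matrix, in which each cross-product
is damped by the product of the two entries' weights and means are
weight-weighted; with unit weights it reduces to the population covariance.
Component signs are fixed so each component's largest-magnitude loading is
positive. The number of components carried into non-linear methods is chosen
by a permutation test: each gene's values (jointly with its weights) are
permuted across cells 100 times, and component `r` is retained while its
eigenvalue exceeds the 95th percentile of permuted rank-`r` eigenvalues, with
a floor of 5 components. Per gene set, all 11 methods run on the non-reduced
matrix and the 8 non-PCA-pair methods additionally run on the PCA-reduced
matrix: 19 configurations per gene set, 76 for the default four.

Every projection is standardized — columns centered, then both scaled by one
common factor so the mean of `x^2 + y^2` over cells is exactly 1 — which makes
the neighborhood kernel below comparable across projections. Each
configuration draws its RNG seed deterministically from the master seed and
its own name, so results are reproducible regardless of execution order, and
a failing method skips its configuration without aborting the run.

# Signature scoring and consistency

Expression is z-normalized per gene (zero-variance genes become zero rows).
A signature score is the weighted, signed average of its genes' z-scores with
the false-negative weights; undirected signatures use sign +1 throughout.
Scores are rank-transformed (average ranks on ties). For a projection `p`,
each cell's rank is predicted from the other cells with a Gaussian kernel of
width `alpha = 0.33` on the standardized coordinates, and

    consistency = 1 - median(|predicted - observed|) / N.

We use the decaying (negative-exponent) kernel in both the rank and the
categorical form: a kernel *growing* with distance would invert the meaning
of a neighborhood. With two cells each is predicted by the other, giving
consistency exactly 0.5 — a useful anchor for the scale.

Significance comes from random-signature backgrounds: for each size bin (10,
20, 50, 100, 200 genes) we draw 1000 gene sets uniformly from the analyzed
pool with independent ±1 signs, score them, and record the mean and standard
deviation of their consistency per projection. One shared background serves
signed and unsigned queries. An observed pair is tested one-sided
(upper tail) against the bin nearest its present-gene count (ties to the
smaller bin), and Benjamini–Hochberg correction is applied across the full
signature-by-projection grid. A signature is flagged when any projection
reaches q < 0.05.

Pre-computed per-cell values are handled analogously: numeric columns are
rank-transformed and tested against a null of 1000 within-dataset shuffles;
categorical columns use the neighborhood label-agreement statistic (median
over cells of the kernel-weighted fraction of same-label neighbors) with the
same shuffle null. The pipeline always injects two numeric pre-computed
signatures — the cell quality score and the per-cell zero fraction — so the
association of every projection with data quality is reported next to the
biology; their shuffle-test p-values enter the same BH grid, a deliberate
choice to keep one coherent error rate over everything the report shows.

# The simulator

The generator emulates zero-inflated counts: gene `i` is expressed in a cell
with probability `P_i` (1 for the leading housekeeping block, else uniform on
[0, 1]); expressed entries draw from a negative binomial with mean `mu_i`
(exponential, mean 75) and dispersion `gamma_i` (uniform on [0, 4]; variance
`mu + gamma * mu^2`); counts are `log(x+1)`-transformed without
renormalization. Dropout then zeroes each non-zero entry with probability
given by the cell's sigmoid (`alpha` uniform on [2, 6], `beta` on [1, 3])
evaluated at the gene's non-zero mean on the log scale — the same scale the
estimator bins genes on, so simulator and estimator agree about what
"abundance" means. The default scale is 3000 genes by 2000 cells with 500
housekeeping genes; tests run the same generative law at 300 x 200 with 50
housekeeping genes, and the structured variant plants differentially
expressed gene modules across two cell populations to provide ground-truth
signatures.

What the simulator does *not* emulate: library-size variation, batch effects,
doublets, gene–gene correlation beyond the planted modules, and mean-variance
trends estimated from any particular protocol. Passing tests therefore show
that the estimators recover the model they assume and that the statistics are
calibrated under it — not that the model captures every real dataset.

# Numerical choices and edge cases

* Quantile binning is by rank with ties broken by gene-id order; equal-count
  bins.
* The quality-score integral runs over `[min(mu), max(mu)]` of the scaffold;
  a degenerate range is an error.
* Weights at entries of genes with detection rate 0 or 1 are exactly 1; a
  zero entry in a gene with detection rate 1 indicates upstream corruption
  and raises an assertion.
* Kernel rows whose mass underflows to zero (a point farther than ~16
  standardized units from all others, which standardization precludes in
  practice) fall back to a uniform neighborhood.
* k-means uses k-means++-style seeded initialization over the default grid
  k = 2..7; `k = 1` is allowed as a degenerate entry.
* Cluster labels are 1-based, following R convention.
* When no housekeeping list is supplied, genes detected in at least 95% of
  cells stand in as the constitutive set; a study-matched list is always
  preferable.
* Duplicate gene rows on input collapse by entry-wise maximum (conservative
  against double counting); gene identifiers are upper-cased so signature
  files with mixed-case symbols match.
* Signed signatures are encoded in GMT as a shared stem with `_UP` and
  `_DN`/`_DOWN` suffixes; a gene listed on both sides keeps the UP sign with
  a warning.

# Known limitations

The dropout model is per-cell, not per-gene: genes with unusual capture
behavior are averaged into the cell curve. The background model assumes
random signatures of equal size are exchangeable with biological ones under
the null, which ignores gene–gene correlation; the shuffle control in the
test suite probes exactly this. ISOMAP can fail on fragmented neighbor
graphs, in which case its configurations are skipped and logged rather than
repaired. t-SNE configurations refuse datasets too small for their
perplexity (3·perplexity must be below N−1).
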