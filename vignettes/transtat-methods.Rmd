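---
title: "transtat: methods, defaults and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{transtat: methods, defaults and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transtat)
```

transtat is an exploratory-statistics toolbox for genes × samples
expression matrices. This vignette records the statistical model behind
each operation, the tunable parameters with their defaults and rationale,
the numerical choices that make results bit-reproducible, and what the
synthetic-data generator does and does not emulate. Nothing here asserts an
empirical result that the test suite or the acceptance script does not
itself compute.

## Input model

The central object is a non-negative, finite, gene × sample matrix with
unique, case-sensitively matched, whitespace-trimmed gene and sample names.
Duplicate gene names are an error, never merged: silent case-folding or
merging is a classic source of irreproducible joins. Whether values are raw
read counts is tracked explicitly; the auto-detection ("every value is a
non-negative whole number") is only a heuristic — normalized data can be
integer-valued by coincidence — so every reader accepts an explicit
override. Parsing is locale-independent (decimal point only). Supporting
files (gene lengths, metadata, DE tables) accept an optional header,
detected by a non-numeric field where a number is expected; the one-column
control-gene list has no detectable header, so every non-empty line is read
as a gene name.

## Pre-processing

**Filtering.** A gene is kept iff its expression strictly exceeds
`min_value` in at least `min_samples` samples. The comparison is strict
(`>`): "minimum value required to exceed" reads as strict exceedance.
Filtering is idempotent, and removing every gene is an error because every
downstream statistic would be undefined.

**FPKM/RPKM/TPM.** FPKM is `count · 10⁹ / (column_total · length_bp)`; RPKM
is the same arithmetic under the single-end name. TPM normalizes the
length-corrected rates so each column sums to exactly 10⁶ — equivalently,
FPKM rescaled per column; this identity is one of the acceptance
properties. Both require raw counts and a length for every gene; an
absent length or an all-zero column is an error, not a silent NaN.

**Upper quartile.** Genes with zero counts in *every* sample are set aside;
each column is divided by the 75th percentile of the remaining counts and
rescaled by the mean of those percentiles so magnitudes stay count-like.
Percentiles use linear interpolation between order statistics
(`quantile type 7`), pinned so results are bit-reproducible across
platforms.

**RUV.** The control-gene (RUVg-style) route: on `log(count + 1)`, the
row-centered control submatrix is decomposed by SVD and the top-`k` right
singular vectors are taken as per-sample unwanted factors; every gene is
regressed on them and the fitted component subtracted. Because the factors
are orthonormal and sum to zero, the regression is a single matrix product,
and control-gene residuals are orthogonal to the removed factors by
construction. Singular values indistinguishable from zero are dropped, so
controls that are constant across samples leave the data untouched instead
of injecting an arbitrary direction. `k` defaults to 1 (the tool's flag
controls it); the pseudocount defaults to 1 and must be positive. Values
return to the original scale as `exp(cleaned) − pseudocount`, floored at 0.

**RLE.** Per gene, natural-log expression (plus pseudocount) minus the
gene's median log across samples; per-sample quartiles summarize the
boxplots. Tight, zero-centered boxes indicate comparable samples. The
pseudocount (default 1) guarantees positivity, so genes with zeros remain
included.

The command-line pipeline applies filtering before normalization (matching
the order in which the steps are described for the original workflow), but
both orders are reachable through the library.

## Distribution fitting

Six strictly positive families are supported: lognormal, Pareto (type I),
log-logistic, gamma, Weibull, and Burr type XII with density
`f(x) = (ck/λ)(x/λ)^{c−1}[1+(x/λ)^c]^{−(k+1)}` — stated explicitly because
Burr parameterizations differ across sources; the log-logistic is its
`k = 1` special case. Zeros are excluded before fitting (every support is
positive) and their count reported; below 30 positive values a warning is
issued.

Closed forms are used where they exist: lognormal (mean and *population*
standard deviation of the logs) and Pareto (location profiled at the sample
minimum, shape `n / Σ ln(xᵢ/x_min)`; the AIC still counts 2 parameters,
following standard practice). The other families are optimized on
log-parameters from three fixed moment-based starting points (Nelder-Mead,
relative tolerance 1e-8, followed by a BFGS polish), because the Burr
likelihood is multi-modal on skewed data and because the simplex alone
stalls about 5e-5 short of the closed-form optimum — the package requires
1e-6 agreement between its two routes. Each numerical fit records a
convergence flag and the gradient norm at the optimum; non-converged fits
are kept but excluded from AIC rankings. AIC is exactly `2k − 2 ln L`, and
ties rank the family with fewer parameters first.

Model-recovery behaviour (checked, not assumed, by the acceptance suite):
at n = 5000 each family is recovered as the AIC winner in ≥ 80% of seeded
replicates. Burr ↔ log-logistic confusions are tolerated (one nests the
other); Burr also approaches the Weibull in a boundary limit, so it
occasionally undercuts Weibull by less than one AIC unit — those misses are
*not* tolerated, they simply stay within the 80% margin.

The power-law cutoff report addresses low signal-to-noise expression: it
returns the fraction of values strictly below a threshold (default 10, the
conventional FPKM reliability cutoff) and the Pareto fit restricted to the
values at or above it, letting the user judge whether the reliable tail is
power-law-like.

## Correlations, PCA, k-means

Correlations are computed on the matrix as provided (a flag applies
log10(x+1) first; both conventions are common, so neither is forced).
Spearman uses mid-ranks for ties, i.e. it equals Pearson on ranked data —
that equivalence is an acceptance property. A zero-variance sample yields
`NA` with a warning, never a silent 0.

PCA treats samples as observations and genes as variables (samples appear
as points), with log10(x+1) then gene-wise centering by default — raw
magnitudes would let a few highly expressed genes dominate — and optional
unit-variance scaling. Components number `min(samples − 1, genes)`;
variance fractions are non-negative, non-increasing and sum to 1, and the
decomposition is validated against a brute-force covariance
eigendecomposition.

k-means is Lloyd's algorithm with 25 seeded restarts, keeping the lowest
within-cluster sum of squares; assignment ties break toward the lowest
cluster index and emptied clusters are re-seeded with the worst-fitted
point. The implementation is deterministic given the seed — the reason it
is hand-rolled rather than delegated. The CLI clusters PC scores by
default (`--on matrix` uses the log-transformed sample vectors instead).

## Entropy and noise

Entropy of a sample is computed by binning its expression vector into
equal-width bins spanning [min, max] (right-closed last bin), with the bin
count from Doane's rule `ceil(1 + log₂ n + log₂(1 + |g₁|/σ_g₁))`, where
`g₁` is the moment skewness and `σ_g₁ = sqrt(6(n−2)/((n+1)(n+3)))`. The
vector is log10(x+1)-transformed by default — raw RNA-seq spans decades,
which makes linear bins degenerate — with a flag restoring linear binning.
Entropy is reported in bits (base-2 logs, stated because conventions
differ) and satisfies `0 ≤ H ≤ log₂(bins)`; a constant vector gets one bin
and zero entropy with a warning.

Noise between two samples is the squared coefficient of variation
`σ²/μ²` computed per gene on the pair and averaged. The two-point variance
uses the **population** convention (divide by 2), making a gene with values
`(x, 3x)` contribute exactly 0.25; this is stated prominently because the
sample convention would double every entry. Genes whose pair mean is zero
are excluded (count recorded); a pair with no usable genes yields `NA`. The
per-gene CV² vectors are exposed for users who want distributions rather
than means.

## Clustering and volcano categorization

Gene selection takes either an external DE table (genes categorized
significant by the volcano rule) or a fold-change screen: fold =
`(mean_B + 1)/(mean_A + 1)`, kept iff `≥ min_fold` or `≤ 1/min_fold`. The
pseudocount avoids division by zero and the reciprocal rule makes the
selection symmetric in the condition labels.

Selected genes are z-scored per row using the sample (n−1) standard
deviation — the population/sample choice is ambiguous in common usage, so
it is fixed and documented; zero-variance genes are dropped with a report.
Ward clustering uses Euclidean distances with the criterion applied to
squared distances ("ward.D2" convention; merge heights are square roots of
the Ward criterion) — stated because two incompatible "Ward" variants
circulate. Merge heights are validated against a hand-written O(n³)
Lance-Williams implementation, and tree cuts satisfy the nesting property.
Cluster gene lists are written one file per cluster; leaf order keeps
cluster blocks contiguous for the heatmap.

Volcano categorization: `sig-up` iff `p < p_threshold` and `log2fc ≥
fc_threshold`; `sig-down` mirrored; otherwise `not-sig`. p-values of 0 are
mapped to a 1e-300 floor (warning) so `−log10 p` stays finite.

## Synthetic data: the stated world

The generator draws one baseline expression per gene from a named family
(defaults: lognormal with meanlog 2, sdlog 1 — median ≈ 7.4, heavy right
tail, a typical normalized bulk profile), plants a fold change (default 4,
half up / half down) in one condition for a fraction of genes (default
10%), applies an optional multiplicative per-sample factor to *all* genes
including the controls (the artifact RUV removes), multiplies by lognormal
replicate noise (sdlog 0.1 ≈ 10% CV, typical technical-plus-biological
replicate scatter in bulk RNA-seq; tests that need a noise-free world
request sdlog 0 explicitly), and rounds to integer counts — rounding, not
truncation, to preserve means. Seeding is mandatory and the same seed
reproduces the bundle byte-for-byte.

What the generator does **not** emulate: gene-gene correlation structure,
mean-variance (overdispersion) trends, length bias within a library,
batch-by-condition confounding, or zero-inflation beyond what rounding
small baselines produces. A green test therefore establishes algorithmic
correctness on a controlled world — scale invariances, conservation
identities, factor recovery — not robustness to every artifact of real
libraries.

## Numerical and degenerate-input policy

All tolerances used by the test suite are stated in the tests themselves
(e.g. 1e-12 for oracle identities, 1e-9 for eigen/reconstruction checks,
1e-6 for closed-form agreement). Percentiles are type 7 everywhere.
Degenerate inputs fail loudly rather than silently: empty matrices, all
zero columns, constant matrices for PCA, single-sample RLE, metadata not
covering the matrix, `k` ≥ samples for RUV. Where a statistic is undefined
for part of the data (zero-variance Pearson, zero-mean noise pairs), the
result is `NA` plus a warning, preserving the distinction between "zero"
and "undefined".

## Known limitations

- Differential-expression *testing* is out of scope by design: the package
  categorizes an externally produced DE table but does not estimate
  dispersions or run exact/Wald tests (edgeR/DESeq2/NOISeq territory).
- Gene-ontology enrichment is out of scope (requires annotation services).
- No TMM or median-of-ratios size factors; the five implemented schemes
  cover the depth/length and unwanted-variation families only.
- Distribution fitting assumes independent draws; expression values within
  a sample are not independent, so AIC rankings are descriptive
  diagnostics, not formal tests.
- The RUV implementation is the control-gene (RUVg-like) flavor only; with
  biased controls (e.g. controls that actually respond to condition) the
  removed factor absorbs biology.
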