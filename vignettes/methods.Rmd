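---
title: "Methods: consensus gene scoring and cross-dataset DAM marker selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus gene scoring and cross-dataset DAM marker selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Disease-associated microglia (DAM) are a transcriptional subpopulation of
microglia found near amyloid plaques in Alzheimer's-model mice, defined by
upregulated AD-risk genes and downregulated homeostatic genes. A recurring
analysis question is how a target gene — here a PIEZO1-like mechanosensitive
channel — relates to that program across independent single-cell datasets.
scDAM packages the full chain of that analysis as tested, reusable stages:
quality control, normalization, embedding and graph clustering, marker-panel
annotation, a per-cell-type gene *consensus score*, and a cross-dataset
marker selection procedure combining correlation with the target and
presence among target-positive cells.

## Quality control

`apply_qc()` keeps a gene if it is detected (count > 0) in at least 3 cells
and a cell if it detects at least 200 genes and has a mitochondrial UMI
fraction of at most 5% (strictly greater is removed; a cell at exactly 5%
is kept). All criteria are evaluated on the raw input matrix in a single
simultaneous pass, not iterated to a fixed point; a kept gene may therefore
fall below the detection threshold among the surviving cells. This matches
the common droplet-workflow behaviour and keeps the operation idempotent in
practice without hiding an implicit fixed-point loop. The mitochondrial
fraction of a zero-count cell is defined as 0 so such cells are removed by
the detected-genes rule rather than a division error. Optional depth bounds
(UMIs per cell, genes-per-cell upper bound) are off by default because they
are dataset-specific choices. Multiplet removal is supported only as an
externally supplied barcode exclusion list: doublet detection itself is a
separate method family, and a hook preserves the pipeline's shape without
re-implementing it.

Mitochondrial genes are flagged by the case-insensitive symbol prefix
`MT-`, covering human (`MT-ND4`) and mouse (`mt-Nd4`) nomenclature; an
explicit gene list overrides the prefix rule.

## Normalization, embedding, clustering, annotation

`normalize_log()` scales every cell to a common target depth (median
library size by default) and applies `log(1 + x)`. Zeros are preserved, so
detection is identical on the raw and normalized layers — which is why the
consensus score's frequency component can be computed on raw counts while
its expression component uses the normalized layer without inconsistency.

`select_hvg()` ranks genes by the variance of the log-normalized layer
(2000 genes by default), breaking ties by ascending gene index so the
selection is deterministic. Variance is the simplest defensible dispersion
measure; any monotone alternative would satisfy the same contract.

`embed_pca()` standardizes each selected gene, clips standardized values at
±10 (configurable) to bound the influence of outlier cells, and takes the
leading 20 components of the gene-gene covariance eigendecomposition. Each
component's sign is fixed so its largest-magnitude loading is positive,
making embeddings machine-independent.

`cluster_graph()` builds an exact k-nearest-neighbour graph (k = 20) in PC
space, weights edges by the Jaccard overlap of the two cells'
self-inclusive neighbourhoods, prunes overlaps below 1/15, and partitions
with Louvain modularity at the configured resolution. Resolutions are
dataset-specific in the motivating analyses (0.32, 0.2 and 0.06 on the
three datasets); 0.32 is the default. Clustering is randomized internally,
so the partition is made reproducible by seeding; cluster ids are relabelled
0-based by decreasing size. Note that a disconnected neighbourhood graph can
never merge across components, whatever the resolution.

`annotate_clusters()` scores each (cluster, panel) pair as the mean
rank-quantile of the panel genes' mean expression among all genes in the
cluster, and annotates each cluster with the argmax panel, ties broken by
panel order. This is a deliberate substitution: the annotation tools used
in the motivating analyses (scCATCH, GSVA) are full external methods, and
what downstream stages actually require is a deterministic panel argmax per
cluster. The rank-quantile score provides that with a two-line definition
and exact tie semantics. It shares the rank-ratio primitive with the
consensus score below, so its behaviour is covered by the same oracle
tests.

## The consensus score

For a cell type with cells \(C\) and genes \(g = 1..G\) (\(G \ge 2\)), let
\(f_g\) be the detection frequency of gene \(g\) in \(C\) (raw counts) and
\(e_g\) its mean log-normalized expression in \(C\). The rank ratio of a
value \(v_g\) within \(\{v_1..v_G\}\) is

\[
  r(g) = \frac{\#\{h \ne g : v_h < v_g\} + \tfrac12\,\#\{h \ne g : v_h = v_g\}}{G - 1},
\]

i.e. the fraction of *other* genes the gene strictly exceeds, with ties at
half weight. The consensus score is \(s_g = r_f(g) + r_e(g) \in [0, 2]\): a
gene that is strictly the most frequently detected and the most expressed
in a cell type scores exactly 2; strictly last in both scores exactly 0; a
rank ratio of 0.6 means the gene exceeds 60% of the other genes. The
half-tie rule is the normative formula of this package: it keeps the
all-equal case symmetric at 0.5 and conserves the mean rank ratio at
exactly 0.5 per cell type, which the tests assert to machine precision.
The expression component uses the normalized layer because raw means are
depth-confounded; the frequency component is unaffected by that choice
since normalization preserves zeros.

## Marker selection

Given named microglial subclusters per dataset, a target gene and marker
classes (up-in-DAM, down-in-DAM):

* **Correlation** — Pearson on the log-normalized layer over *all* cells of
  the pooled named subclusters (Spearman available by configuration).
  Up-class markers must reach \(r \le -0.7\), down-class \(r \ge +0.7\),
  bounds inclusive.
* **Presence** — among the subcluster cells with raw target count > 0, the
  fraction detecting the marker must be \(\ge 70\%\), inclusive.
* **Intersection** — by default a marker must satisfy both criteria in
  every configured dataset.

Target-positivity enters only the presence criterion, never the
correlation; the two criteria deliberately answer different questions (is
the marker's level coupled to the target's level; is the marker reliably
co-detected where the target is detected). Pooling the named subclusters
(rather than requiring the criteria per subcluster) is the default; a
per-subcluster mode is available but flagged experimental, since the
motivating description does not disambiguate the two. Thresholds are
applied by `select_markers()` on stored statistics, so sensitivity
re-thresholding costs nothing and threshold-monotonicity (relaxing bounds
never shrinks the kept set) is testable directly. Fixed correlation
thresholds, not p-values, define "high correlation"; no multiplicity
correction applies.

## Bulk harmonization

`harmonize_bulk()` chains `log2(x + 1)` (pseudocount configurable),
quantile normalization (via `limma::normalizeQuantiles`, ties receiving the
mean of their reference values; idempotent), and per-gene batch-mean
centering — each batch's mean is replaced by the grand mean, the
no-covariate special case of linear-model batch residualization, verified
in the tests against `limma::removeBatchEffect`.

## Study design calculations

`sample_size_two_group()` uses the normal-approximation formula
\(n = \lceil 2 (z_{1-\alpha/2} + z_{\beta})^2 / d^2\rceil\) per group with
\(d = (\text{fold} - 1)/\text{sd}\) against a unit baseline and a floor of
2. At the package defaults (power 0.80, two-sided alpha 0.05, 1.5-fold,
sd 0.3) it returns 6 per group. The baseline is fixed at 1 so "1.5-fold"
maps to an absolute difference of 0.5 — the only reading consistent with
that result; a noncentral-t iteration is stricter (7 at the same settings)
and available behind `method = "t"`. `relative_expression()` computes
\(2^{\Delta\Delta Ct}\) fold change with the sign convention made explicit:
the default orientation expects the input pre-oriented so that enrichment
gives fold > 1, and a `raw_difference` orientation applies the textbook
\(2^{-\Delta\Delta Ct}\) instead — both are offered because the published
convention is written both ways and the correct sign depends on how the
differences were taken.

## The synthetic data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, not any particular tissue: three cell types (40% microglia by
default) with 10 planted identity markers each; a latent DAM activation
\(a\) per cell — standard normal, shifted by 2 SD in the 40% of microglia
designated DAM; negative-binomial counts with mean
\(\text{lib}_i \cdot \text{base}_g \cdot e^{\lambda_g a_i}\) and size 10;
a log-normal library factor (sigma 0.3); and mitochondrial genes whose
means are solved so the expected mitochondrial fraction is 3%. The target
gene loads negatively on \(a\) (lower in DAM, as observed for PIEZO1), 7
up-markers positively, 13 down-markers negatively, 50 null markers not at
all — mirroring the 7-up/13-down structure the selection procedure is
meant to recover. Program genes (target, DAM markers, nulls) have base
mean 20, emulating the well-expressed genes (ferritin, ribosomal,
Malat1-class) that real DAM signatures comprise; identity markers 8;
background genes 0.3.

Correlations cannot be dialled directly because NB noise and the log1p
transform attenuate the latent coupling, so `calibrate_loadings()` solves
for loading magnitudes numerically: it traces the attainable correlation
over a loading grid under the generator's own noise model (Monte Carlo at
n = 6000 with common random numbers, which makes the curve smooth and the
solve stable), fixes the target loading at the strongest requested class
and solves the weaker class conditionally. Requests beyond the attainable
ceiling error out stating the maximum. At 10,000 cells the empirical
bias of the realized correlations is below 0.05 (asserted in the tests);
at the default 3000 cells sampling spread dominates. Setting a requested
correlation to 0 decouples the class entirely, giving the null
configuration used for specificity checks.

What the generator does **not** emulate: ambient RNA, doublets, batch
chemistry effects, realistic gene-gene correlation beyond the single DAM
factor, or cell-type specificity of the target's baseline expression (the
target is well-expressed in all planted types, so consensus-score contrasts
between cell types are weaker than in real tissue). Passing tests on
generator output therefore demonstrate the pipeline's correctness and
power under the planted model, not performance on any real dataset.

## Problem sizes and numerical choices

The test-suite exercises the planted-marker recovery at the generator
defaults (two datasets of 3000 cells x 1000 genes, 10 seeds) and the null
control at 100 paired runs of 3000 cells x 300 genes — the null
configuration needs only enough genes for stable normalization, so the
gene complement is reduced there. The workflow scripts under `analysis/`
use the full defaults. Ties everywhere have defined semantics (half-weight
in rank ratios, ascending index in HVG selection, panel order in
annotation, first maximum in argmax). Degenerate inputs are contracts, not
crashes: zero-cell datasets pass QC as empty; zero-count cells are
rejected by normalization with a pointer to QC; constant or absent markers
fail selection with a stated reason rather than propagating NA.

## Known limitations

Exact kNN via blockwise distances is quadratic in cells — fine at the
package's intended desk scale (thousands of cells), wasteful at atlas
scale. Louvain resolution semantics differ subtly across graph libraries;
partitions at matched resolutions are comparable within this package, not
across toolchains. The annotation score substitutes the external
enrichment methods it stands in for; labels agree on well-separated types
(adjusted Rand ≥ 0.9 in the tests) but the scores themselves are not
GSVA enrichment values. The qPCR fold-change sign depends on the caller's
ΔΔCt orientation; the package documents both rather than guessing.
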