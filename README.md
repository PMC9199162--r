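# scDAM

Consensus gene scoring and cross-dataset DAM marker selection for
single-cell RNA-seq.

Disease-associated microglia (DAM) are a microglial subpopulation in
Alzheimer's-model brains, marked by upregulated AD-risk genes and
downregulated homeostatic genes. Analyses that relate a target gene — the
motivating case is the mechanosensitive channel gene *PIEZO1* — to the DAM
program across independent datasets all share the same chain of steps:
quality control, normalization, clustering and annotation, a per-cell-type
gene score, and a marker filter applied consistently across datasets.
scDAM implements that chain as tested, reusable stages, plus a seeded
synthetic data generator so every stage can be exercised end-to-end with a
known ground truth and no downloads.

## The two core procedures

**Consensus score.** For each cell type with genes *g* = 1..*G*, let
*f<sub>g</sub>* be the detection frequency (fraction of the type's cells
with count > 0) and *e<sub>g</sub>* the mean log-normalized expression.
With the rank ratio

&nbsp;&nbsp;&nbsp;&nbsp;r(g) = ( #{h ≠ g : v<sub>h</sub> < v<sub>g</sub>} + ½·#{h ≠ g : v<sub>h</sub> = v<sub>g</sub>} ) / (G − 1),

the consensus score is s<sub>g</sub> = r<sub>f</sub>(g) + r<sub>e</sub>(g) ∈ [0, 2]:
exactly 2 for a gene strictly top in both frequency and expression, exactly
0 for a gene strictly last in both.

**Marker selection.** Within named microglial subclusters, each DAM marker
is (a) correlated with the target on the log-normalized layer over all
subcluster cells — up-in-DAM markers must reach r ≤ −0.7, down-in-DAM
r ≥ +0.7, bounds inclusive — and (b) required to be detected in ≥ 70%
(inclusive) of the target-positive subcluster cells. A marker is kept only
if it satisfies both criteria in every configured dataset.

Also included: QC with the standard droplet thresholds (gene in ≥ 3 cells,
cell with ≥ 200 genes, mitochondrial fraction ≤ 5%), HVG/PCA/Louvain
clustering with panel-based annotation, bulk RNA-seq harmonization
(log2 → quantile normalization → batch centering), and study design
calculations (two-group sample size, ΔΔCt fold change).

## Worked example

```r
library(scDAM)

params <- sim_params(seed = 1L)            # 3000 cells, 1000 genes, 2 datasets
pair   <- simulate_dataset_pair(params)    # shared truth, independent noise
truth  <- pair[[1]]$truth

markers <- marker_set(truth$symbol[truth$gene_role == "up_dam"],
                      truth$symbol[truth$gene_role == "down_dam"])
config  <- analysis_config(
  cluster     = cluster_params(n_hvg = params$n_genes),
  corr_filter = correlation_filter_params(target_gene = "Piezo1",
                                          select_cell_type = "Microglia"),
  seed = 1L)

res <- run_pipeline(config, lapply(pair, `[[`, "dataset"),
                    truth_panels(truth), markers)
res$markers
#> MarkerCorrelationResult: 20/20 markers kept
#>   UpDam1, UpDam2, ..., UpDam7, DownDam1, ..., DownDam13
```

All 7 planted up-markers (model correlation −0.85 with the target) and 13
down-markers (+0.8) are recovered; none of the 50 null markers pass the
±0.7/70% criteria. The clustering stage finds the three planted cell types
plus a DAM subcluster within the microglia (labels `Microglia_2`,
`Microglia_3`), and the selection pools the microglial clusters of each
dataset.

```r
sample_size_two_group(power_params(power = 0.80, alpha = 0.05,
                                   fold_change = 1.5, sd = 0.3))
#> [1] 6
```

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01` simulates and writes the paired datasets (10x-style
triplets + truth tables), `02` runs QC/clustering/annotation, `03`
computes consensus scores, `04` performs the cross-dataset marker
selection (printing `precision 1.00 recall 1.00` against the planted
truth), `05` demonstrates bulk harmonization, `06` the study design
calculations. Each writes its tables under `results/`.

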