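#!/usr/bin/env Rscript
# Step 4: cross-dataset DAM marker selection. Within the microglial
# clusters of each dataset, correlate every DAM marker with the target on
# the log-normalized layer and measure its presence among target-positive
# cells; keep markers with |r| >= 0.7 (sign by class, bounds inclusive)
# and presence >= 70% in BOTH datasets. Compares the kept set with the
# planted truth.

suppressPackageStartupMessages(library(scDAM))

ids <- c("mouse1", "mouse2")
truth <- utils::read.table("results/data/mouse1/gene_truth.tsv",
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
mk <- marker_set(truth$symbol[truth$role == "up_dam"],
                 truth$symbol[truth$role == "down_dam"])
params <- correlation_filter_params(target_gene = "Piezo1",
                                    select_cell_type = "Microglia")

stats <- lapply(ids, function(id) {
  dir <- file.path("results/data", id)
  ds <- read_sparse_triplet(file.path(dir, "matrix.mtx"),
                            file.path(dir, "barcodes.tsv"),
                            file.path(dir, "features.tsv"),
                            dataset_id = id)
  ds <- normalize_log(apply_qc(ds, qc_params())$dataset)
  ann <- utils::read.table(file.path("results",
                                     sprintf("clusters_%s.tsv", id)),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ds$cell_meta$cluster <- ann$label
  evaluate_marker_stats(ds, mk, params)
})

sel <- select_markers(stats, mk, params)
print(sel)
utils::write.table(sel$table, "results/marker_stats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sel$final, "results/marker_selection.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

planted <- c(mk$up_markers, mk$down_markers)
kept <- sel$final$marker[sel$final$final_kept]
cat(sprintf("kept %d markers; planted %d; precision %.2f recall %.2f\n",
            length(kept), length(planted),
            mean(kept %in% planted), mean(planted %in% kept)))
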