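#' Full analysis configuration
#'
#' Bundles every stage's parameters into one validated structure. All
#' workflow thresholds (gene/cell/mito QC, HVG and PC counts, resolution,
#' correlation and presence bounds) live here as named defaults, never as
#' literals in stage code.
#'
#' @param qc A \code{\link{qc_params}} object.
#' @param cluster A \code{\link{cluster_params}} object, or a named list of
#'   them keyed by dataset id (resolutions are typically dataset-specific).
#' @param corr_filter A \code{\link{correlation_filter_params}} object.
#' @param power A \code{\link{power_params}} object.
#' @param seed Integer master seed for the run; overrides the clustering
#'   seed so one value governs the whole pipeline.
#' @return A validated list of class \code{AnalysisConfig}.
#' @export
analysis_config <- function(qc = qc_params(), cluster = cluster_params(),
                            corr_filter = correlation_filter_params(
                              select_cell_type = "Microglia"),
                            power = power_params(), seed = 1L) {
  if (inherits(cluster, "ClusterParams")) {
    stopifnot(TRUE)
  } else {
    stopifnot(is.list(cluster), length(cluster) >= 1,
              all(vapply(cluster, inherits, logical(1), "ClusterParams")),
              !is.null(names(cluster)))
  }
  stopifnot(inherits(qc, "QCParams"),
            inherits(corr_filter, "CorrelationFilterParams"),
            inherits(power, "PowerParams"))
  structure(list(qc = qc, cluster = cluster, corr_filter = corr_filter,
                 power = power, seed = as.integer(seed)),
            class = "AnalysisConfig")
}

#' MD5 hash of an arbitrary R object
#'
#' Deterministic content hash used by the pipeline run record to assert
#' reproducibility (identical config + seed must give identical hashes).
#'
#' @param x Any serializable R object.
#' @return A hex string.
#' @export
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 3), f)
  unname(tools::md5sum(f))
}

cluster_params_for <- function(config, dataset_id) {
  cp <- if (inherits(config$cluster, "ClusterParams")) config$cluster
        else config$cluster[[dataset_id]]
  if (is.null(cp)) {
    stop(sprintf("no cluster params configured for dataset '%s'", dataset_id))
  }
  cp$seed <- config$seed
  cp
}

run_stage <- function(stage, dataset_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed on dataset '%s': %s",
                 stage, dataset_id, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full single-cell analysis pipeline
#'
#' Executes, per dataset: QC -> normalization -> HVG selection -> PCA ->
#' graph clustering -> panel-based cluster annotation -> per-cell-type
#' consensus scores -> marker correlation/presence statistics; then the
#' cross-dataset marker selection. Deterministic for a fixed config + seed;
#' no stage mutates its input (asserted via content hashes in the run
#' record).
#'
#' @param config An \code{\link{analysis_config}}.
#' @param datasets Named list of \code{\link{expression_dataset}} objects;
#'   names must match each dataset's \code{dataset_id}.
#' @param panels A \code{\link{gene_panel}} for cluster annotation.
#' @param markers A \code{\link{marker_set}} for the selection stage.
#' @return A list of class \code{PipelineResult}: \code{scores} (consensus
#'   score table over all datasets), \code{markers} (a
#'   \code{MarkerCorrelationResult}), \code{annotated} (the per-dataset
#'   processed datasets with cluster labels), \code{qc_reports}, and
#'   \code{record} (config snapshot, seed, per-stage output hashes,
#'   timestamps, package version).
#' @export
run_pipeline <- function(config, datasets, panels, markers) {
  stopifnot(inherits(config, "AnalysisConfig"), length(datasets) >= 1,
            inherits(panels, "GenePanel"), inherits(markers, "MarkerSet"))
  if (is.null(names(datasets))) {
    names(datasets) <- vapply(datasets, function(d) d$cell_meta$dataset_id[1],
                              character(1))
  }
  # fail fast on configuration before any compute
  for (id in names(datasets)) cluster_params_for(config, id)

  record <- list(config = config, seed = config$seed,
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 version = as.character(utils::packageVersion("scDAM")),
                 input_hashes = lapply(datasets, hash_object),
                 stage_hashes = list())
  scores_all <- list()
  stats_all <- list()
  qc_reports <- list()
  annotated <- list()

  for (id in names(datasets)) {
    ds <- datasets[[id]]
    cp <- cluster_params_for(config, id)
    qc_out <- run_stage("qc", id, apply_qc(ds, config$qc))
    qc_reports[[id]] <- qc_out$report
    norm <- run_stage("normalize", id, normalize_log(qc_out$dataset, cp))
    hvg <- run_stage("hvg", id, select_hvg(norm, cp$n_hvg))
    emb <- run_stage("pca", id, embed_pca(norm, hvg, cp))
    cl <- run_stage("cluster", id, cluster_graph(emb, cp))
    ann <- run_stage("annotate", id, annotate_clusters(norm, cl, panels))
    norm$cell_meta$cluster <- ann$cluster_label
    annotated[[id]] <- norm
    scores <- run_stage("score", id, consensus_scores(norm, ann$cell_type))
    scores$dataset_id <- id
    scores_all[[id]] <- scores
    stats_all[[id]] <- run_stage("correlate", id,
      evaluate_marker_stats(norm, markers, config$corr_filter))
    record$stage_hashes[[id]] <- list(
      qc = hash_object(qc_out$dataset$counts),
      clusters = hash_object(cl),
      annotation = hash_object(ann$table),
      scores = hash_object(scores),
      marker_stats = hash_object(stats_all[[id]]))
  }
  selection <- run_stage("select", "all",
    select_markers(stats_all, markers, config$corr_filter))
  record$stage_hashes$final <- hash_object(selection)
  record$input_hashes_after <- lapply(datasets, hash_object)
  record$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  structure(list(scores = do.call(rbind, c(scores_all,
                                           list(make.row.names = FALSE))),
                 markers = selection, annotated = annotated,
                 qc_reports = qc_reports, record = record),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult: %d dataset(s)\n", length(x$annotated)))
  print(x$markers)
  invisible(x)
}
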