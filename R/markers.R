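#' Marker selection parameters
#'
#' Controls the cross-dataset DAM-marker selection against a target gene
#' (the motivating study's target is \emph{Piezo1}). A marker of the
#' "up-in-DAM" class is kept when its correlation with the target is at or
#' below \code{-corr_threshold}; a "down-in-DAM" marker when at or above
#' \code{+corr_threshold}; both additionally require detection in at least
#' \code{presence_threshold} of the target-positive cells. All bounds are
#' inclusive. With \code{require_all_datasets} (the default) a marker must
#' satisfy the criteria in every configured dataset.
#'
#' @param target_gene Symbol of the target gene.
#' @param corr_threshold Magnitude of the correlation bound, in (0, 1].
#' @param presence_threshold Minimum fraction of target-positive cells in
#'   which the marker is detected, in (0, 1].
#' @param subclusters_per_dataset Named list mapping dataset id to the
#'   cluster labels whose cells enter the analysis (exact string match on
#'   \code{ClusterAssignment} labels). May be \code{NULL} when
#'   \code{select_cell_type} is given.
#' @param select_cell_type Convenience alternative: use every cluster
#'   annotated to this cell type (e.g. \code{"Microglia"}) in each dataset.
#' @param require_all_datasets Keep a marker only if it passes in all
#'   configured datasets (set intersection across datasets).
#' @param correlation_kind \code{"pearson_on_lognorm"} (default) or
#'   \code{"spearman_on_lognorm"}.
#' @param per_subcluster Experimental: evaluate the criteria within each
#'   named subcluster separately and require all to pass, instead of pooling
#'   the subclusters' cells (the default).
#' @return A validated list of class \code{CorrelationFilterParams}.
#' @export
correlation_filter_params <- function(target_gene = "Piezo1",
                                      corr_threshold = 0.7,
                                      presence_threshold = 0.70,
                                      subclusters_per_dataset = NULL,
                                      select_cell_type = NULL,
                                      require_all_datasets = TRUE,
                                      correlation_kind = c("pearson_on_lognorm",
                                                           "spearman_on_lognorm"),
                                      per_subcluster = FALSE) {
  stopifnot(corr_threshold > 0, corr_threshold <= 1,
            presence_threshold > 0, presence_threshold <= 1,
            is.character(target_gene), nchar(target_gene) > 0)
  if (is.null(subclusters_per_dataset) && is.null(select_cell_type)) {
    stop("either subclusters_per_dataset or select_cell_type must be given")
  }
  structure(list(target_gene = target_gene,
                 corr_threshold = corr_threshold,
                 presence_threshold = presence_threshold,
                 subclusters_per_dataset = subclusters_per_dataset,
                 select_cell_type = select_cell_type,
                 require_all_datasets = isTRUE(require_all_datasets),
                 correlation_kind = match.arg(correlation_kind),
                 per_subcluster = isTRUE(per_subcluster)),
            class = "CorrelationFilterParams")
}

#' Marker set with up- and down-regulated classes
#'
#' @param up_markers,down_markers Disjoint character vectors of gene symbols
#'   (the DAM up- and down-regulated marker classes).
#' @return A list of class \code{MarkerSet}.
#' @export
marker_set <- function(up_markers, down_markers) {
  up_markers <- unique(as.character(up_markers))
  down_markers <- unique(as.character(down_markers))
  overlap <- intersect(up_markers, down_markers)
  if (length(overlap)) {
    stop(sprintf("markers in both classes: %s", paste(overlap, collapse = ", ")))
  }
  structure(list(up_markers = up_markers, down_markers = down_markers),
            class = "MarkerSet")
}

subcluster_cells <- function(dataset, subclusters) {
  cl <- dataset$cell_meta$cluster
  if (all(is.na(cl))) stop("dataset has no cluster labels")
  which(cl %in% subclusters)
}

#' Presence of a marker among target-positive cells
#'
#' Among the cells of the named subclusters with a raw target-gene count
#' above zero, the fraction in which the marker's raw count is above zero.
#'
#' @param dataset An annotated \code{\link{expression_dataset}} (cluster
#'   labels in \code{cell_meta$cluster}).
#' @param subclusters Character vector of cluster labels to pool.
#' @param target Target gene symbol.
#' @param marker Marker gene symbol.
#' @return A proportion, or \code{NA} if there are no target-positive cells
#'   or the marker is absent from the dataset.
#' @export
target_positive_presence <- function(dataset, subclusters, target, marker) {
  cells <- subcluster_cells(dataset, subclusters)
  ti <- match(target, dataset$gene_meta$symbol)
  if (is.na(ti)) stop(sprintf("target gene '%s' not in dataset", target))
  mi <- match(marker, dataset$gene_meta$symbol)
  if (is.na(mi)) return(NA_real_)
  pos <- cells[dataset$counts[cells, ti] > 0]
  if (!length(pos)) return(NA_real_)
  sum(dataset$counts[pos, mi] > 0) / length(pos)
}

#' Correlation of markers with the target gene in named subclusters
#'
#' Pearson (or Spearman) correlation on the log-normalized layer, computed
#' over \emph{all} cells of the pooled named subclusters; target-positivity
#' plays no role here (it enters only the presence criterion).
#'
#' @param dataset A dataset with cluster labels and a \code{lognorm} layer.
#' @param subclusters Character vector of cluster labels to pool.
#' @param target Target gene symbol (must have nonzero variance in the
#'   pooled cells).
#' @param markers Character vector of marker symbols.
#' @param kind \code{"pearson_on_lognorm"} or \code{"spearman_on_lognorm"}.
#' @return Named numeric vector of correlations; \code{NA} for markers that
#'   are absent or have constant expression.
#' @export
marker_target_correlation <- function(dataset, subclusters, target, markers,
                                      kind = "pearson_on_lognorm") {
  layer <- require_lognorm(dataset)
  cells <- subcluster_cells(dataset, subclusters)
  if (length(cells) < 3) stop("need >= 3 cells in the pooled subclusters")
  ti <- match(target, dataset$gene_meta$symbol)
  if (is.na(ti)) stop(sprintf("target gene '%s' not in dataset", target))
  tv <- as.numeric(layer[cells, ti])
  if (stats::sd(tv) == 0) stop("target gene has zero variance in subclusters")
  method <- if (kind == "spearman_on_lognorm") "spearman" else "pearson"
  r <- vapply(markers, function(m) {
    mi <- match(m, dataset$gene_meta$symbol)
    if (is.na(mi)) return(NA_real_)
    mv <- as.numeric(layer[cells, mi])
    if (stats::sd(mv) == 0) return(NA_real_)
    stats::cor(tv, mv, method = method)
  }, numeric(1))
  names(r) <- markers
  r
}

resolve_subclusters <- function(dataset, params) {
  id <- dataset$cell_meta$dataset_id[1]
  if (!is.null(params$subclusters_per_dataset)) {
    sub <- params$subclusters_per_dataset[[id]]
    if (is.null(sub)) stop(sprintf("no subclusters configured for dataset '%s'", id))
    return(sub)
  }
  cl <- dataset$cell_meta$cluster
  ct <- sub("_[0-9]+$", "", cl)
  sub <- unique(cl[!is.na(ct) & ct == params$select_cell_type])
  if (!length(sub)) {
    stop(sprintf("no cluster annotated '%s' in dataset '%s'",
                 params$select_cell_type, id))
  }
  sub
}

#' Evaluate correlation and presence statistics for all markers in a dataset
#'
#' Computes, per marker, the correlation with the target over the pooled
#' subcluster cells and the presence among target-positive cells, together
#' with a failure reason where a statistic is undefined. Thresholds are not
#' applied here; \code{\link{select_markers}} does that, so sensitivity
#' analyses can re-threshold without recomputation.
#'
#' @param dataset Annotated, normalized \code{ExpressionDataset}.
#' @param markers A \code{\link{marker_set}}.
#' @param params A \code{\link{correlation_filter_params}}.
#' @return A data.frame (one row per marker): \code{dataset_id},
#'   \code{marker}, \code{class}, \code{r}, \code{presence}, \code{reason}.
#' @export
evaluate_marker_stats <- function(dataset, markers, params) {
  stopifnot(inherits(markers, "MarkerSet"),
            inherits(params, "CorrelationFilterParams"))
  subclusters <- resolve_subclusters(dataset, params)
  groups <- if (params$per_subcluster) as.list(subclusters) else list(subclusters)
  all_markers <- c(markers$up_markers, markers$down_markers)
  classes <- rep(c("up", "down"),
                 c(length(markers$up_markers), length(markers$down_markers)))
  per_group <- lapply(groups, function(sub) {
    r <- marker_target_correlation(dataset, sub, params$target_gene,
                                   all_markers, params$correlation_kind)
    pres <- vapply(all_markers, function(m) {
      target_positive_presence(dataset, sub, params$target_gene, m)
    }, numeric(1))
    data.frame(dataset_id = dataset$cell_meta$dataset_id[1],
               subcluster_group = paste(sub, collapse = "+"),
               marker = all_markers, class = classes,
               r = as.numeric(r), presence = as.numeric(pres),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, per_group)
  absent <- !(out$marker %in% dataset$gene_meta$symbol)
  out$reason <- ifelse(absent, "absent",
                ifelse(is.na(out$r), "constant expression",
                ifelse(is.na(out$presence), "no target-positive cells", "")))
  out
}

#' Select markers by correlation, presence, and cross-dataset intersection
#'
#' Applies the class-dependent inclusive thresholds to per-dataset marker
#' statistics: an up-class marker passes a dataset when
#' \code{r <= -corr_threshold} and \code{presence >= presence_threshold};
#' a down-class marker when \code{r >= +corr_threshold} and
#' \code{presence >= presence_threshold}. A marker with an undefined
#' statistic fails that dataset. The final set intersects the per-dataset
#' decisions when \code{require_all_datasets}.
#'
#' @param stats_per_dataset List of data.frames from
#'   \code{\link{evaluate_marker_stats}}, one per dataset.
#' @param markers A \code{\link{marker_set}}.
#' @param params A \code{\link{correlation_filter_params}}.
#' @return A list of class \code{MarkerCorrelationResult}: \code{table}
#'   (per marker x dataset rows with \code{passed}) and \code{final}
#'   (per marker: \code{final_kept}).
#' @export
select_markers <- function(stats_per_dataset, markers, params) {
  stopifnot(length(stats_per_dataset) >= 1)
  tab <- do.call(rbind, stats_per_dataset)
  ok_corr <- ifelse(tab$class == "up",
                    tab$r <= -params$corr_threshold,
                    tab$r >= params$corr_threshold)
  ok_pres <- tab$presence >= params$presence_threshold
  tab$passed <- !is.na(ok_corr) & !is.na(ok_pres) & ok_corr & ok_pres
  agg <- if (params$require_all_datasets) all else any
  # a marker absent from a dataset contributes a FALSE row for it
  kept <- tapply(tab$passed, tab$marker, agg)
  final <- data.frame(marker = c(markers$up_markers, markers$down_markers),
                      class = rep(c("up", "down"),
                                  c(length(markers$up_markers),
                                    length(markers$down_markers))),
                      stringsAsFactors = FALSE)
  final$final_kept <- as.logical(kept[final$marker])
  final$final_kept[is.na(final$final_kept)] <- FALSE
  structure(list(table = tab, final = final),
            class = "MarkerCorrelationResult")
}

#' @export
print.MarkerCorrelationResult <- function(x, ...) {
  kept <- x$final$marker[x$final$final_kept]
  cat(sprintf("MarkerCorrelationResult: %d/%d markers kept\n",
              length(kept), nrow(x$final)))
  if (length(kept)) cat(" ", paste(kept, collapse = ", "), "\n")
  invisible(x)
}
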