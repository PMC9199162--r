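#' Clustering stage parameters
#'
#' Defaults follow the common droplet scRNA-seq workflow: library-size
#' normalization to the median depth, log1p, the 2000 most variable genes,
#' 20 principal components, a 20-nearest-neighbour graph and Louvain
#' community detection. The resolution is dataset-specific (the analyses
#' this package reproduces used 0.32, 0.2 and 0.06 on their three
#' datasets); 0.32 is the default.
#'
#' @param target_library_size Depth every cell is scaled to before log1p;
#'   either a positive number or \code{"median"} (median cell depth).
#' @param n_hvg Number of highly variable genes kept for embedding.
#' @param n_pcs Number of principal components.
#' @param n_neighbors Neighbourhood size of the cell-cell graph.
#' @param resolution Louvain resolution (> 0); larger gives more clusters.
#' @param scale_clip Per-gene standardized values are clipped to
#'   \code{[-scale_clip, scale_clip]} before PCA.
#' @param seed Integer seed making graph clustering reproducible.
#' @return A validated list of class \code{ClusterParams}.
#' @export
cluster_params <- function(target_library_size = "median", n_hvg = 2000,
                           n_pcs = 20, n_neighbors = 20, resolution = 0.32,
                           scale_clip = 10, seed = 1L) {
  stopifnot(n_hvg >= 1, n_pcs >= 1, n_pcs <= n_hvg, n_neighbors >= 2,
            resolution > 0, scale_clip > 0)
  if (!identical(target_library_size, "median")) {
    stopifnot(is.numeric(target_library_size), target_library_size > 0)
  }
  structure(list(target_library_size = target_library_size, n_hvg = n_hvg,
                 n_pcs = n_pcs, n_neighbors = n_neighbors,
                 resolution = resolution, scale_clip = scale_clip,
                 seed = as.integer(seed)),
            class = "ClusterParams")
}

#' Library-size normalize and log-transform
#'
#' Scales every cell's counts to a common target depth and applies
#' \code{log(1 + x)}. Zeros are preserved, so detection (count > 0) is
#' identical on the raw and normalized layers. Raw counts are retained.
#'
#' @param dataset An \code{\link{expression_dataset}} (QC applied).
#' @param params A \code{\link{cluster_params}} object (only
#'   \code{target_library_size} is used).
#' @return The dataset with a sparse \code{lognorm} layer added and the
#'   target size recorded as \code{norm_target}.
#' @export
normalize_log <- function(dataset, params = cluster_params()) {
  validate_expression_dataset(dataset)
  libsize <- Matrix::rowSums(dataset$counts)
  if (any(libsize == 0)) {
    stop(sprintf("%d cell(s) have zero total counts; run apply_qc() first",
                 sum(libsize == 0)))
  }
  target <- params$target_library_size
  if (identical(target, "median")) target <- stats::median(libsize)
  scaled <- Matrix::Diagonal(x = target / libsize) %*% dataset$counts
  scaled <- methods::as(scaled, "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(dataset$counts)
  dataset$lognorm <- scaled
  dataset$norm_target <- target
  dataset
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of the log-normalized layer; ties are broken
#' by ascending gene index so the selection is deterministic.
#'
#' @param dataset A dataset with a \code{lognorm} layer.
#' @param n_hvg Number of genes to keep; if it exceeds the gene count, all
#'   genes are returned with a warning.
#' @return Integer vector of gene (column) indices, ordered by decreasing
#'   variance.
#' @export
select_hvg <- function(dataset, n_hvg = 2000) {
  layer <- require_lognorm(dataset)
  n_genes <- ncol(layer)
  if (n_hvg > n_genes) {
    warning(sprintf("n_hvg = %d exceeds %d genes; using all genes",
                    n_hvg, n_genes))
    n_hvg <- n_genes
  }
  v <- sparse_col_vars(layer)
  order(-v, seq_len(n_genes))[seq_len(n_hvg)]
}

require_lognorm <- function(dataset) {
  if (is.null(dataset$lognorm)) {
    stop("dataset has no lognorm layer; run normalize_log() first")
  }
  dataset$lognorm
}

sparse_col_means <- function(m) Matrix::colSums(m) / nrow(m)

sparse_col_vars <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colSums(m) / n
  (Matrix::colSums(m^2) - n * mu^2) / (n - 1)
}

#' PCA embedding of scaled highly variable genes
#'
#' Each selected gene is centred and scaled to unit variance on the
#' log-normalized layer, standardized values are clipped at
#' \code{scale_clip}, and the leading principal components are extracted
#' from the gene-gene covariance eigendecomposition. The sign of every
#' component is fixed so its largest-magnitude gene loading is positive,
#' making the embedding machine-independent.
#'
#' @param dataset A dataset with a \code{lognorm} layer.
#' @param hvg Integer gene indices from \code{\link{select_hvg}}.
#' @param params A \code{\link{cluster_params}} object.
#' @return A cells x \code{n_pcs} matrix with attributes \code{loadings}
#'   (genes x PCs) and \code{var_explained}.
#' @export
embed_pca <- function(dataset, hvg, params = cluster_params()) {
  layer <- require_lognorm(dataset)
  if (nrow(layer) < params$n_pcs) {
    stop(sprintf("n_cells (%d) < n_pcs (%d)", nrow(layer), params$n_pcs))
  }
  x <- as.matrix(layer[, hvg, drop = FALSE])
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- Inf  # constant genes contribute nothing
  x <- scale(x, center = mu, scale = sdev)
  x[x > params$scale_clip] <- params$scale_clip
  x[x < -params$scale_clip] <- -params$scale_clip
  x <- sweep(x, 2, colMeans(x))  # re-centre after clipping

  cv <- crossprod(x) / (nrow(x) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  k <- min(params$n_pcs, ncol(x))
  rot <- eig$vectors[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  emb <- x %*% rot
  colnames(emb) <- sprintf("PC%d", seq_len(k))
  rownames(emb) <- rownames(layer)
  attr(emb, "loadings") <- rot
  attr(emb, "var_explained") <- eig$values[seq_len(k)] / sum(pmax(eig$values, 0))
  emb
}

#' Louvain clustering on a shared-nearest-neighbour graph
#'
#' Builds a k-nearest-neighbour graph in PCA space, weights edges by the
#' Jaccard overlap of the two cells' neighbourhoods (pruning overlaps below
#' 1/15, as is conventional), and partitions it with Louvain community
#' detection at the requested resolution. Deterministic for a fixed
#' \code{params$seed}. Cluster ids are 0-based and ordered by decreasing
#' cluster size.
#'
#' @param embedding Cells x PCs matrix from \code{\link{embed_pca}}.
#' @param params A \code{\link{cluster_params}} object.
#' @return Integer vector of per-cell cluster ids (0-based).
#' @export
cluster_graph <- function(embedding, params = cluster_params()) {
  n <- nrow(embedding)
  k <- params$n_neighbors
  if (k >= n) stop(sprintf("n_neighbors (%d) must be < n_cells (%d)", k, n))

  nn <- knn_indices(embedding, k)
  # SNN: Jaccard similarity of (self-inclusive) neighbourhoods
  nbhd <- cbind(seq_len(n), nn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nbhd)),
                              j = as.vector(nbhd), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(methods::as(shared, "generalMatrix"), "TsparseMatrix")
  keep <- shared@i < shared@j
  i <- shared@i[keep] + 1L
  j <- shared@j[keep] + 1L
  w <- shared@x[keep] / (2 * (k + 1) - shared@x[keep])  # Jaccard
  prune <- w >= 1 / 15
  g <- igraph::graph_from_edgelist(cbind(i[prune], j[prune]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[prune]

  comm <- withr::with_seed(params$seed,
    igraph::cluster_louvain(g, resolution = params$resolution))
  memb <- igraph::membership(comm)
  # stable relabel: 0-based, by decreasing size, ties by first occurrence
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes) - 1L
  as.integer(relabel[memb])
}

# Exact k-nearest neighbours (excluding self) by blockwise distances.
knn_indices <- function(x, k, block = 1024L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Annotate clusters with cell types from marker panels
#'
#' For every cluster, a panel's score is the mean rank-quantile (see
#' \code{\link{rank_ratio}}) of the mean log-normalized expression of the
#' panel's genes among all genes in that cluster. Each cluster is annotated
#' with the highest-scoring panel; exact ties are broken by panel order.
#'
#' @param dataset A dataset with a \code{lognorm} layer.
#' @param clusters Integer per-cell cluster ids from
#'   \code{\link{cluster_graph}}.
#' @param panels A \code{\link{gene_panel}}.
#' @return A list of class \code{ClusterAssignment}: \code{table} (one row
#'   per cluster: \code{cluster}, \code{cell_type}, \code{score},
#'   \code{label} of the form \code{"<cell_type>_<cluster>"}),
#'   \code{cell_type} and \code{cluster_label} (per-cell vectors).
#' @export
annotate_clusters <- function(dataset, clusters, panels) {
  stopifnot(inherits(panels, "GenePanel"))
  layer <- require_lognorm(dataset)
  stopifnot(length(clusters) == nrow(layer))
  symbols <- dataset$gene_meta$symbol
  present <- lapply(panels$panels, function(g) match(g, symbols))
  if (all(is.na(unlist(present)))) {
    stop(sprintf("no panel gene present in the dataset; missing: %s",
                 paste(unique(unlist(panels$panels)), collapse = ", ")))
  }
  ids <- sort(unique(clusters))
  rows <- lapply(ids, function(cl) {
    mu <- sparse_col_means(layer[clusters == cl, , drop = FALSE])
    rq <- rank_ratio(mu)
    scores <- vapply(present, function(ix) mean(rq[ix[!is.na(ix)]]),
                     numeric(1))
    scores[is.nan(scores)] <- -Inf  # panel entirely absent from data
    best <- which.max(scores)  # first maximum = panel order tie-break
    data.frame(cluster = cl, cell_type = names(panels$panels)[best],
               score = scores[best], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$label <- sprintf("%s_%d", tab$cell_type, tab$cluster)
  per_cell <- tab[match(clusters, tab$cluster), ]
  structure(list(table = tab,
                 cell_type = per_cell$cell_type,
                 cluster_label = per_cell$label),
            class = "ClusterAssignment")
}
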