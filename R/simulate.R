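#' Synthetic single-cell simulation parameters
#'
#' Defines a seeded negative-binomial count generator with the structure the
#' downstream analysis assumes: several cell types with planted marker
#' panels, a DAM-like activated subpopulation within the microglia, a target
#' gene ("Piezo1") whose expression is coupled to the DAM marker classes
#' through a shared latent factor at controllable strength, null markers,
#' mitochondrial genes at a controllable expected fraction and log-normal
#' library-size variation.
#'
#' Correlation signs follow the biology being emulated: the target is lower
#' in DAM cells, so up-in-DAM markers correlate negatively with it
#' (default model correlation -0.85) and down-in-DAM markers positively
#' (default +0.8). Setting a correlation to 0 decouples that class (used
#' for null controls).
#'
#' @param n_cells Number of cells.
#' @param n_genes Total number of genes (marker, program, mito and
#'   background genes together).
#' @param cell_type_proportions Named simplex vector of cell-type
#'   proportions; must include \code{"Microglia"}.
#' @param markers_per_type Planted identity-marker genes per cell type.
#' @param dam_fraction_of_microglia Fraction of microglial cells in the
#'   DAM-like activated state.
#' @param up_markers,down_markers Number of up-/down-in-DAM marker genes.
#' @param target_up_corr Model correlation (log-normalized scale, among
#'   microglial cells) between the target and each up-marker, in (-1, 0].
#' @param target_down_corr Ditto for down-markers, in [0, 1).
#' @param n_null_markers Number of uncoupled decoy markers.
#' @param baseline_mean Negative-binomial mean of background genes.
#' @param marker_mean Mean of a cell type's identity markers within that
#'   type (elsewhere they fall back to \code{baseline_mean}).
#' @param program_mean Mean of the target, DAM-marker and null-marker genes
#'   (these emulate well-expressed genes, so presence criteria are
#'   meaningful).
#' @param nb_dispersion Negative-binomial size (shape) parameter; larger
#'   means less overdispersed.
#' @param libsize_sigma SD of the per-cell log-normal library factor.
#' @param dam_shift Shift of the latent DAM activation in activated cells,
#'   in latent-SD units.
#' @param mito_genes Number of mitochondrial genes (\code{mt-} prefixed).
#' @param mito_mean_fraction Expected mitochondrial fraction of a cell's
#'   counts.
#' @param seed Integer seed; the full output is reproducible from it.
#' @return A validated list of class \code{SimParams}.
#' @export
sim_params <- function(n_cells = 3000, n_genes = 1000,
                       cell_type_proportions = c(Microglia = 0.4,
                                                 Astrocyte = 0.3,
                                                 Neuron = 0.3),
                       markers_per_type = 10,
                       dam_fraction_of_microglia = 0.4,
                       up_markers = 7, down_markers = 13,
                       target_up_corr = -0.85, target_down_corr = 0.8,
                       n_null_markers = 50,
                       baseline_mean = 0.3, marker_mean = 8,
                       program_mean = 20, nb_dispersion = 10,
                       libsize_sigma = 0.3, dam_shift = 2,
                       mito_genes = 10, mito_mean_fraction = 0.03,
                       seed = 1L) {
  stopifnot(n_cells >= 1, n_genes >= 1,
            abs(sum(cell_type_proportions) - 1) < 1e-8,
            all(cell_type_proportions > 0),
            "Microglia" %in% names(cell_type_proportions),
            markers_per_type >= 1,
            dam_fraction_of_microglia >= 0, dam_fraction_of_microglia <= 1,
            up_markers >= 0, down_markers >= 0, n_null_markers >= 0,
            target_up_corr <= 0, target_up_corr > -1,
            target_down_corr >= 0, target_down_corr < 1,
            baseline_mean > 0, marker_mean > 0, program_mean > 0,
            nb_dispersion > 0, libsize_sigma >= 0, dam_shift >= 0,
            mito_genes >= 0, mito_mean_fraction >= 0, mito_mean_fraction < 1)
  n_special <- length(cell_type_proportions) * markers_per_type +
    up_markers + down_markers + n_null_markers + mito_genes + 1
  if (n_genes < n_special + 1) {
    stop(sprintf("n_genes must be at least %d for these settings",
                 n_special + 1))
  }
  structure(as.list(environment()), class = "SimParams")
}

# Layout of the synthetic gene set: roles, symbols and per-type base means.
sim_gene_table <- function(params) {
  types <- names(params$cell_type_proportions)
  role <- character(0); symbol <- character(0)
  for (t in types) {
    role <- c(role, rep(paste0("type_marker:", t), params$markers_per_type))
    symbol <- c(symbol, sprintf("%s.marker%d", t, seq_len(params$markers_per_type)))
  }
  role <- c(role,
            "target",
            rep("up_dam", params$up_markers),
            rep("down_dam", params$down_markers),
            rep("null", params$n_null_markers),
            rep("mito", params$mito_genes))
  symbol <- c(symbol,
              "Piezo1",
              sprintf("UpDam%d", seq_len(params$up_markers)),
              sprintf("DownDam%d", seq_len(params$down_markers)),
              sprintf("NullMk%d", seq_len(params$n_null_markers)),
              sprintf("mt-Nd%d", seq_len(params$mito_genes)))
  n_bg <- params$n_genes - length(role)
  role <- c(role, rep("background", n_bg))
  symbol <- c(symbol, sprintf("Bg%d", seq_len(n_bg)))
  data.frame(symbol = symbol, role = role, stringsAsFactors = FALSE)
}

# Monte-Carlo correlation between two latent-coupled genes on the
# log-normalized scale, under the generator's own noise model. Common
# random numbers (fixed local seed) keep the curve smooth in the loadings.
simulated_pair_corr <- function(l1, l2, params, n = 6000, calib_seed) {
  withr::with_seed(calib_seed, {
    p <- params$dam_fraction_of_microglia
    a <- stats::rnorm(n) + params$dam_shift * (stats::runif(n) < p)
    lib <- exp(stats::rnorm(n, 0, params$libsize_sigma))
    c1 <- stats::rnbinom(n, mu = lib * params$program_mean * exp(l1 * a),
                         size = params$nb_dispersion)
    c2 <- stats::rnbinom(n, mu = lib * params$program_mean * exp(l2 * a),
                         size = params$nb_dispersion)
    stats::cor(log1p(c1 / lib), log1p(c2 / lib))
  })
}

#' Calibrate latent-factor loadings for requested correlations
#'
#' The generator couples genes through a shared Gaussian latent factor; the
#' correlation observable on log-normalized counts is attenuated by
#' negative-binomial noise, so loadings cannot be written down in closed
#' form. This routine solves for them numerically: it traces the
#' correlation attainable at equal target/marker loading magnitudes over a
#' loading grid under the generator's own noise model (Monte Carlo with
#' common random numbers), fixes the target loading at the strongest
#' requested class, then solves the weaker class conditionally on it.
#'
#' @param params A \code{\link{sim_params}} object.
#' @return A list with \code{lambda_target}, \code{lambda_up},
#'   \code{lambda_down} (loading magnitudes; signs are applied by the
#'   generator) and \code{max_attainable_r}.
#' @export
calibrate_loadings <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  calib_seed <- (params$seed %% 1000000L) + 500000L
  r_up <- abs(params$target_up_corr)
  r_dn <- abs(params$target_down_corr)
  if (r_up == 0 && r_dn == 0) {
    return(list(lambda_target = 0, lambda_up = 0, lambda_down = 0,
                max_attainable_r = NA_real_))
  }
  grid <- seq(0.05, 4, length.out = 24)
  # symmetric curve: |corr| at equal loading magnitudes (sign-agnostic to
  # first order; the conditional solve below uses the true signs)
  sym <- vapply(grid, function(l) {
    abs(simulated_pair_corr(-l, l, params, calib_seed = calib_seed))
  }, numeric(1))
  sym <- cummax(sym)  # enforce monotonicity against MC jitter
  max_r <- max(sym)
  r_strong <- max(r_up, r_dn)
  if (r_strong > max_r) {
    stop(sprintf(paste0("requested |correlation| %.2f exceeds the maximum ",
                        "attainable %.2f at these noise settings"),
                 r_strong, max_r))
  }
  solve_on <- function(xs, ys, target) {
    if (target <= 0) return(0)
    stats::approx(ys, xs, xout = target, ties = "ordered")$y
  }
  lambda_strong <- solve_on(grid, sym, r_strong)
  strong_is_up <- r_up >= r_dn
  lambda_target <- lambda_strong
  solve_conditional <- function(r_want, marker_sign) {
    if (r_want <= 0) return(0)
    if (abs(r_want - r_strong) < 1e-12) return(lambda_strong)
    cur <- vapply(grid, function(l) {
      abs(simulated_pair_corr(-lambda_target, marker_sign * l, params,
                              calib_seed = calib_seed))
    }, numeric(1))
    cur <- cummax(cur)
    if (r_want > max(cur)) {
      stop(sprintf(paste0("requested |correlation| %.2f exceeds the maximum ",
                          "attainable %.2f given the target loading"),
                   r_want, max(cur)))
    }
    solve_on(grid, cur, r_want)
  }
  lambda_up <- if (strong_is_up) lambda_strong else solve_conditional(r_up, +1)
  lambda_down <- if (!strong_is_up) lambda_strong else solve_conditional(r_dn, -1)
  list(lambda_target = lambda_target, lambda_up = lambda_up,
       lambda_down = lambda_down, max_attainable_r = max_r)
}

#' Simulate a single-cell dataset with planted structure
#'
#' Draws cell types from the configured proportions, gives microglial cells
#' a latent DAM activation (standard normal, shifted by \code{dam_shift} in
#' DAM cells), builds per-gene negative-binomial means as
#' \code{library_factor * base_mean * exp(loading * activation)} and samples
#' counts. The target gene loads negatively on the activation, up-in-DAM
#' markers positively and down-in-DAM markers negatively, with magnitudes
#' calibrated by \code{\link{calibrate_loadings}} so the model correlations
#' with the target equal the requested values. Mitochondrial gene means are
#' set so the expected mitochondrial fraction equals
#' \code{mito_mean_fraction}. Fully reproducible from \code{params$seed}.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param dataset_id Dataset identifier recorded per cell.
#' @param loadings Optional precomputed result of
#'   \code{\link{calibrate_loadings}} (shared across a dataset pair).
#' @return A list with \code{dataset} (an
#'   \code{\link{expression_dataset}}) and \code{truth} (a
#'   \code{SimulationTruth} list: per-cell \code{cell_type} and
#'   \code{is_dam}, per-gene \code{gene_role}, the loadings, requested
#'   correlations and seed).
#' @export
simulate_dataset <- function(params, dataset_id = "sim1", loadings = NULL) {
  stopifnot(inherits(params, "SimParams"))
  if (is.null(loadings)) loadings <- calibrate_loadings(params)
  genes <- sim_gene_table(params)
  types <- names(params$cell_type_proportions)
  n <- params$n_cells
  g <- params$n_genes

  # per-gene loading on the latent DAM activation
  load_vec <- numeric(g)
  load_vec[genes$role == "target"] <- -loadings$lambda_target
  load_vec[genes$role == "up_dam"] <- +loadings$lambda_up
  load_vec[genes$role == "down_dam"] <- -loadings$lambda_down

  # per-type base means (genes x types)
  base <- matrix(params$baseline_mean, g, length(types),
                 dimnames = list(genes$symbol, types))
  for (t in types) {
    base[genes$role == paste0("type_marker:", t), t] <- params$marker_mean
  }
  program <- genes$role %in% c("target", "up_dam", "down_dam", "null")
  base[program, ] <- params$program_mean

  # mito means: match the expected mito fraction per type, accounting for
  # the lognormal latent inflation E[exp(lambda * a)] of program genes
  if (params$mito_genes > 0) {
    p_dam <- params$dam_fraction_of_microglia
    e_load <- function(l, type) {
      infl <- exp(l^2 / 2)
      if (type == "Microglia") {
        infl * ((1 - p_dam) + p_dam * exp(l * params$dam_shift))
      } else infl  # activation is centred outside microglia
    }
    for (t in types) {
      tot <- sum(base[genes$role != "mito", t] *
                   vapply(load_vec[genes$role != "mito"], e_load,
                          numeric(1), type = t))
      f <- params$mito_mean_fraction
      base[genes$role == "mito", t] <- f / (1 - f) * tot / params$mito_genes
    }
  }

  withr::with_seed(params$seed, {
    cell_type <- sample(types, n, replace = TRUE,
                        prob = params$cell_type_proportions)
    is_mg <- cell_type == "Microglia"
    is_dam <- is_mg & stats::runif(n) < params$dam_fraction_of_microglia
    activation <- stats::rnorm(n)
    activation[!is_mg] <- stats::rnorm(sum(!is_mg))  # centred everywhere
    activation[is_dam] <- activation[is_dam] + params$dam_shift
    lib <- exp(stats::rnorm(n, 0, params$libsize_sigma))

    mu <- base[, cell_type, drop = FALSE]            # genes x cells
    mu <- mu * exp(outer(load_vec, activation))
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = params$nb_dispersion),
                     nrow = g)
  })

  ds <- expression_dataset(
    Matrix::t(methods::as(counts, "CsparseMatrix")),
    cell_meta = data.frame(
      barcode = sprintf("%s_cell%05d", dataset_id, seq_len(n)),
      dataset_id = dataset_id, stringsAsFactors = FALSE),
    gene_meta = data.frame(symbol = genes$symbol,
                           is_mito = genes$role == "mito",
                           stringsAsFactors = FALSE),
    dataset_id = dataset_id)
  truth <- structure(list(cell_type = cell_type, is_dam = is_dam,
                          gene_role = genes$role, symbol = genes$symbol,
                          target_gene = "Piezo1",
                          requested = list(up = params$target_up_corr,
                                           down = params$target_down_corr),
                          loadings = loadings, seed = params$seed),
                     class = "SimulationTruth")
  list(dataset = ds, truth = truth)
}

#' Simulate a pair of datasets sharing planted truth
#'
#' Both datasets share gene roles, calibrated loadings and requested
#' correlations but are drawn with independent noise (seeds \code{seed} and
#' \code{seed + 1}), emulating two studies of the same biology.
#'
#' @param params A \code{\link{sim_params}} object.
#' @param dataset_ids Length-2 character vector of dataset identifiers.
#' @return A named list of two \code{simulate_dataset} results.
#' @export
simulate_dataset_pair <- function(params, dataset_ids = c("mouse1", "mouse2")) {
  stopifnot(length(dataset_ids) == 2)
  loadings <- calibrate_loadings(params)
  p2 <- params
  p2$seed <- params$seed + 1L
  out <- list(simulate_dataset(params, dataset_ids[1], loadings),
              simulate_dataset(p2, dataset_ids[2], loadings))
  names(out) <- dataset_ids
  out
}

#' Marker panels of the planted cell types
#'
#' Builds the \code{\link{gene_panel}} a user would supply for annotation,
#' from the generator's planted identity markers.
#'
#' @param truth A \code{SimulationTruth}.
#' @return A \code{GenePanel} with one panel per planted cell type.
#' @export
truth_panels <- function(truth) {
  is_marker <- startsWith(truth$gene_role, "type_marker:")
  type <- sub("^type_marker:", "", truth$gene_role[is_marker])
  gene_panel(split(truth$symbol[is_marker], type))
}

#' Attach planted cluster labels to a simulated dataset
#'
#' Writes truth-derived cluster labels into \code{cell_meta$cluster}
#' (\code{"<type>_0"}; DAM microglia get \code{"Microglia_1"}), so selection
#' stages can be exercised against ground truth without running the
#' clustering stage.
#'
#' @param dataset The simulated \code{ExpressionDataset}.
#' @param truth The matching \code{SimulationTruth}.
#' @return The dataset with cluster labels set.
#' @export
apply_truth_clusters <- function(dataset, truth) {
  stopifnot(nrow(dataset$counts) == length(truth$cell_type))
  lab <- paste0(truth$cell_type, "_0")
  lab[truth$is_dam] <- "Microglia_1"
  dataset$cell_meta$cluster <- lab
  dataset
}

#' Deterministic toy fixtures used across the test-suite
#'
#' Small hand-checkable inputs: a 6-cell x 5-gene QC fixture whose survivor
#' counts are enumerated by hand, a QC boundary fixture probing the exact
#' detected-gene and mitochondrial-fraction thresholds, a 200-cell x 50-gene
#' random count matrix for scoring oracles and a two-blob embedding for
#' graph clustering.
#'
#' @return A named list of fixtures, identical on every call.
#' @export
make_toy_fixtures <- function() {
  # QC fixture: gene g5 detected in 2 cells (c1, c4) -> removed at
  # min_cells_per_gene = 3; with min_genes_per_cell = 3 cells c2 (2 genes
  # detected) and c6 (1) are removed -> survivors 4 cells x 4 genes.
  qc_counts <- matrix(c(
    5, 1, 0, 2, 1,
    3, 0, 1, 0, 0,
    0, 2, 4, 1, 0,
    1, 1, 0, 0, 1,
    2, 0, 3, 1, 0,
    0, 0, 0, 1, 0), nrow = 6, byrow = TRUE,
    dimnames = list(NULL, sprintf("g%d", 1:5)))
  qc <- expression_dataset(qc_counts, dataset_id = "toy_qc")

  # Boundary fixture: 250 genes incl. MT-ND4. Cells (all deep enough):
  #   b1 detects 199 genes, b2 detects 200 (gene-count boundary);
  #   b3 mito fraction exactly 500/10000 = 0.05 (kept);
  #   b4 mito fraction 501/10000 = 0.0501 (removed).
  n_genes <- 250
  symbols <- c("MT-ND4", sprintf("G%03d", seq_len(n_genes - 1)))
  b <- matrix(0L, 4, n_genes, dimnames = list(NULL, symbols))
  b[1, 2:200] <- 1L                      # 199 detected, no mito
  b[2, 2:201] <- 1L                      # 200 detected
  b[3, 1] <- 500L                        # mito 500 / 10000 = 0.0500
  b[3, 2:101] <- 48L; b[3, 102:201] <- 47L   # non-mito 9500
  b[4, 1] <- 501L                        # mito 501 / 10000 = 0.0501
  b[4, 2:100] <- 48L; b[4, 101:201] <- 47L   # non-mito 9499
  # gene-level boundary at min_cells_per_gene = 3: MT-ND4 is detected in 2
  # cells (b3, b4) -> removed; column 201 in 3 cells (b2, b3, b4) -> kept
  qc_boundary <- expression_dataset(b, dataset_id = "toy_boundary")

  # Random score fixture for the brute-force consensus oracle.
  score <- withr::with_seed(424242L, {
    m <- matrix(stats::rpois(200 * 50, lambda = 2), nrow = 200,
                dimnames = list(NULL, sprintf("s%02d", 1:50)))
    expression_dataset(m, dataset_id = "toy_score")
  })
  score_labels <- rep(c("A", "B"), each = 100)

  # Two well-separated Gaussian blobs in 2D, 100 cells each.
  blobs <- withr::with_seed(77L, {
    emb <- rbind(cbind(stats::rnorm(100), stats::rnorm(100)),
                 cbind(stats::rnorm(100) + 12, stats::rnorm(100) + 12))
    rownames(emb) <- sprintf("blob%03d", 1:200)
    emb
  })
  list(qc = qc,
       qc_expected = list(kept_cells = c(1L, 3L, 4L, 5L),
                          kept_genes = c("g1", "g2", "g3", "g4"),
                          min_genes_per_cell = 3, min_cells_per_gene = 3),
       qc_boundary = qc_boundary,
       score = score, score_labels = score_labels,
       blobs = blobs, blob_labels = rep(c(1L, 2L), each = 100))
}
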