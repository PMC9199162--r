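test_that("the generator is exactly reproducible from its seed", {
  p <- sim_params(n_cells = 200, n_genes = 200, n_null_markers = 5, seed = 10L)
  a <- simulate_dataset(p)
  b <- simulate_dataset(p)
  expect_identical(as.matrix(a$dataset$counts), as.matrix(b$dataset$counts))
  expect_identical(a$truth$cell_type, b$truth$cell_type)
  p2 <- p; p2$seed <- 11L
  c_ <- simulate_dataset(p2, loadings = a$truth$loadings)
  expect_false(identical(as.matrix(a$dataset$counts),
                         as.matrix(c_$dataset$counts)))
})

test_that("generator output is a valid container over random parameter draws", {
  for (s in 1:12) {
    p <- withr::with_seed(s, sim_params(
      n_cells = sample(50:200, 1),
      n_genes = sample(150:300, 1),
      cell_type_proportions = local({
        w <- runif(3) + 0.2
        stats::setNames(w / sum(w), c("Microglia", "Astrocyte", "Neuron"))
      }),
      dam_fraction_of_microglia = runif(1, 0.1, 0.6),
      n_null_markers = sample(0:20, 1),
      libsize_sigma = runif(1, 0, 0.5),
      mito_mean_fraction = runif(1, 0, 0.1),
      target_up_corr = -runif(1, 0.3, 0.7),
      target_down_corr = runif(1, 0.3, 0.7),
      seed = s))
    sim <- simulate_dataset(p)
    expect_silent(validate_expression_dataset(sim$dataset))
    expect_equal(length(sim$truth$cell_type), p$n_cells)
    expect_equal(length(sim$truth$gene_role), p$n_genes)
    # roles partition the gene set
    expect_equal(sum(table(sim$truth$gene_role)), p$n_genes)
  }
})

test_that("planted cell-type counts follow the configured proportions", {
  p <- sim_params(n_cells = 2000, n_genes = 200, n_null_markers = 5,
                  cell_type_proportions = c(Microglia = 0.5, Astrocyte = 0.25,
                                            Neuron = 0.25),
                  target_up_corr = 0, target_down_corr = 0, seed = 19L)
  sim <- simulate_dataset(p)
  n_mg <- sum(sim$truth$cell_type == "Microglia")
  # within 3 binomial standard deviations of expectation
  expect_lt(abs(n_mg - 1000), 3 * sqrt(2000 * 0.5 * 0.5))
})

test_that("empirical correlations match the requested model values", {
  p <- sim_params(seed = 55L)  # defaults: 3000 cells, -0.85 / +0.8
  sim <- simulate_dataset(p)
  ds <- normalize_log(apply_truth_clusters(sim$dataset, sim$truth))
  sub <- c("Microglia_0", "Microglia_1")
  up <- sim$truth$symbol[sim$truth$gene_role == "up_dam"]
  dn <- sim$truth$symbol[sim$truth$gene_role == "down_dam"]
  r_up <- marker_target_correlation(ds, sub, "Piezo1", up)
  r_dn <- marker_target_correlation(ds, sub, "Piezo1", dn)
  expect_true(all(abs(r_up - (-0.85)) <= 0.10))
  expect_true(all(abs(r_dn - 0.8) <= 0.10))
})

test_that("correlation calibration bias is small at large n", {
  p <- sim_params(n_cells = 10000, seed = 77L)  # default gene complement
  sim <- simulate_dataset(p)
  ds <- normalize_log(apply_truth_clusters(sim$dataset, sim$truth))
  sub <- c("Microglia_0", "Microglia_1")
  up <- sim$truth$symbol[sim$truth$gene_role == "up_dam"]
  dn <- sim$truth$symbol[sim$truth$gene_role == "down_dam"]
  bias_up <- mean(marker_target_correlation(ds, sub, "Piezo1", up)) - (-0.85)
  bias_dn <- mean(marker_target_correlation(ds, sub, "Piezo1", dn)) - 0.8
  expect_lt(abs(bias_up), 0.05)
  expect_lt(abs(bias_dn), 0.05)
})

test_that("mitochondrial fraction tracks its requested mean", {
  p <- sim_params(n_cells = 1500, n_genes = 300, n_null_markers = 10,
                  mito_mean_fraction = 0.04, seed = 23L)
  sim <- simulate_dataset(p)
  frac <- Matrix::rowSums(sim$dataset$counts[, sim$dataset$gene_meta$is_mito]) /
    Matrix::rowSums(sim$dataset$counts)
  expect_lt(abs(mean(frac) - 0.04), 0.01)
})

test_that("unsatisfiable correlation requests error with the attainable bound", {
  p <- sim_params(n_cells = 100, n_genes = 200, program_mean = 0.5,
                  nb_dispersion = 0.2, target_up_corr = -0.95, seed = 3L)
  expect_error(calibrate_loadings(p), "maximum attainable")
})

test_that("a dataset pair shares truth but not noise", {
  p <- sim_params(n_cells = 300, n_genes = 200, n_null_markers = 5, seed = 9L)
  pair <- simulate_dataset_pair(p)
  expect_identical(pair[[1]]$truth$gene_role, pair[[2]]$truth$gene_role)
  expect_identical(pair[[1]]$truth$loadings, pair[[2]]$truth$loadings)
  expect_false(identical(as.matrix(pair[[1]]$dataset$counts),
                         as.matrix(pair[[2]]$dataset$counts)))
  expect_equal(pair[[1]]$dataset$cell_meta$dataset_id[1], "mouse1")
  expect_equal(pair[[2]]$dataset$cell_meta$dataset_id[1], "mouse2")
})

test_that("toy fixtures are stable across calls", {
  a <- make_toy_fixtures()
  b <- make_toy_fixtures()
  expect_identical(hash_object(a), hash_object(b))
})
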