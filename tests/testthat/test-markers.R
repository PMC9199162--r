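make_marker_toy <- function() {
  # 6 cells in subcluster "MG_0", 2 elsewhere; target in column 1. All MG
  # rows sum to 12 (filler gene), and target/same/anti take only two
  # distinct values, so after depth normalization to 12 the log layer is
  # exactly two-point: 'same' is identical to the target (r = 1) and
  # 'anti' exactly affine-decreasing in it (r = -1).
  m <- rbind(
    c(3L, 3L, 1L, 1L, 2L, 2L),
    c(3L, 3L, 1L, 1L, 2L, 2L),
    c(3L, 3L, 1L, 0L, 2L, 3L),
    c(0L, 0L, 4L, 0L, 2L, 6L),
    c(0L, 0L, 4L, 0L, 2L, 6L),
    c(0L, 0L, 4L, 0L, 2L, 6L),
    c(9L, 0L, 0L, 9L, 2L, 1L),
    c(9L, 0L, 0L, 9L, 2L, 1L))
  colnames(m) <- c("Piezo1", "same", "anti", "rare", "flat", "filler")
  ds <- expression_dataset(m)
  ds$cell_meta$cluster <- c(rep("MG_0", 6), rep("Other_0", 2))
  normalize_log(ds, cluster_params(target_library_size = 12))
}

test_that("correlations hit the exact limits for identical and affine markers", {
  ds <- make_marker_toy()
  r <- marker_target_correlation(ds, "MG_0", "Piezo1",
                                 c("same", "anti", "flat"))
  expect_equal(unname(r["same"]), 1)
  expect_equal(unname(r["anti"]), -1, tolerance = 1e-12)
  expect_true(is.na(r["flat"]))
  expect_error(marker_target_correlation(ds, "MG_0", "absent", "same"),
               "absent")
})

test_that("presence is the detected fraction among target-positive cells", {
  ds <- make_marker_toy()
  # 3 target-positive cells in MG_0; 'rare' detected in 2 of them
  expect_equal(target_positive_presence(ds, "MG_0", "Piezo1", "rare"), 2 / 3)
  expect_equal(target_positive_presence(ds, "MG_0", "Piezo1", "flat"), 1)
  expect_equal(target_positive_presence(ds, "MG_0", "Piezo1", "missing"),
               NA_real_)
})

test_that("selection applies inclusive class-dependent bounds and intersects datasets", {
  mk <- marker_set(up_markers = c("u1", "u2"), down_markers = "d1")
  params <- correlation_filter_params(select_cell_type = "MG")
  stats1 <- data.frame(dataset_id = "a", subcluster_group = "MG_0",
                       marker = c("u1", "u2", "d1"),
                       class = c("up", "up", "down"),
                       r = c(-0.70, -0.69, 0.70),
                       presence = c(0.70, 0.95, 0.70),
                       reason = "", stringsAsFactors = FALSE)
  stats2 <- stats1
  stats2$dataset_id <- "b"
  sel <- select_markers(list(stats1, stats2), mk, params)
  # exact boundary -0.70 / 0.70 presence 0.70 -> kept; r = -0.69 -> dropped
  expect_equal(sel$final$final_kept, c(TRUE, FALSE, TRUE))

  # failing one dataset drops the marker under require_all_datasets
  stats2$r[1] <- -0.5
  sel2 <- select_markers(list(stats1, stats2), mk, params)
  expect_false(sel2$final$final_kept[1])

  # relaxing thresholds never shrinks the kept set (monotonicity)
  loose <- correlation_filter_params(select_cell_type = "MG",
                                     corr_threshold = 0.4,
                                     presence_threshold = 0.4)
  sel3 <- select_markers(list(stats1, stats2), mk, loose)
  expect_true(all(sel3$final$final_kept >= sel2$final$final_kept))
})

test_that("evaluated statistics flag absent and constant markers with reasons", {
  ds <- make_marker_toy()
  mk <- marker_set(up_markers = c("anti", "ghost"),
                   down_markers = c("same", "flat"))
  params <- correlation_filter_params(
    subclusters_per_dataset = list(dataset1 = "MG_0"))
  st <- evaluate_marker_stats(ds, mk, params)
  expect_equal(st$reason[st$marker == "ghost"], "absent")
  expect_equal(st$reason[st$marker == "flat"], "constant expression")
  sel <- select_markers(list(st), mk, params)
  expect_equal(sel$final$final_kept[sel$final$marker %in% c("anti", "same")],
               c(TRUE, TRUE))
  expect_false(any(sel$final$final_kept[sel$final$marker %in%
                                          c("ghost", "flat")]))
})

test_that("kept set is invariant to cell and marker ordering", {
  sim <- small_sim(seed = 14L)
  ds <- sim$dataset
  mk <- marker_set(sim$truth$symbol[sim$truth$gene_role == "up_dam"],
                   sim$truth$symbol[sim$truth$gene_role == "down_dam"])
  params <- correlation_filter_params(select_cell_type = "Microglia")
  sel <- select_markers(list(evaluate_marker_stats(ds, mk, params)),
                        mk, params)
  perm <- withr::with_seed(2L, sample(nrow(ds$counts)))
  ds_p <- subset_cells(ds, cells = perm)
  mk_r <- marker_set(rev(mk$up_markers), rev(mk$down_markers))
  sel_p <- select_markers(list(evaluate_marker_stats(ds_p, mk_r, params)),
                          mk_r, params)
  expect_equal(sort(sel$final$marker[sel$final$final_kept]),
               sort(sel_p$final$marker[sel_p$final$final_kept]))
})

test_that("generator-planted correlations are recovered within sampling error", {
  p <- sim_params(seed = 33L)
  sim <- simulate_dataset(p)
  ds <- normalize_log(apply_truth_clusters(sim$dataset, sim$truth))
  sub <- c("Microglia_0", "Microglia_1")
  up <- sim$truth$symbol[sim$truth$gene_role == "up_dam"]
  r <- marker_target_correlation(ds, sub, "Piezo1", up)
  expect_true(all(r >= -0.95 & r <= -0.75))
})
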