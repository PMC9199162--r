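test_that("sparse triplet reader transcribes counts and orientation", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 3", "1 1 5", "2 2 3", "1 3 1"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("AAAC", "TTTG", "GGGA"), file.path(dir, "barcodes.tsv"))
  writeLines(c("id1\tMT-ND4", "id2\tACTB"), file.path(dir, "features.tsv"))
  ds <- read_sparse_triplet(file.path(dir, "matrix.mtx"),
                            file.path(dir, "barcodes.tsv"),
                            file.path(dir, "features.tsv"))
  # on-disk genes x cells -> in-memory cells x genes
  expect_equal(dim(ds$counts), c(3L, 2L))
  expect_equal(as.numeric(Matrix::rowSums(ds$counts)), c(5, 3, 1))
  expect_equal(ds$gene_meta$symbol, c("MT-ND4", "ACTB"))
  expect_equal(ds$gene_meta$is_mito, c(TRUE, FALSE))
})

test_that("sparse reader errors name the offending sidecar file", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 1", "1 1 5"), file.path(dir, "matrix.mtx"))
  writeLines(c("AAAC", "TTTG"), file.path(dir, "barcodes.tsv"))
  writeLines(c("g1", "g2"), file.path(dir, "features.tsv"))
  expect_error(read_sparse_triplet(file.path(dir, "matrix.mtx"),
                                   file.path(dir, "barcodes.tsv"),
                                   file.path(dir, "features.tsv")),
               "barcodes")
})

test_that("an empty declared matrix loads as zeros without error", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "2 2 0"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("g1", "g2"), file.path(dir, "features.tsv"))
  ds <- read_sparse_triplet(file.path(dir, "matrix.mtx"),
                            file.path(dir, "barcodes.tsv"),
                            file.path(dir, "features.tsv"))
  expect_equal(sum(ds$counts), 0)
  expect_equal(dim(ds$counts), c(2L, 2L))
})

test_that("dense reader honours orientation and rejects bad cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tg1\tg2", "c1\t1\t0", "c2\t0\t2"), f)
  ds <- read_dense_table(f, orientation = "cells_rows")
  expect_equal(as.matrix(ds$counts),
               matrix(c(1, 0, 0, 2), 2, dimnames = list(c("c1", "c2"),
                                                        c("g1", "g2"))))
  ds_t <- read_dense_table(f, orientation = "genes_rows")
  expect_equal(unname(as.matrix(ds_t$counts)),
               unname(t(as.matrix(ds$counts))))
  expect_equal(ds_t$gene_meta$symbol, c("c1", "c2"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tg1\tg2", "c1\t1\tNA", "c2\t0\t2"), f2)
  expect_error(read_dense_table(f2), "c1.*g2")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tg1\tg2", "c1\t1", "c2\t0\t2"), f3)
  expect_error(read_dense_table(f3), "row 2")
})

test_that("write-then-read round-trips a dataset bit-exactly, sparse and dense", {
  sim <- simulate_dataset(sim_params(n_cells = 40, n_genes = 120, seed = 5L,
                                     target_up_corr = 0, target_down_corr = 0))
  ds <- sim$dataset
  dir <- withr::local_tempdir()
  write_sparse_triplet(ds, dir)
  back <- read_sparse_triplet(file.path(dir, "matrix.mtx"),
                              file.path(dir, "barcodes.tsv"),
                              file.path(dir, "features.tsv"),
                              dataset_id = ds$cell_meta$dataset_id[1])
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts))
  expect_equal(back$cell_meta$barcode, ds$cell_meta$barcode)
  expect_equal(back$gene_meta$symbol, ds$gene_meta$symbol)
  expect_equal(back$gene_meta$is_mito, ds$gene_meta$is_mito)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_dense_table(ds, f)
  dense <- read_dense_table(f, orientation = "cells_rows",
                            dataset_id = ds$cell_meta$dataset_id[1])
  expect_equal(unname(as.matrix(dense$counts)), unname(as.matrix(ds$counts)))
  expect_equal(dense$gene_meta$is_mito, ds$gene_meta$is_mito)
})

test_that("container invariants are enforced", {
  m <- matrix(1:4, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_error(expression_dataset(m - 2), "non-negative")
  expect_error(expression_dataset(m / 3), "integral")
  expect_error(expression_dataset(
    m, cell_meta = data.frame(barcode = c("a", "a"))), "unique")
  expect_error(expression_dataset(
    m, gene_meta = data.frame(symbol = c("g", "g"))), "unique")
})

test_that("gene panels parse, deduplicate, and preserve order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_type\tgene_symbol", "MG\tCd9", "MG\tCtsb",
               "MG\tCd9", "AST\tGfap"), f)
  gp <- read_gene_panels(f)
  expect_equal(gp$panels$MG, c("Cd9", "Ctsb"))
  expect_equal(names(gp$panels), c("MG", "AST"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cell_type\tgene_symbol", f2)
  expect_error(read_gene_panels(f2), "zero rows")
  expect_error(gene_panel(list(MG = character(0))), "empty panel")
})
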