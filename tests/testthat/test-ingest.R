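test_that("MTX round trip through write_fixture and read_10x preserves counts", {
  sce <- tiny_sce()
  dir <- withr::local_tempdir()
  write_fixture(sce, dir)
  back <- suppressMessages(read_10x(dir, file.path(dir, "meta.csv")))
  expect_identical(dim(back), c(3L, 4L))
  expect_equal(as.matrix(SummarizedExperiment::assay(back, "counts")),
               as.matrix(tiny_counts()))
  expect_equal(rownames(back), rownames(sce))

  # gzip dialect reads identically
  dir_gz <- withr::local_tempdir()
  write_fixture(sce, dir_gz, gzip = TRUE)
  back_gz <- suppressMessages(read_10x(dir_gz, file.path(dir_gz, "meta.csv")))
  expect_equal(as.matrix(SummarizedExperiment::assay(back_gz, "counts")),
               as.matrix(SummarizedExperiment::assay(back, "counts")))
})

test_that("cells without metadata are dropped and missing files are fatal", {
  sce <- tiny_sce()
  dir <- withr::local_tempdir()
  write_fixture(sce, dir)
  meta3 <- tiny_meta()[1:3, ]
  write.csv(meta3, file.path(dir, "meta3.csv"), row.names = FALSE)
  back <- suppressMessages(read_10x(dir, file.path(dir, "meta3.csv")))
  expect_identical(ncol(back), 3L)
  expect_error(read_10x(withr::local_tempdir(), file.path(dir, "meta.csv")),
               "missing file")
})

test_that("duplicate barcodes are fatal and duplicate symbols get suffixed", {
  dir <- withr::local_tempdir()
  write_fixture(tiny_sce(), dir)
  writeLines(c("cell1", "cell1", "cell3", "cell4"),
             file.path(dir, "barcodes.tsv"))
  expect_error(suppressMessages(read_10x(dir, file.path(dir, "meta.csv"))),
               "duplicate")
  writeLines(c("cell1", "cell2", "cell3", "cell4"),
             file.path(dir, "barcodes.tsv"))
  write.table(data.frame(id = c("g", "g", "MT1"), sym = c("g", "g", "MT1")),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  back <- suppressMessages(read_10x(dir, file.path(dir, "meta.csv")))
  expect_false(anyDuplicated(rownames(back)) > 0)
})

test_that("QC bounds are strict: boundary cells are removed", {
  # cell1: nFeature exactly 200; cell2: pct_mt exactly 12.5; cell3 passes
  n_genes <- 300
  counts <- matrix(0, n_genes, 3)
  counts[1:200, 1] <- 2                       # nFeature = 200 -> removed
  counts[1:300, 2] <- 2; counts[1, 2] <- 77   # 600 total, mito 75+2=...
  # make cell2 mito fraction exactly 12.5%: total 600 -> mito 75
  counts[, 2] <- 0; counts[2:281, 2] <- 1; counts[1, 2] <- 40
  # cell2: total = 320, mito = 40 -> 12.5%
  counts[1:250, 3] <- 2; counts[1, 3] <- 1    # passes everything
  rownames(counts) <- c("MT1", paste0("g", seq_len(n_genes - 1)))
  colnames(counts) <- paste0("c", 1:3)
  sce <- make_count_matrix(counts, tiny_meta(paste0("c", 1:3)))
  t_tumor <- qc_thresholds("tumor")
  kept <- suppressMessages(apply_qc(sce, t_tumor, mito_genes = "MT1"))
  expect_identical(colnames(kept), "c3")

  # vacuous thresholds return the input unchanged
  t_open <- qc_thresholds(min_features = 0, max_features = Inf,
                          max_pct_mt = 100, min_counts = 0, max_counts = Inf)
  expect_identical(ncol(apply_qc(sce, t_open)), 3L)

  # all-removed is fatal with an attrition report
  t_harsh <- qc_thresholds(min_features = 1e5, max_features = 1e6,
                           max_pct_mt = 100, min_counts = 0, max_counts = Inf)
  expect_error(suppressMessages(apply_qc(sce, t_harsh)), "attrition|removed")
})

test_that("apply_qc is idempotent and removals are the union over criteria", {
  sim <- small_sim()
  m <- sim$matrix
  t <- qc_thresholds(min_features = 30, max_features = 5000,
                     max_pct_mt = 100, min_counts = 900, max_counts = 1e9)
  once <- suppressMessages(apply_qc(m, t))
  twice <- suppressMessages(apply_qc(once, t))
  expect_identical(colnames(twice), colnames(once))

  # per-criterion removal sets union up to the joint removal
  only_feat <- qc_thresholds(min_features = 30, max_features = 5000,
                             max_pct_mt = 100, min_counts = 0, max_counts = 1e9)
  only_cnt <- qc_thresholds(min_features = 0, max_features = 1e9,
                            max_pct_mt = 100, min_counts = 900, max_counts = 1e9)
  rm_feat <- setdiff(colnames(m), colnames(suppressMessages(apply_qc(m, only_feat))))
  rm_cnt <- setdiff(colnames(m), colnames(suppressMessages(apply_qc(m, only_cnt))))
  rm_joint <- setdiff(colnames(m), colnames(once))
  expect_setequal(rm_joint, union(rm_feat, rm_cnt))
})

test_that("log-normalization has the closed form and its invariances", {
  counts <- matrix(0, 3, 2)
  counts[1, 1] <- 1; counts[2, 1] <- 9999      # cell1 total = 10000
  counts[1, 2] <- 10; counts[2, 2] <- 10
  rownames(counts) <- paste0("g", 1:3); colnames(counts) <- c("c1", "c2")
  sce <- make_count_matrix(counts, tiny_meta(c("c1", "c2")))
  nm <- normalize_counts(sce, scale_factor = 10000)
  v <- SummarizedExperiment::assay(nm, "logcounts")
  expect_equal(v[1, 1], log(2))            # count 1 in a 10000-total cell
  expect_identical(v[3, 1], 0)             # zero count stays exactly zero
  expect_true(all((as.matrix(v) == 0) == (counts == 0)))

  # doubling all counts of a cell leaves its normalized values unchanged
  counts2 <- counts; counts2[, 2] <- counts2[, 2] * 2
  sce2 <- make_count_matrix(counts2, tiny_meta(c("c1", "c2")))
  v2 <- SummarizedExperiment::assay(normalize_counts(sce2), "logcounts")
  expect_equal(as.numeric(v2[, 2]),
               as.numeric(SummarizedExperiment::assay(
                 normalize_counts(sce), "logcounts")[, 2]))

  # zero-total cell is fatal
  counts3 <- counts; counts3[, 2] <- 0
  sce3 <- make_count_matrix(counts3, tiny_meta(c("c1", "c2")))
  expect_error(normalize_counts(sce3), "apply_qc")
})

test_that("balanced down-sampling equalizes groups reproducibly", {
  sim <- small_sim()
  m <- sim$matrix
  tab <- table(SummarizedExperiment::colData(m)$tissue)
  d1 <- downsample_balanced(m, "tissue", seed = 5)
  expect_true(all(table(SummarizedExperiment::colData(d1)$tissue) == min(tab)))
  d2 <- downsample_balanced(m, "tissue", seed = 5)
  expect_identical(colnames(d1), colnames(d2))
  d3 <- downsample_balanced(m, "tissue", seed = 6)
  expect_false(identical(colnames(d1), colnames(d3)))
})
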