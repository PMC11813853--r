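test_that("pseudobulk aggregation sums counts exactly and conserves totals", {
  sce <- tiny_sce()
  pb <- aggregate_pseudobulk(sce, c("sample_id", "tissue"))
  counts <- SummarizedExperiment::assay(pb, "counts")
  raw <- as.matrix(tiny_counts())
  # cells 1,3 -> s1.blood; cells 2,4 -> s2.tumor
  expect_equal(unname(counts[, "s1.blood"]), unname(raw[, 1] + raw[, 3]))
  expect_equal(sum(counts), sum(raw))
  expect_identical(SummarizedExperiment::colData(pb)$n_cells, c(2L, 2L))

  # grouping by barcode reproduces the single-cell layout
  pb_id <- aggregate_pseudobulk(sce, "barcode")
  expect_equal(unname(as.matrix(SummarizedExperiment::assay(pb_id, "counts"))),
               unname(raw))
  expect_error(aggregate_pseudobulk(sce, "no_such_field"), "absent")
})

test_that("low-abundance filter flips at exactly 10 cells with count > 1", {
  n_cells <- 1200
  counts <- matrix(0, 3, n_cells)
  counts[1, 1:9] <- 2        # 9 cells with count > 1 -> removed
  counts[2, 1:10] <- 2       # 10 cells -> retained
  counts[3, 1:1000] <- 1     # many cells but never exceeding 1 -> removed
  rownames(counts) <- c("g9", "g10", "gOnes")
  colnames(counts) <- paste0("c", seq_len(n_cells))
  sce <- make_count_matrix(counts, tiny_meta(paste0("c", seq_len(n_cells))))
  kept <- filter_low_abundance(sce, de_config())
  expect_identical(kept, "g10")
})

test_that("median-of-ratios size factors match hand computation", {
  # proportional columns: factors in the column ratio
  pb <- matrix(c(10, 20, 20, 40), nrow = 2)  # genes x units, unit2 = 2*unit1
  colnames(pb) <- c("u1", "u2"); rownames(pb) <- c("g1", "g2")
  sf <- estimate_size_factors(pb)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # single unit
  expect_equal(unname(estimate_size_factors(pb[, 1, drop = FALSE])), 1)
  # no common nonzero gene is fatal
  bad <- matrix(c(5, 0, 0, 5), nrow = 2,
                dimnames = list(c("g1", "g2"), c("u1", "u2")))
  expect_error(estimate_size_factors(bad), "nonzero")
})

test_that("dispersion estimation recovers the generator and floors degenerates", {
  sp <- simulate_pseudobulk(600, n_blood = 4, n_tumor = 4, dispersion = 0.4,
                            lfc = 0, seed = 2)
  tis <- SummarizedExperiment::colData(sp$pb)$tissue
  d <- estimate_dispersion(sp$pb, tis)
  expect_gt(median(d), 0.25)
  expect_lt(median(d), 0.6)

  sp0 <- simulate_pseudobulk(600, n_blood = 4, n_tumor = 4, dispersion = 0,
                             lfc = 0, seed = 2)
  d0 <- estimate_dispersion(sp0$pb, SummarizedExperiment::colData(sp0$pb)$tissue)
  expect_lt(median(d0), 0.01)

  # identical counts in all units -> floored at 1e-8
  pb <- matrix(7, 12, 6)
  set.seed(1)
  pb[1:11, ] <- matrix(rpois(66, 50), 11)   # context so the trend can fit
  pb[12, ] <- 7
  rownames(pb) <- paste0("g", 1:12); colnames(pb) <- paste0("u", 1:6)
  dd <- estimate_dispersion(pb, rep(c("a", "b"), each = 3))
  expect_equal(unname(dd[12]), 1e-8)

  expect_error(estimate_dispersion(pb, c("a", rep("b", 5))), "replicate")
})

test_that("threshold Wald statistic and p-value follow the closed form", {
  # boundary estimate: W = 0, p = 1 exactly
  b <- wald_threshold_test(0.58, se = 0.3, theta = 0.58)
  expect_identical(b$wald_stat, 0)
  expect_identical(b$p, 1)
  # one unit beyond the null at se 0.5: W = 2, p = 2(1 - Phi(2))
  t1 <- wald_threshold_test(1.58, 0.5, 0.58)
  expect_equal(t1$wald_stat, 2)
  expect_equal(t1$p, 2 * pnorm(2, lower.tail = FALSE))
  # symmetric in the sign of the estimate
  t2 <- wald_threshold_test(-1.58, 0.5, 0.58)
  expect_equal(t2$p, t1$p)
  # theta = 0 reduces to the ordinary two-sided Wald test
  t0 <- wald_threshold_test(0.7, 0.35, 0)
  expect_equal(t0$p, 2 * pnorm(2, lower.tail = FALSE))
  expect_error(wald_threshold_test(1, se = 0), "positive")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 4)), rep(1, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_true(all(adjust_bh(p) >= p))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_de removes excluded genes and respects the replicate contract", {
  sim <- small_sim()
  m <- sim$matrix
  cd <- SummarizedExperiment::colData(m)
  bcs <- rownames(cd)[cd$cell_type == "CD4_T"]
  excl <- rownames(m)[1:5]
  res <- run_de(m, cell_subset = bcs, exclude = excl)
  expect_false(any(excl %in% res$gene))
  expect_true(all(res$padj >= res$p - 1e-12))
  expect_identical(res$significant, res$padj < 0.01)
  expect_true(all(res$wald_stat >= 0))
  expect_true(all(res$p[res$wald_stat == 0] == 1))
  # fewer than 2 samples per tissue is fatal
  one_blood <- rownames(cd)[cd$sample_id %in%
    c("canine_blood_s01", "canine_tumor_s01", "canine_tumor_s02")]
  expect_error(run_de(m, cell_subset = one_blood), ">= 2 samples")
})

test_that("relabeling tissues flips every log2 fold change", {
  sp <- simulate_pseudobulk(150, n_blood = 4, n_tumor = 4, dispersion = 0.1,
                            lfc = rep(c(0, 1.5), 75), seed = 31)
  res <- de_test_pseudobulk(sp$pb)
  flipped <- sp$pb
  SummarizedExperiment::colData(flipped)$tissue <-
    ifelse(SummarizedExperiment::colData(sp$pb)$tissue == "blood",
           "tumor", "blood")
  res_f <- de_test_pseudobulk(flipped)
  expect_equal(res_f$log2fc, -res$log2fc, tolerance = 1e-6)
  expect_equal(res_f$p, res$p, tolerance = 1e-6)
})

test_that("scaling one unit moves its size factor, not the calls", {
  sp <- simulate_pseudobulk(400, n_blood = 5, n_tumor = 5, dispersion = 0.05,
                            lfc = rep(c(0, 2), 200), base_mean_meanlog = log(400),
                            seed = 17)
  res <- de_test_pseudobulk(sp$pb)
  scaled <- sp$pb
  counts <- SummarizedExperiment::assay(scaled, "counts")
  counts[, 1] <- counts[, 1] * 3L
  SummarizedExperiment::assay(scaled, "counts") <- counts
  # relative to the other units, unit 1's factor grows by exactly 3
  sf_new <- estimate_size_factors(counts)
  sf_old <- estimate_size_factors(SummarizedExperiment::assay(sp$pb, "counts"))
  expect_equal(unname((sf_new[1] / sf_new[2]) / (sf_old[1] / sf_old[2])), 3,
               tolerance = 0.02)
  res_s <- de_test_pseudobulk(scaled)
  hi <- res$base_mean > 50
  expect_gt(mean(res_s$significant[hi] == res$significant[hi]), 0.95)
})
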