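# A dense normalized matrix with controllable structure: `bump` adds
# expression of the first `n_marker` genes in cluster "A" cells.
make_norm_fixture <- function(n_genes = 60, n_cells = 120, bump = 0,
                              n_marker = 3, seed = 99) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells,
                         lambda = rep(exp(rnorm(n_genes, 1, 0.8)), n_cells)),
                   n_genes, n_cells)
  clusters <- rep(c("A", "B"), length.out = n_cells)
  if (bump > 0) {
    counts[seq_len(n_marker), clusters == "A"] <-
      counts[seq_len(n_marker), clusters == "A"] + rpois(
        n_marker * sum(clusters == "A"), bump)
  }
  rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
  colnames(counts) <- sprintf("c%03d", seq_len(n_cells))
  meta <- data.frame(barcode = colnames(counts),
                     sample_id = rep(c("s1", "s2", "s3", "s4"),
                                     length.out = n_cells),
                     tissue = rep(c("blood", "tumor"), length.out = n_cells),
                     cell_type = clusters, stringsAsFactors = FALSE)
  normalize_counts(make_count_matrix(counts, meta))
}

test_that("module score of a self-controlled set is near zero and linear", {
  nm <- make_norm_fixture(n_genes = 120, n_cells = 400)
  all_genes <- rownames(nm)
  ms <- module_score(nm, all_genes, seed = 4)
  expect_lt(abs(mean(ms$score)), 0.01)

  # adding c to the signature genes of one cell raises its score by c
  gs <- all_genes[1:10]
  base <- module_score(nm, gs, seed = 4)
  bumped <- nm
  lc <- SummarizedExperiment::assay(bumped, "logcounts")
  lc <- as.matrix(lc); lc[gs, 1] <- lc[gs, 1] + 0.7
  SummarizedExperiment::assay(bumped, "logcounts") <- Matrix::Matrix(lc, sparse = TRUE)
  after <- module_score(bumped, gs, seed = 4)
  expect_equal(unname(after$score[1] - base$score[1]), 0.7, tolerance = 1e-9)
  expect_equal(unname(after$score[2]), unname(base$score[2]), tolerance = 1e-12)

  # determinism and missing-gene handling
  expect_identical(module_score(nm, gs, seed = 4)$score, base$score)
  expect_warning(ms2 <- module_score(nm, c(gs, "nope"), seed = 4), "absent")
  expect_identical(ms2$score, base$score)
  expect_error(module_score(nm, "nope"), "no signature gene")
})

test_that("disjoint random gene sets score exchangeably around zero", {
  nm <- make_norm_fixture(n_genes = 150, n_cells = 300)
  set.seed(7)
  pools <- split(sample(rownames(nm), 60), rep(1:3, each = 20))
  means <- vapply(pools, function(gs) {
    mean(module_score(nm, gs, seed = 11)$score)
  }, numeric(1))
  expect_lt(max(abs(means)), 0.15)
})

test_that("find_markers matches a brute-force Wilcoxon sweep and finds planted markers", {
  nm <- make_norm_fixture(n_genes = 50, n_cells = 80, bump = 6)
  mk <- find_markers(nm, "cell_type", min_pct = 0, min_lfc = 0)
  # planted markers top-ranked for cluster A
  top_a <- mk$gene[mk$cluster == "A"][1:3]
  expect_setequal(top_a, c("g001", "g002", "g003"))

  # brute force over all genes, cluster A vs rest
  expr <- as.matrix(SummarizedExperiment::assay(nm, "logcounts"))
  cl <- SummarizedExperiment::colData(nm)$cell_type
  for (g in mk$gene[mk$cluster == "A"]) {
    p_ref <- suppressWarnings(
      wilcox.test(expr[g, cl == "A"], expr[g, cl != "A"])$p.value)
    expect_equal(mk$p[mk$cluster == "A" & mk$gene == g], p_ref)
  }
  # only positive-lfc rows are retained
  expect_true(all(mk$log2fc >= 0))
  expect_error(find_markers(nm, rep("A", ncol(nm))), ">= 2 clusters")
})

test_that("permuting cluster labels destroys planted marker calls", {
  nm <- make_norm_fixture(n_genes = 50, n_cells = 80, bump = 6)
  set.seed(3)
  perm <- sample(SummarizedExperiment::colData(nm)$cell_type)
  mk_perm <- find_markers(nm, perm, min_pct = 0, min_lfc = 0)
  expect_lt(sum(mk_perm$padj < 0.05), 0.05 * 50 * 2 + 3)
})

test_that("positive fractions count raw-positive cells, scale-free", {
  counts <- matrix(0, 2, 7)
  counts[1, c(1, 3, 5)] <- c(2, 1, 7)
  counts[2, ] <- 1
  rownames(counts) <- c("gX", "gY"); colnames(counts) <- paste0("c", 1:7)
  meta <- data.frame(barcode = colnames(counts), sample_id = "s1",
                     tissue = c(rep("blood", 4), rep("tumor", 3)),
                     cell_type = "T", stringsAsFactors = FALSE)
  nm <- normalize_counts(make_count_matrix(counts, meta))
  pf <- positive_fraction(nm, "gX", "tissue")
  expect_equal(pf$n_positive[pf$tissue == "blood"], 2)
  expect_equal(pf$n_positive[pf$tissue == "tumor"], 1)
  expect_equal(sum(pf$n_positive), 3)  # groups partition the global count
  expect_equal(sum(pf$n_total), 7)
  # invariant to the normalization scale factor
  nm2 <- normalize_counts(make_count_matrix(counts, meta), scale_factor = 137)
  expect_identical(positive_fraction(nm2, "gX", "tissue")$n_positive,
                   pf$n_positive)
  # all-zero gene
  counts0 <- counts; counts0[1, ] <- 0; counts0[2, 1] <- 5
  nm0 <- normalize_counts(make_count_matrix(counts0, meta))
  expect_true(all(positive_fraction(nm0, "gX", "tissue")$n_positive == 0))
  expect_error(positive_fraction(nm, "gZ"), "not in the matrix")
})

test_that("relatedness dendrogram groups the transcriptionally close profiles", {
  # TIM-like and blood-monocyte profiles nearly identical; TAM far away
  set.seed(5)
  base <- rpois(100, 60)
  pb <- cbind(Mono_blood = base + rpois(100, 3),
              TIM = base + rpois(100, 3),
              TAM = rpois(100, 60))
  rownames(pb) <- sprintf("g%03d", 1:100)
  dend <- relatedness_dendrogram(pb, colnames(pb))
  d <- dend$dist
  expect_lt(d["Mono_blood", "TIM"], d["Mono_blood", "TAM"])
  expect_lt(d["Mono_blood", "TIM"], d["TIM", "TAM"])
  # the two monocyte groups are siblings in the Newick topology
  expect_match(dend$newick, "\\((Mono_blood|TIM):[0-9.e-]+,(Mono_blood|TIM):")
  expect_error(relatedness_dendrogram(pb[, 1:2], colnames(pb)[1:2]), ">= 3")

  # a duplicated profile merges first at distance zero
  pb2 <- cbind(pb, TIM_copy = pb[, "TIM"])
  dend2 <- relatedness_dendrogram(pb2, colnames(pb2))
  expect_equal(dend2$dist["TIM", "TIM_copy"], 0)
})
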