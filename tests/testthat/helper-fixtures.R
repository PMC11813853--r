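# Shared fixtures, built in code at test time.

# Deterministic 3-gene x 4-cell matrix with mixed zeros.
tiny_counts <- function() {
  m <- Matrix::Matrix(matrix(c(
    0, 2, 5, 0,
    1, 0, 3, 4,
    0, 0, 2, 7
  ), nrow = 3, byrow = TRUE), sparse = TRUE)
  rownames(m) <- c("gA", "gB", "MT1")
  colnames(m) <- paste0("cell", 1:4)
  m
}

tiny_meta <- function(barcodes = paste0("cell", 1:4)) {
  data.frame(
    barcode = barcodes,
    sample_id = rep(c("s1", "s2"), length.out = length(barcodes)),
    tissue = rep(c("blood", "tumor"), length.out = length(barcodes)),
    cell_type = "T",
    stringsAsFactors = FALSE
  )
}

tiny_sce <- function() make_count_matrix(tiny_counts(), tiny_meta())

# Small full-featured simulation reused across test blocks (built once).
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(n_samples_blood = 4, n_samples_tumor = 3,
                      cells_per_sample = 300, n_genes = 250,
                      ambient_genes = 10, seed = 101)
    .fixture_env$sim <- simulate_dataset(cfg)
  }
  .fixture_env$sim
}

# Hand-built DE tables for the conservation classifier: one gene per state.
make_de_table <- function(genes, lfc, sig) {
  data.frame(gene = genes, base_mean = 50, log2fc = lfc, se = 0.2,
             wald_stat = abs(lfc) / 0.2, p = ifelse(sig, 1e-6, 0.5),
             padj = ifelse(sig, 1e-5, 0.7), significant = sig,
             stringsAsFactors = FALSE)
}
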