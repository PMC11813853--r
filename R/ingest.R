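#' Read a 10x-style MTX triplet plus cell annotations
#'
#' Loads a MatrixMarket sparse count matrix with its features and barcodes
#' files (optionally gzip-compressed) and joins a per-cell annotation table.
#' Cells without annotation are dropped with a logged count; gene order is
#' preserved from the features file. Duplicate gene symbols are
#' disambiguated by suffixing (logged); duplicate barcodes are fatal.
#'
#' @param dir_path Directory containing `matrix.mtx[.gz]`,
#'   `features.tsv[.gz]` (or `genes.tsv[.gz]`) and `barcodes.tsv[.gz]`.
#' @param meta_path CSV/TSV file with a header and one row per barcode;
#'   must contain columns `barcode`, `sample_id` and `tissue`
#'   (`blood`/`tumor`); `cell_type`, `subcluster` and `species` are kept
#'   when present.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay (genes x cells) and the annotations in `colData`.
#' @export
read_10x <- function(dir_path, meta_path) {
  mtx  <- find_10x_file(dir_path, "matrix.mtx")
  feat <- find_10x_file(dir_path, c("features.tsv", "genes.tsv"))
  bc   <- find_10x_file(dir_path, "barcodes.tsv")
  counts <- read_mm(mtx)
  features <- read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(bc)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(features) != nrow(counts)) {
    stop(sprintf("features file has %d rows but matrix has %d rows",
                 nrow(features), nrow(counts)), call. = FALSE)
  }
  if (length(barcodes) != ncol(counts)) {
    stop(sprintf("barcodes file has %d entries but matrix has %d columns",
                 length(barcodes), ncol(counts)), call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate cell barcodes in ", bc, call. = FALSE)
  }
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  if (anyDuplicated(symbols)) {
    n_dup <- sum(duplicated(symbols))
    til_log(n_dup, " duplicated gene symbols disambiguated by suffixing")
    symbols <- make.unique(symbols, sep = ".")
  }
  rownames(counts) <- symbols
  colnames(counts) <- barcodes

  meta <- read_table_auto(meta_path)
  if (!"barcode" %in% names(meta)) {
    stop("metadata must contain a 'barcode' column: ", meta_path, call. = FALSE)
  }
  for (f in c("sample_id", "tissue")) {
    if (!f %in% names(meta)) {
      stop("metadata must contain a '", f, "' column", call. = FALSE)
    }
  }
  if (anyDuplicated(meta$barcode)) {
    stop("duplicate barcodes in metadata table", call. = FALSE)
  }
  keep <- barcodes %in% meta$barcode
  if (!any(keep)) {
    stop("no matrix barcode is covered by the metadata table", call. = FALSE)
  }
  if (any(!keep)) {
    til_log(sum(!keep), " cells without metadata dropped")
  }
  counts <- counts[, keep, drop = FALSE]
  meta <- meta[match(colnames(counts), meta$barcode), , drop = FALSE]
  rownames(meta) <- meta$barcode
  make_count_matrix(counts, meta)
}

#' Assemble a CountMatrix container from parts
#'
#' @param counts Non-negative integer matrix (genes x cells), dense or
#'   sparse; coerced to `dgCMatrix`.
#' @param cell_meta data.frame with one row per cell carrying at least
#'   `sample_id` and `tissue`; row order must match `colnames(counts)`.
#' @return A `SingleCellExperiment`.
#' @export
make_count_matrix <- function(counts, cell_meta) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must carry unique gene identifiers as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts must carry unique cell barcodes as colnames", call. = FALSE)
  }
  stopifnot(nrow(cell_meta) == ncol(counts))
  for (f in c("sample_id", "tissue")) {
    if (!f %in% names(cell_meta) || anyNA(cell_meta[[f]])) {
      stop("every cell needs a non-missing '", f, "'", call. = FALSE)
    }
  }
  bad <- setdiff(unique(cell_meta$tissue), c("blood", "tumor"))
  if (length(bad)) {
    stop("tissue must be 'blood' or 'tumor'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_meta, row.names = colnames(counts))
  )
}

find_10x_file <- function(dir_path, stems) {
  for (stem in stems) {
    for (cand in file.path(dir_path, c(stem, paste0(stem, ".gz")))) {
      if (file.exists(cand)) return(cand)
    }
  }
  stop("missing file '", stems[1], "[.gz]' in ", dir_path, call. = FALSE)
}

# Matrix::readMM wants a plain file; inflate .gz to a tempfile first.
read_mm <- function(path) {
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = ".mtx")
    on.exit(unlink(tmp))
    writeLines(readLines(gzfile(path)), tmp)
    path <- tmp
  }
  methods::as(Matrix::readMM(path), "CsparseMatrix")
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Per-tissue quality-control thresholds
#'
#' Presets follow the study design for droplet scRNA-seq of osteosarcoma:
#' tumor cells kept when 200 < nFeature < 5500, percent-mito < 12.5 and
#' 100 < nCount < 15000; blood cells when 200 < nFeature < 3500,
#' percent-mito < 20 and 500 < nCount < 20000. All bounds are strict.
#'
#' @param tissue `"tumor"` or `"blood"` to obtain the preset, or NULL to
#'   pass explicit values.
#' @param min_features,max_features Bounds on genes detected per cell.
#' @param max_pct_mt Upper bound on percent mitochondrial counts.
#' @param min_counts,max_counts Bounds on total counts per cell.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(tissue = NULL, min_features = 200,
                          max_features = 5500, max_pct_mt = 12.5,
                          min_counts = 100, max_counts = 15000) {
  if (!is.null(tissue)) {
    preset <- switch(match.arg(tissue, c("tumor", "blood")),
      tumor = list(200, 5500, 12.5, 100, 15000),
      blood = list(200, 3500, 20, 500, 20000)
    )
    min_features <- preset[[1]]; max_features <- preset[[2]]
    max_pct_mt <- preset[[3]]; min_counts <- preset[[4]]
    max_counts <- preset[[5]]
  }
  stopifnot(min_features < max_features, min_counts < max_counts,
            max_pct_mt >= 0, max_pct_mt <= 100)
  structure(list(min_features = min_features, max_features = max_features,
                 max_pct_mt = max_pct_mt, min_counts = min_counts,
                 max_counts = max_counts),
            class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' @param m CountMatrix (`SingleCellExperiment`).
#' @param mito_genes Character vector of mitochondrial gene identifiers.
#' @return data.frame with `n_features`, `n_counts`, `pct_mt` per cell.
#' @export
qc_metrics <- function(m, mito_genes = character()) {
  counts <- SummarizedExperiment::assay(m, "counts")
  missing <- setdiff(mito_genes, rownames(counts))
  if (length(missing)) {
    til_log(length(missing), " mitochondrial ids absent from matrix; ",
            "intersecting", level = "WARN")
    warning(length(missing), " mitochondrial gene ids not in the matrix",
            call. = FALSE)
    mito_genes <- intersect(mito_genes, rownames(counts))
  }
  n_counts <- Matrix::colSums(counts)
  n_features <- Matrix::colSums(counts > 0)
  mt <- if (length(mito_genes)) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE])
  } else rep(0, ncol(counts))
  pct_mt <- ifelse(n_counts > 0, 100 * mt / n_counts, 0)
  data.frame(barcode = colnames(counts), n_features = n_features,
             n_counts = n_counts, pct_mt = pct_mt,
             row.names = colnames(counts), stringsAsFactors = FALSE)
}

#' Filter cells on quality-control thresholds
#'
#' Retains cells satisfying every bound strictly:
#' `min_features < nFeature < max_features`, `pct_mt < max_pct_mt` and
#' `min_counts < nCount < max_counts`. Boundary cells are removed, matching
#' the strict inequalities of the study protocol.
#'
#' @param m CountMatrix.
#' @param t `qc_thresholds` object.
#' @param mito_genes Mitochondrial gene ids used for the percent-mito
#'   criterion (supplied explicitly; naming conventions differ by species).
#' @return Filtered CountMatrix.
#' @export
apply_qc <- function(m, t, mito_genes = character()) {
  stopifnot(inherits(t, "qc_thresholds"))
  qm <- suppressWarnings(qc_metrics(m, mito_genes))
  pass_feat <- qm$n_features > t$min_features & qm$n_features < t$max_features
  pass_mt   <- qm$pct_mt < t$max_pct_mt
  pass_cnt  <- qm$n_counts > t$min_counts & qm$n_counts < t$max_counts
  keep <- pass_feat & pass_mt & pass_cnt
  if (!any(keep)) {
    stop(sprintf(paste0(
      "all %d cells removed by QC (failing features: %d, mito: %d, ",
      "counts: %d)"), length(keep), sum(!pass_feat), sum(!pass_mt),
      sum(!pass_cnt)), call. = FALSE)
  }
  if (any(!keep)) til_log(sum(!keep), " cells removed by QC")
  m[, keep]
}

#' Log-normalize counts
#'
#' Counts are scaled per cell to `scale_factor` total and transformed with
#' `log1p`: value(g,c) = ln(1 + count * scale_factor / total(c)). A value is
#' zero iff the raw count is zero, so positivity calls (e.g. marker-positive
#' cells) are invariant to the scale factor.
#'
#' @param m CountMatrix.
#' @param scale_factor Positive scaling constant (default 10000).
#' @return The input with a `logcounts` assay added; the scale factor is
#'   recorded in `metadata(m)$scale_factor`.
#' @export
normalize_counts <- function(m, scale_factor = 10000) {
  stopifnot(is.numeric(scale_factor), scale_factor > 0)
  counts <- SummarizedExperiment::assay(m, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop(sum(totals == 0), " cells have zero total counts; run apply_qc ",
         "before normalizing", call. = FALSE)
  }
  norm <- counts
  norm@x <- log1p(norm@x * rep.int(scale_factor / totals, diff(norm@p)))
  SummarizedExperiment::assay(m, "logcounts") <- norm
  S4Vectors::metadata(m)$scale_factor <- scale_factor
  m
}

#' Down-sample cells for balanced group representation
#'
#' Every level of `group_key` retains exactly the minimum group size of
#' cells, sampled without replacement; used so visual comparisons between
#' tissues are not dominated by the larger dataset.
#'
#' @param m CountMatrix.
#' @param group_key Column of `colData(m)` to balance on (e.g. "tissue").
#' @param seed Integer seed; the same seed reproduces the same cells.
#' @return CountMatrix restricted to the sampled cells.
#' @export
downsample_balanced <- function(m, group_key = "tissue", seed = 1L) {
  groups <- SummarizedExperiment::colData(m)[[group_key]]
  if (is.null(groups)) stop("no column '", group_key, "' in colData", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups to balance", call. = FALSE)
  if (any(tab == 0)) stop("empty group in '", group_key, "'", call. = FALSE)
  n_keep <- min(tab)
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(groups), groups), function(i) {
      if (length(i) == n_keep) i else sample(i, n_keep)
    }), use.names = FALSE)
  })
  m[, sort(idx)]
}
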