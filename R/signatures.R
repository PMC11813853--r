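#' Gene-set module score with expression-binned control genes
#'
#' Re-implementation of the binned-control scoring procedure popularized by
#' Seurat's AddModuleScore: genes are ranked by mean normalized expression
#' across cells and cut into `n_bins` bins; for each signature gene,
#' `n_ctrl` control genes are sampled uniformly without replacement from
#' its bin (independently across signature genes, so a control gene can
#' serve several of them); a cell's score is the mean expression of the
#' signature genes minus the mean over the pooled control draws. Signature
#' genes are excluded from the control candidates of their bin, so adding a
#' constant to a cell's signature expression shifts its score by exactly
#' that constant; if a bin holds no other genes its full membership is used.
#'
#' @param nm Normalized CountMatrix (needs a `logcounts` assay, see
#'   [normalize_counts()]).
#' @param gene_set Character vector of signature gene ids; ids absent from
#'   the matrix are dropped with a warning (empty intersection is fatal).
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100;
#'   capped at the bin size).
#' @param seed Integer seed making the control draw reproducible.
#' @return List with `score` (named per-cell numeric) and `parameters`.
#' @export
module_score <- function(nm, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  expr <- SummarizedExperiment::assay(nm, "logcounts")
  missing <- setdiff(gene_set, rownames(expr))
  if (length(missing) == length(gene_set)) {
    stop("no signature gene is present in the matrix", call. = FALSE)
  }
  if (length(missing)) {
    warning(length(missing), " signature genes absent from matrix; ",
            "intersecting", call. = FALSE)
    gene_set <- setdiff(gene_set, missing)
  }
  avg <- Matrix::rowMeans(expr)
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  names(bin) <- rownames(expr)
  ctrl_pool <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      members <- setdiff(names(bin)[bin == bin[g]], gene_set)
      if (!length(members)) members <- names(bin)[bin == bin[g]]
      sample(members, min(n_ctrl, length(members)))
    }), use.names = FALSE)
  })
  sig_score <- Matrix::colMeans(expr[gene_set, , drop = FALSE])
  ## pooled multiset mean: duplicates across signature genes count again
  ctrl_tab <- table(ctrl_pool)
  w <- as.numeric(ctrl_tab) / length(ctrl_pool)
  ctrl_score <- as.numeric(w %*% expr[names(ctrl_tab), , drop = FALSE])
  list(score = setNames(sig_score - ctrl_score, colnames(expr)),
       parameters = list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed))
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For every cluster, genes detected in at least `min_pct` of the cells
#' inside or outside the cluster and with log2 fold change >= `min_lfc`
#' are tested cluster-vs-rest with a Wilcoxon rank-sum on normalized
#' expression; p-values are BH-adjusted within cluster and only
#' positive-fold-change rows are kept. The fold change follows the
#' log-normalized convention: log2 of the ratio of expm1-mean expressions,
#' each plus a pseudo-count of 1.
#'
#' @param nm Normalized CountMatrix.
#' @param cluster_labels Cluster assignment per cell (character/factor), or
#'   the name of a `colData` column.
#' @param min_pct Detection-fraction filter (default 0.1).
#' @param min_lfc Fold-change filter on the log2 scale (default 0.25).
#' @return data.frame: cluster, gene, log2fc, p, padj, pct_in, pct_out.
#' @export
find_markers <- function(nm, cluster_labels = "cell_type", min_pct = 0.1,
                         min_lfc = 0.25) {
  expr <- SummarizedExperiment::assay(nm, "logcounts")
  if (is.character(cluster_labels) && length(cluster_labels) == 1) {
    cluster_labels <- SummarizedExperiment::colData(nm)[[cluster_labels]]
  }
  cluster_labels <- as.character(cluster_labels)
  stopifnot(length(cluster_labels) == ncol(expr))
  clusters <- sort(unique(cluster_labels))
  if (length(clusters) < 2) stop("need >= 2 clusters", call. = FALSE)

  out <- list()
  for (cl in clusters) {
    inside <- cluster_labels == cl
    e_in <- expr[, inside, drop = FALSE]
    e_out <- expr[, !inside, drop = FALSE]
    pct_in <- Matrix::rowSums(e_in > 0) / ncol(e_in)
    pct_out <- Matrix::rowSums(e_out > 0) / ncol(e_out)
    lfc <- log2((Matrix::rowMeans(expm1_sparse(e_in)) + 1) /
                (Matrix::rowMeans(expm1_sparse(e_out)) + 1))
    test <- (pct_in >= min_pct | pct_out >= min_pct) & lfc >= min_lfc
    if (!any(test)) next
    genes <- rownames(expr)[test]
    p <- vapply(genes, function(g) {
      suppressWarnings(wilcox.test(as.numeric(e_in[g, ]),
                                   as.numeric(e_out[g, ]))$p.value)
    }, numeric(1))
    d <- data.frame(cluster = cl, gene = genes, log2fc = lfc[test], p = p,
                    padj = adjust_bh(p), pct_in = pct_in[test],
                    pct_out = pct_out[test], row.names = NULL,
                    stringsAsFactors = FALSE)
    out[[cl]] <- d[order(d$p, -d$log2fc), ]
  }
  if (!length(out)) {
    return(data.frame(cluster = character(), gene = character(),
                      log2fc = numeric(), p = numeric(), padj = numeric(),
                      pct_in = numeric(), pct_out = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

expm1_sparse <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    m <- methods::as(m, "CsparseMatrix")
    m@x <- expm1(m@x)
    m
  } else {
    expm1(m)
  }
}

#' Marker-positive cell counts per group
#'
#' A cell is positive for a gene iff its normalized value exceeds 0, which
#' under log1p normalization is equivalent to a raw count > 0, so the
#' counts are invariant to the normalization scale factor.
#'
#' @param nm Normalized CountMatrix.
#' @param gene Gene id (fatal if absent).
#' @param group_fields `colData` columns defining the groups
#'   (default "tissue").
#' @return data.frame with one row per group: the group fields,
#'   `n_positive`, `n_total`.
#' @export
positive_fraction <- function(nm, gene, group_fields = "tissue") {
  expr <- SummarizedExperiment::assay(nm, "logcounts")
  if (!gene %in% rownames(expr)) {
    stop("gene '", gene, "' not in the matrix", call. = FALSE)
  }
  cd <- as.data.frame(SummarizedExperiment::colData(nm))
  key <- interaction(cd[group_fields], drop = TRUE, sep = ".")
  pos <- as.numeric(expr[gene, ]) > 0
  out <- do.call(rbind, lapply(split(seq_along(key), key), function(i) {
    row <- cd[i[1], group_fields, drop = FALSE]
    row$n_positive <- sum(pos[i])
    row$n_total <- length(i)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Hierarchical relatedness of pseudobulk expression profiles
#'
#' Builds one profile per group as the mean over its pseudobulk units of
#' log1p size-factor-normalized counts, computes pairwise Euclidean
#' distances and agglomerates with average linkage. The tree is also
#' returned serialized in Newick format.
#'
#' @param pb PseudobulkMatrix.
#' @param groups Group label per unit (>= 3 distinct groups), or the name
#'   of a colData column.
#' @param linkage `hclust` agglomeration method (default "average").
#' @return List: `tree` (an [ape::as.phylo] object), `newick` (string),
#'   `dist` (distance matrix), `profiles`.
#' @export
relatedness_dendrogram <- function(pb, groups, linkage = "average") {
  counts <- pb_counts(pb)
  if (is.character(groups) && length(groups) == 1) {
    groups <- SummarizedExperiment::colData(pb)[[groups]]
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts))
  if (length(unique(groups)) < 3) {
    stop("need >= 3 groups for a dendrogram", call. = FALSE)
  }
  sf <- estimate_size_factors(counts)
  lognorm <- log1p(sweep(counts, 2, sf, "/"))
  profiles <- vapply(sort(unique(groups)), function(g) {
    rowMeans(lognorm[, groups == g, drop = FALSE])
  }, numeric(nrow(counts)))
  d <- dist(t(profiles), method = "euclidean")
  hc <- hclust(d, method = linkage)
  tree <- ape::as.phylo(hc)
  list(tree = tree, newick = ape::write.tree(tree), dist = as.matrix(d),
       profiles = profiles)
}

#' Read gene sets from a two-column CSV
#'
#' @param path CSV with header columns `set_name`, `gene`.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  d <- read_table_auto(path)
  if (!all(c("set_name", "gene") %in% names(d))) {
    stop("gene-set file needs 'set_name' and 'gene' columns", call. = FALSE)
  }
  lapply(split(d$gene, d$set_name), unique)
}
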