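#' Per-sample cell-type proportions
#'
#' Abundance comparisons are made on the percentage of total cells in the
#' analyzed subset: percent(sample, type) = 100 * n(sample, type) /
#' n(sample), zero-filled so every sample contributes a row for every cell
#' type. Samples with no cells in the subset are dropped with a warning.
#'
#' @param m CountMatrix.
#' @param cell_subset Barcodes defining the analyzed subset (default: all).
#' @return Object of class `abundance_table`: list with `table` (long
#'   data.frame sample_id, tissue, cell_type, n, percent) and `summary`
#'   (per cell type and tissue: mean percent, sd, n_samples), plus
#'   `max_subset_size` used for the pseudo-floor default.
#' @export
compute_proportions <- function(m, cell_subset = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(m))
  if (is.null(cd$cell_type)) stop("no 'cell_type' in colData", call. = FALSE)
  if (!is.null(cell_subset)) cd <- cd[rownames(cd) %in% cell_subset, ]
  if (!nrow(cd)) stop("empty cell subset", call. = FALSE)
  all_samples <- unique(SummarizedExperiment::colData(m)$sample_id)
  dropped <- setdiff(all_samples, unique(cd$sample_id))
  if (length(dropped)) {
    warning(length(dropped), " samples with no cells in the subset dropped",
            call. = FALSE)
  }
  tab <- as.data.frame(table(sample_id = cd$sample_id,
                             cell_type = cd$cell_type),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  totals <- tapply(tab$n, tab$sample_id, sum)
  tab$percent <- 100 * tab$n / as.numeric(totals[tab$sample_id])
  tissue_of <- tapply(cd$tissue, cd$sample_id, function(x) x[1])
  tab$tissue <- as.character(tissue_of[tab$sample_id])
  tab <- tab[order(tab$sample_id, tab$cell_type),
             c("sample_id", "tissue", "cell_type", "n", "percent")]
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(split(tab, tab[c("cell_type", "tissue")]),
    function(d) {
      data.frame(cell_type = d$cell_type[1], tissue = d$tissue[1],
                 mean_percent = mean(d$percent), sd_percent = sd(d$percent),
                 n_samples = nrow(d), stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ,
                 max_subset_size = max(as.numeric(totals))),
            class = "abundance_table")
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact-distribution p when the combined sample size is at most 20 and no
#' ties are present; otherwise the normal approximation with tie and
#' continuity correction. Either list shorter than 2 returns p = 1 with a
#' warning.
#'
#' @param x,y Numeric vectors (e.g. per-sample percentages by tissue).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    warning("fewer than 2 observations in a group; p set to 1",
            call. = FALSE)
    return(1)
  }
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
  # fully tied data carry no ranking information (z = 0/0 in the
  # tie-corrected approximation): no evidence against the null
  if (is.nan(p)) p <- 1
  p
}

#' Classify cell-type abundance shifts between tumor and blood
#'
#' For each cell type, per-sample percentages are compared between tissues
#' with a two-sided Wilcoxon rank-sum test and the fold change is
#' log2((mean% tumor + pseudo) / (mean% blood + pseudo)). Classes follow
#' the study rule: significant (p < alpha) shifts with |log2FC| < fc_cut
#' are over-/under-represented; "unique" is reserved for significant shifts
#' with |log2FC| > fc_cut, the exaggerated fold changes produced by types
#' with little or no representation in one tissue. p >= alpha gives `ns`
#' regardless of fold change. A significant |log2FC| exactly at `fc_cut`
#' takes the conservative over/under label and is flagged in `boundary`.
#'
#' @param tab An `abundance_table`.
#' @param alpha Significance level (default 0.05).
#' @param fc_cut |log2FC| cut separating over/under from unique (default 3).
#' @param pseudo Pseudo-percentage floor added to both means so absent
#'   types yield finite, exaggerated fold changes. Default: one-cell
#'   equivalent, 100 / (largest subset size per sample).
#' @return data.frame: cell_type, mean_pct_blood, mean_pct_tumor, p,
#'   log2fc, class in over_tumor/under_tumor/unique_tumor/unique_blood/ns,
#'   boundary flag.
#' @export
classify_abundance <- function(tab, alpha = 0.05, fc_cut = 3, pseudo = NULL) {
  stopifnot(inherits(tab, "abundance_table"))
  check_prob(alpha, "alpha")
  pseudo <- pseudo %||% (100 / tab$max_subset_size)
  d <- tab$table
  for (tis in c("blood", "tumor")) {
    if (length(unique(d$sample_id[d$tissue == tis])) < 2) {
      stop("need >= 2 samples per tissue; '", tis, "' has fewer",
           call. = FALSE)
    }
  }
  out <- do.call(rbind, lapply(split(d, d$cell_type), function(g) {
    x_t <- g$percent[g$tissue == "tumor"]
    x_b <- g$percent[g$tissue == "blood"]
    p <- wilcoxon_rank_sum(x_t, x_b)
    lfc <- log2((mean(x_t) + pseudo) / (mean(x_b) + pseudo))
    cls <- if (p >= alpha || lfc == 0) {
      "ns"
    } else if (abs(lfc) > fc_cut) {
      if (lfc > 0) "unique_tumor" else "unique_blood"
    } else {
      if (lfc > 0) "over_tumor" else "under_tumor"
    }
    data.frame(cell_type = g$cell_type[1], mean_pct_blood = mean(x_b),
               mean_pct_tumor = mean(x_t), p = p, log2fc = lfc, class = cls,
               boundary = (p < alpha && abs(lfc) == fc_cut),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
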