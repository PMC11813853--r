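#' Differential-expression configuration
#'
#' Defaults follow the study protocol: the Wald test is against the null
#' |log2FC| < 0.58, significance is FDR-adjusted p < 0.01, and the
#' low-abundance filter removes genes detected (count > 1) in fewer than 10
#' cells.
#'
#' @param lfc_threshold Null-interval half-width theta on the log2 scale
#'   (default 0.58).
#' @param alpha FDR significance level (default 0.01).
#' @param min_cells_expressing Minimum number of cells with count >
#'   `min_count` for a gene to be tested (default 10).
#' @param min_count Count a cell must exceed to witness expression
#'   (default 1, i.e. counts of 2 or more).
#' @return An object of class `de_config`.
#' @export
de_config <- function(lfc_threshold = 0.58, alpha = 0.01,
                      min_cells_expressing = 10, min_count = 1) {
  stopifnot(lfc_threshold >= 0, min_cells_expressing >= 0, min_count >= 0)
  check_prob(alpha, "alpha")
  structure(list(lfc_threshold = lfc_threshold, alpha = alpha,
                 min_cells_expressing = min_cells_expressing,
                 min_count = min_count),
            class = "de_config")
}

#' Aggregate single-cell counts into pseudobulk units
#'
#' Sums raw counts over all cells sharing the same combination of grouping
#' fields (e.g. sample and tissue), yielding bulk-like replicates for NB
#' testing. Units with zero cells are absent by construction.
#'
#' @param m CountMatrix.
#' @param group_fields Character vector of `colData` columns defining a
#'   unit (default `c("sample_id", "tissue")`).
#' @return A `SummarizedExperiment` with integer `counts` (genes x units)
#'   and colData holding the grouping fields plus `n_cells`.
#' @export
aggregate_pseudobulk <- function(m, group_fields = c("sample_id", "tissue")) {
  cd <- SummarizedExperiment::colData(m)
  missing <- setdiff(group_fields, colnames(cd))
  if (length(missing)) {
    stop("grouping fields absent from colData: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(group_fields) == 0 || ncol(m) == 0) {
    stop("empty grouping", call. = FALSE)
  }
  key <- do.call(paste, c(lapply(group_fields, function(f) cd[[f]]),
                          sep = "\r"))
  key <- factor(key, levels = unique(key))
  memb <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(key),
                               x = 1, dims = c(length(key), nlevels(key)))
  counts <- as.matrix(SummarizedExperiment::assay(m, "counts") %*% memb)
  ann <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  colnames(ann) <- group_fields
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  ann$n_cells <- as.integer(table(key)[levels(key)])
  unit_ids <- do.call(paste, c(ann[group_fields], sep = "."))
  colnames(counts) <- unit_ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(ann, row.names = unit_ids)
  )
}

#' Low-abundance gene filter on single-cell counts
#'
#' Retains genes witnessed by at least `min_cells_expressing` cells with a
#' raw count strictly greater than `min_count`, evaluated on single-cell
#' counts across the analyzed cell subset (not on pseudobulk sums).
#'
#' @param m CountMatrix.
#' @param cfg `de_config`.
#' @param cell_subset Barcodes restricting the evaluation (default: all).
#' @return Character vector of retained gene ids, in matrix order.
#' @export
filter_low_abundance <- function(m, cfg = de_config(), cell_subset = NULL) {
  counts <- SummarizedExperiment::assay(m, "counts")
  if (!is.null(cell_subset)) {
    counts <- counts[, colnames(counts) %in% cell_subset, drop = FALSE]
  }
  if (ncol(counts) == 0) stop("empty cell subset", call. = FALSE)
  n_expressing <- Matrix::rowSums(counts > cfg$min_count)
  rownames(counts)[n_expressing >= cfg$min_cells_expressing]
}

#' Median-of-ratios size factors
#'
#' The DESeq-style estimator: for each unit, the median over genes of the
#' ratio of its count to the gene's geometric mean across units, using only
#' genes with nonzero counts in every unit.
#'
#' @param pb PseudobulkMatrix (`SummarizedExperiment`) or a plain counts
#'   matrix.
#' @return Named positive numeric vector, one entry per unit.
#' @export
estimate_size_factors <- function(pb) {
  counts <- pb_counts(pb)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop("no gene has nonzero counts in every unit; relax filtering or ",
         "merge units", call. = FALSE)
  }
  sf <- apply(counts[usable, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo[usable]))
  })
  setNames(sf, colnames(counts))
}

pb_counts <- function(pb) {
  if (methods::is(pb, "SummarizedExperiment")) {
    as.matrix(SummarizedExperiment::assay(pb, "counts"))
  } else {
    as.matrix(pb)
  }
}

#' Per-gene NB dispersion with trend and empirical-Bayes shrinkage
#'
#' A simplified DESeq2-style scheme on size-factor-normalized pseudobulk
#' counts with condition-specific means: method-of-moments initialization,
#' per-gene Cox-Reid-adjusted maximum likelihood on the log-dispersion, a
#' parametric mean
#' trend alpha(mu) = a/mu + b fitted by iterated gamma regression, and
#' shrinkage of the log-dispersion toward the trend under a normal prior
#' whose variance is estimated from the spread of gene-wise values around
#' the trend minus the expected sampling variance (floored at 0.25).
#' Estimates are floored at 1e-8. No outlier refitting is attempted.
#'
#' @param pb PseudobulkMatrix or counts matrix.
#' @param design Factor/character of conditions, one per unit.
#' @param size_factors Optional precomputed size factors.
#' @return Numeric vector of final per-gene dispersions, with attributes
#'   `genewise`, `trend`, `prior_var` and `mean_norm`.
#' @export
estimate_dispersion <- function(pb, design, size_factors = NULL) {
  counts <- pb_counts(pb)
  design <- as.factor(design)
  stopifnot(length(design) == ncol(counts))
  if (any(table(design) < 2)) {
    stop("every condition needs at least 2 replicate units to estimate ",
         "dispersion", call. = FALSE)
  }
  sf <- size_factors %||% estimate_size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  mean_norm <- rowMeans(norm)

  ## condition-specific fitted means on the raw-count scale
  cond_means <- vapply(levels(design), function(l) {
    rowMeans(norm[, design == l, drop = FALSE])
  }, numeric(nrow(counts)))
  mu_hat <- cond_means[, as.integer(design), drop = FALSE] *
    rep(sf, each = nrow(counts))

  m <- ncol(counts); p <- nlevels(design)
  ## method-of-moments on normalized counts, pooled within conditions
  within_var <- rowSums(vapply(levels(design), function(l) {
    sub <- norm[, design == l, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }, numeric(nrow(counts)))) / (m - p)
  mom <- (within_var - mean_norm) / pmax(mean_norm, 1e-8)^2
  mom <- pmax(mom, 1e-8)

  ## Cox-Reid adjusted NB log-likelihood: the 0.5*log det(X'WX) penalty
  ## corrects the downward MLE bias from estimating the condition means.
  ## With condition-specific means X'WX is diagonal per condition.
  nll <- function(log_a, y, mu) {
    a <- exp(log_a)
    w <- mu / (1 + a * mu)
    cr <- 0.5 * sum(log(vapply(levels(design), function(l) {
      sum(w[design == l])
    }, numeric(1))))
    -sum(stats::dnbinom(y, size = 1 / a, mu = mu, log = TRUE)) + cr
  }
  genewise <- vapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]; mu <- mu_hat[g, ]
    if (all(y == 0) || var(y) == 0) return(1e-8)
    opt <- optimize(nll, interval = c(-18.5, 7), y = y, mu = mu)
    exp(opt$minimum)
  }, numeric(1))

  trend <- fit_dispersion_trend(genewise, mean_norm)
  ## prior variance: spread of log residuals minus expected sampling noise
  use <- genewise > 1e-7 & mean_norm > 0
  lres <- log(genewise[use]) - log(trend[use])
  samp_var <- trigamma((m - p) / 2)
  prior_var <- max(0.25, stats::mad(lres, constant = 1.4826)^2 - samp_var)

  final <- vapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]; mu <- mu_hat[g, ]
    if (all(y == 0) || var(y) == 0) return(1e-8)
    post <- function(log_a) {
      nll(log_a, y, mu) + (log_a - log(trend[g]))^2 / (2 * prior_var)
    }
    opt <- optimize(post, interval = c(-18.5, 7))
    max(exp(opt$minimum), 1e-8)
  }, numeric(1))

  structure(setNames(final, rownames(counts)),
            genewise = genewise, trend = trend, prior_var = prior_var,
            mean_norm = mean_norm)
}

# alpha(mu) = a/mu + b via iterated gamma GLM with ratio-based outlier
# exclusion; falls back to a flat median trend if the fit degenerates.
fit_dispersion_trend <- function(disp, mean_norm) {
  use <- disp > 1e-7 & mean_norm > 1e-3
  fb_value <- if (any(use)) median(disp[use]) else median(disp)
  fallback <- rep(max(fb_value, 1e-8), length(disp))
  if (sum(use) < 10) return(fallback)
  d <- disp[use]; mu <- mean_norm[use]
  coefs <- c(a = 0, b = median(d))
  for (it in 1:8) {
    pred <- coefs["a"] / mu + coefs["b"]
    keep <- d / pred < 15 & d / pred > 1e-4
    fit <- try(suppressWarnings(
      glm(d[keep] ~ I(1 / mu[keep]),
          family = stats::Gamma(link = "identity"),
          start = pmax(c(coefs["b"], coefs["a"]), 1e-6))
    ), silent = TRUE)
    if (inherits(fit, "try-error")) break
    new <- c(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]))
    if (any(!is.finite(new))) break
    done <- all(abs(new - coefs) < 1e-6 * (abs(coefs) + 1e-6))
    coefs <- new
    if (done) break
  }
  if (coefs["b"] <= 0 || coefs["a"] < 0) return(fallback)
  pmax(coefs["a"] / pmax(mean_norm, 1e-3) + coefs["b"], 1e-8)
}

#' Wald test against a fold-change-threshold null
#'
#' Tests H0: |log2FC| < theta. The statistic is
#' W = max(0, (|log2fc| - theta)/se) with p = 2 * (1 - Phi(W)) capped at 1;
#' theta = 0 recovers the ordinary two-sided Wald test. Estimates inside
#' the null interval give W = 0 and p = 1 exactly.
#'
#' @param log2fc Estimated log2 fold change(s).
#' @param se Standard error(s), strictly positive.
#' @param theta Null half-width on the log2 scale (default 0.58).
#' @return List with `wald_stat` and `p`.
#' @export
wald_threshold_test <- function(log2fc, se, theta = 0.58) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("standard errors must be positive and finite", call. = FALSE)
  }
  stopifnot(theta >= 0)
  w <- pmax(0, (abs(log2fc) - theta) / se)
  p <- pmin(1, 2 * pnorm(w, lower.tail = FALSE))
  list(wald_stat = w, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; a validating wrapper around
#' [stats::p.adjust()] that rejects p-values outside `[0, 1]`.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, each >= the raw value, capped at 1.
#' @export
adjust_bh <- function(p) {
  check_prob(p, "p")
  p.adjust(p, method = "BH")
}

#' Pseudobulk NB differential expression between tumor and blood
#'
#' The full per-contrast procedure: restrict to a cell subset, apply the
#' single-cell low-abundance filter, drop excluded genes, sum counts per
#' (sample, tissue) unit, estimate size factors and dispersions, fit a
#' per-gene NB GLM (log link, log-size-factor offset) of the tissue effect,
#' test against the |log2FC| < theta null, and BH-adjust. The reported
#' log2FC is tumor relative to blood.
#'
#' @param m CountMatrix.
#' @param cell_subset Barcodes to analyze (default: all cells). Both
#'   tissues must retain at least 2 samples.
#' @param cfg `de_config`.
#' @param exclude Gene ids removed before testing (e.g. background tissue
#'   signatures and platelet genes); they never appear in the output.
#' @return data.frame with one row per tested gene: `gene`, `base_mean`
#'   (mean of size-factor-normalized counts), `log2fc`, `se`, `wald_stat`,
#'   `p`, `padj`, `significant` (padj < alpha).
#' @export
run_de <- function(m, cell_subset = NULL, cfg = de_config(),
                   exclude = character()) {
  if (!is.null(cell_subset)) {
    m <- m[, colnames(m) %in% cell_subset]
  }
  cd <- SummarizedExperiment::colData(m)
  for (tis in c("blood", "tumor")) {
    n_samp <- length(unique(cd$sample_id[cd$tissue == tis]))
    if (n_samp < 2) {
      stop("need >= 2 samples per tissue in the subset; '", tis,
           "' has ", n_samp, call. = FALSE)
    }
  }
  keep <- filter_low_abundance(m, cfg)
  keep <- setdiff(keep, exclude)
  if (!length(keep)) stop("no genes left to test after filtering", call. = FALSE)
  pb <- aggregate_pseudobulk(m[keep, ], c("sample_id", "tissue"))
  de_test_pseudobulk(pb, cfg)
}

#' NB Wald test on an existing pseudobulk matrix
#'
#' The statistical core of [run_de()], exposed for engine-level use on
#' directly simulated pseudobulk. Expects a `tissue` column in colData with
#' values `blood` (reference) and `tumor`.
#'
#' @param pb PseudobulkMatrix.
#' @param cfg `de_config`.
#' @return DE result data.frame as in [run_de()].
#' @export
de_test_pseudobulk <- function(pb, cfg = de_config()) {
  counts <- pb_counts(pb)
  tissue <- factor(SummarizedExperiment::colData(pb)$tissue,
                   levels = c("blood", "tumor"))
  if (any(table(tissue) < 2)) {
    stop("need >= 2 pseudobulk units per tissue", call. = FALSE)
  }
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, tissue, size_factors = sf)
  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  off <- log(sf)
  ln2 <- log(2)

  fit_one <- function(y, alpha) {
    fam <- MASS::negative.binomial(theta = 1 / max(alpha, 1e-8))
    fit <- suppressWarnings(glm(y ~ tissue, family = fam, offset = off,
                                control = list(maxit = 100)))
    s <- suppressWarnings(summary(fit))$coefficients
    c(lfc = unname(s["tissuetumor", "Estimate"]) / ln2,
      se = unname(s["tissuetumor", "Std. Error"]) / ln2)
  }
  est <- t(vapply(seq_len(nrow(counts)), function(g) {
    out <- try(fit_one(counts[g, ], disp[g]), silent = TRUE)
    if (inherits(out, "try-error") || any(!is.finite(out)) || out["se"] <= 0) {
      c(lfc = 0, se = NA_real_)
    } else out
  }, c(lfc = 0, se = 0)))

  ok <- is.finite(est[, "se"]) & est[, "se"] > 0
  wald_stat <- rep(0, nrow(counts)); p <- rep(1, nrow(counts))
  if (any(ok)) {
    wt <- wald_threshold_test(est[ok, "lfc"], est[ok, "se"],
                              theta = cfg$lfc_threshold)
    wald_stat[ok] <- wt$wald_stat; p[ok] <- wt$p
  }
  if (any(!ok)) til_log(sum(!ok), " genes with degenerate fits set to p = 1",
                        level = "WARN")
  padj <- adjust_bh(p)
  data.frame(gene = rownames(counts), base_mean = base_mean,
             log2fc = est[, "lfc"], se = est[, "se"], wald_stat = wald_stat,
             p = p, padj = padj, significant = padj < cfg$alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
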