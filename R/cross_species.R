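#' Reduce an orthologue table to strict 1:1 pairs
#'
#' Any gene symbol appearing in more than one pair on either side is
#' removed together with all its pairs; the remainder is injective in both
#' directions. Matching is at the symbol level; with
#' `case_normalize = TRUE` symbols are upper-cased first (logged).
#'
#' @param raw_pairs data.frame with columns `gene_a`, `gene_b`.
#' @param case_normalize Upper-case symbols before matching
#'   (default FALSE).
#' @return Object of class `orthologue_map`: data.frame `gene_a`,
#'   `gene_b`, 1:1.
#' @export
map_orthologues <- function(raw_pairs, case_normalize = FALSE) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(raw_pairs)))
  d <- unique(raw_pairs[c("gene_a", "gene_b")])
  if (case_normalize) {
    til_log("orthologue symbols upper-cased for matching")
    d$gene_a <- toupper(d$gene_a)
    d$gene_b <- toupper(d$gene_b)
    d <- unique(d)
  }
  multi_a <- names(which(table(d$gene_a) > 1))
  multi_b <- names(which(table(d$gene_b) > 1))
  drop <- d$gene_a %in% multi_a | d$gene_b %in% multi_b
  if (any(drop)) {
    til_log(sum(drop), " orthologue rows removed (", length(multi_a),
            " many-to-x symbols on side A, ", length(multi_b), " on side B)")
  }
  d <- d[!drop, , drop = FALSE]
  if (!nrow(d)) {
    stop("no 1:1 orthologue pairs remain (", sum(drop), " rows removed)",
         call. = FALSE)
  }
  rownames(d) <- NULL
  class(d) <- c("orthologue_map", "data.frame")
  d
}

#' Classify cross-species tumor-infiltration responses
#'
#' For every 1:1 orthologue pair, with DE tables computed on each species'
#' tested universe: conserved = significant in at least one species,
#' expressed in both, and same (nonzero) direction of log2FC; divergent =
#' significant in at least one, expressed in both, opposite directions;
#' ambiguous = significant in exactly one species and not expressed (or
#' failing the low-abundance filter) in the other; ns = expressed in both
#' but significant in neither. Pairs significant in neither species and
#' missing from one universe are dropped with a logged count, as are pairs
#' absent from both universes. A non-significant partner with |log2FC| <=
#' 1e-9 has no usable direction: such pairs are kept as conserved but
#' flagged in `zero_lfc_flag` for separate reporting.
#'
#' @param de_a,de_b DE result tables (see [run_de()]) for species A and B.
#' @param map An `orthologue_map`.
#' @param universe_a,universe_b Tested-gene sets per species (genes passing
#'   the low-abundance filter). Defaults: the genes of each DE table.
#' @return data.frame: gene_a, gene_b, lfc_a, lfc_b, sig_a, sig_b,
#'   expressed_a, expressed_b, class, zero_lfc_flag.
#' @export
classify_conservation <- function(de_a, de_b, map,
                                  universe_a = NULL, universe_b = NULL) {
  universe_a <- universe_a %||% de_a$gene
  universe_b <- universe_b %||% de_b$gene
  ia <- match(map$gene_a, de_a$gene)
  ib <- match(map$gene_b, de_b$gene)
  rec <- data.frame(
    gene_a = map$gene_a, gene_b = map$gene_b,
    lfc_a = de_a$log2fc[ia], lfc_b = de_b$log2fc[ib],
    sig_a = !is.na(ia) & de_a$significant[ia],
    sig_b = !is.na(ib) & de_b$significant[ib],
    expressed_a = map$gene_a %in% universe_a,
    expressed_b = map$gene_b %in% universe_b,
    stringsAsFactors = FALSE
  )
  in_neither <- !rec$expressed_a & !rec$expressed_b
  if (any(in_neither)) {
    warning(sum(in_neither), " mapped pairs absent from both universes ",
            "dropped", call. = FALSE)
    rec <- rec[!in_neither, , drop = FALSE]
  }
  eps <- 1e-9
  cls <- character(nrow(rec))
  flag <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    r <- rec[i, ]
    any_sig <- r$sig_a || r$sig_b
    both_expr <- r$expressed_a && r$expressed_b
    if (!any_sig) {
      cls[i] <- if (both_expr) "ns" else "dropped"
    } else if (!both_expr) {
      cls[i] <- "ambiguous"
    } else {
      sa <- sign(r$lfc_a); sb <- sign(r$lfc_b)
      if (abs(r$lfc_a) <= eps || abs(r$lfc_b) <= eps) {
        ## the non-significant partner carries no direction
        cls[i] <- "conserved"
        flag[i] <- TRUE
      } else if (sa == sb) {
        cls[i] <- "conserved"
      } else {
        cls[i] <- "divergent"
      }
    }
  }
  rec$class <- cls
  rec$zero_lfc_flag <- flag
  n_drop <- sum(cls == "dropped")
  if (n_drop) {
    til_log(n_drop, " pairs significant in neither species and missing ",
            "from one universe dropped")
    rec <- rec[rec$class != "dropped", , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

#' Summarize conservation classes
#'
#' Headline percentages use the genes differentially expressed in at least
#' one species as the denominator (conserved + divergent + ambiguous). The
#' scatter table carries the two log2 fold changes and class per
#' expressed-in-both pair, with axis-marginal rows (the missing species'
#' fold change set to NA) for ambiguous genes.
#'
#' @param records Output of [classify_conservation()].
#' @return List: `counts` (named per class), `percentages` (over the
#'   DE-in-at-least-one denominator), `scatter` (data.frame gene_a,
#'   gene_b, lfc_a, lfc_b, class).
#' @export
conservation_summary <- function(records) {
  if (!nrow(records)) stop("no conservation records", call. = FALSE)
  counts <- table(factor(records$class,
                         levels = c("conserved", "divergent", "ambiguous",
                                    "ns")))
  denom <- sum(counts[c("conserved", "divergent", "ambiguous")])
  pct <- if (denom > 0) {
    100 * counts[c("conserved", "divergent", "ambiguous")] / denom
  } else {
    setNames(rep(0, 3), c("conserved", "divergent", "ambiguous"))
  }
  scatter <- records[, c("gene_a", "gene_b", "lfc_a", "lfc_b", "class")]
  scatter$lfc_a[!records$expressed_a] <- NA_real_
  scatter$lfc_b[!records$expressed_b] <- NA_real_
  rownames(scatter) <- NULL
  list(counts = c(counts), percentages = c(pct), scatter = scatter)
}
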