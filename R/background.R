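#' Tumor-vs-blood DE within each major cell type
#'
#' Runs [run_de()] separately inside every listed cell type with no
#' exclusion list; each type applies its own low-abundance filter. Types
#' present in only one tissue, or with fewer than 2 samples per tissue, are
#' skipped with a warning.
#'
#' @param m CountMatrix.
#' @param cell_types Types to analyze (default: all in the metadata).
#' @param cfg `de_config`.
#' @return Named list of DE result data.frames, one per analyzed type.
#' @export
per_celltype_de <- function(m, cell_types = NULL, cfg = de_config()) {
  cd <- SummarizedExperiment::colData(m)
  if (is.null(cd$cell_type)) stop("no 'cell_type' in colData", call. = FALSE)
  cell_types <- cell_types %||% sort(unique(cd$cell_type))
  out <- list()
  for (tt in cell_types) {
    bcs <- rownames(cd)[cd$cell_type == tt]
    sub <- cd[bcs, , drop = FALSE]
    n_per_tissue <- vapply(c("blood", "tumor"), function(tis) {
      length(unique(sub$sample_id[sub$tissue == tis]))
    }, integer(1))
    if (any(n_per_tissue < 2)) {
      warning("cell type '", tt, "' lacks >= 2 samples in both tissues; ",
              "skipped", call. = FALSE)
      next
    }
    out[[tt]] <- run_de(m, cell_subset = bcs, cfg = cfg)
  }
  if (!length(out)) stop("no cell type was analyzable", call. = FALSE)
  out
}

#' Identify background tissue signatures shared by all cell types
#'
#' Ambient mRNA released during tissue dissociation contaminates droplets
#' of every cell type alike, so artifactual tissue signatures show up as
#' genes consistently differentially expressed in the same direction across
#' ALL analyzed cell types. A gene is tumor-associated iff in every cell
#' type's table it is present with raw p < `sig_p` and log2FC > 0;
#' blood-associated analogously with log2FC < 0. A gene absent from any
#' type's tested universe is not flagged. Raw (not FDR-adjusted) p-values
#' are used at this step; the intersection across all types provides the
#' multiplicity control.
#'
#' @param results Named list of DE tables from [per_celltype_de()]
#'   (>= 2 entries).
#' @param sig_p Raw p-value cutoff (default 0.05).
#' @return Object of class `tissue_signature`: list with
#'   `tumor_associated`, `blood_associated` (sorted gene ids) and
#'   `per_celltype_evidence` (gene, cell_type, log2fc, p for every flagged
#'   gene in every type).
#' @export
identify_background <- function(results, sig_p = 0.05) {
  if (!length(results)) stop("empty results map", call. = FALSE)
  if (length(results) < 2) {
    stop("need >= 2 cell types to identify shared signatures", call. = FALSE)
  }
  check_prob(sig_p, "sig_p")
  shared <- Reduce(intersect, lapply(results, function(d) d$gene))
  flag <- function(direction) {
    hits <- shared
    for (d in results) {
      rows <- d[match(hits, d$gene), ]
      ok <- rows$p < sig_p & (if (direction > 0) rows$log2fc > 0
                              else rows$log2fc < 0)
      hits <- hits[ok]
      if (!length(hits)) break
    }
    sort(hits)
  }
  tumor_assoc <- flag(+1)
  blood_assoc <- flag(-1)
  flagged <- c(tumor_assoc, blood_assoc)
  evidence <- do.call(rbind, lapply(names(results), function(tt) {
    d <- results[[tt]]
    rows <- d[d$gene %in% flagged, c("gene", "log2fc", "p")]
    if (!nrow(rows)) return(NULL)
    cbind(rows[1], cell_type = tt, rows[-1])
  }))
  if (is.null(evidence)) {
    evidence <- data.frame(gene = character(), cell_type = character(),
                           log2fc = numeric(), p = numeric())
  }
  structure(list(tumor_associated = tumor_assoc,
                 blood_associated = blood_assoc,
                 per_celltype_evidence = evidence),
            class = "tissue_signature")
}

#' Combined exclusion list for the final DE pass
#'
#' Union of the tumor-associated and blood-associated background signatures
#' with an externally supplied platelet gene list, deduplicated and sorted.
#'
#' @param sig A `tissue_signature`.
#' @param platelet_list Character vector of platelet-associated gene ids
#'   (default empty).
#' @return Sorted character vector.
#' @export
final_exclusion_list <- function(sig, platelet_list = character()) {
  stopifnot(inherits(sig, "tissue_signature"))
  sort(unique(c(sig$tumor_associated, sig$blood_associated, platelet_list)))
}

#' Write a tissue signature to disk
#'
#' Emits one-symbol-per-line text files for the two gene sets and a CSV
#' evidence table.
#'
#' @param sig A `tissue_signature`.
#' @param dir_path Output directory.
#' @return `dir_path`, invisibly.
#' @export
write_tissue_signature <- function(sig, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  writeLines(sig$tumor_associated,
             file.path(dir_path, "tumor_associated.txt"))
  writeLines(sig$blood_associated,
             file.path(dir_path, "blood_associated.txt"))
  write.csv(sig$per_celltype_evidence,
            file.path(dir_path, "background_evidence.csv"), row.names = FALSE)
  invisible(dir_path)
}
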