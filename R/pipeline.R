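#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, collects every validation error before
#' reporting, and injects documented defaults for omitted fields (e.g. the
#' DE threshold 0.58, FDR level 0.01, abundance cuts 0.05 / 3).
#'
#' @param path YAML file. Top-level keys: either `simulate` (a list of
#'   [sim_config()] arguments) or `dataset` (`dir_path`, `meta_path`);
#'   optional `qc` (per-tissue threshold lists), `de` (de_config fields),
#'   `abundance` (`alpha`, `fc_cut`), `gene_sets`, `platelet_list`,
#'   `orthologue_map` (paths), `output_dir`, `seed`.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("unreadable config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  if (is.null(cfg$simulate) && is.null(cfg$dataset)) {
    note("one of 'simulate' or 'dataset' is required")
  }
  if (!is.null(cfg$dataset)) {
    for (f in c("dir_path", "meta_path")) {
      if (is.null(cfg$dataset[[f]])) {
        note(sprintf("dataset.%s is required", f))
      } else if (!file.exists(cfg$dataset[[f]])) {
        note(sprintf("dataset.%s does not exist: %s", f, cfg$dataset[[f]]))
      }
    }
  }
  de <- cfg$de %||% list()
  de$lfc_threshold <- de$lfc_threshold %||% 0.58
  de$alpha <- de$alpha %||% 0.01
  de$min_cells_expressing <- de$min_cells_expressing %||% 10
  de$min_count <- de$min_count %||% 1
  if (de$alpha <= 0 || de$alpha >= 1) note("de.alpha must lie in (0, 1)")
  if (de$lfc_threshold < 0) note("de.lfc_threshold must be >= 0")
  cfg$de <- de

  ab <- cfg$abundance %||% list()
  ab$alpha <- ab$alpha %||% 0.05
  ab$fc_cut <- ab$fc_cut %||% 3
  if (ab$alpha <= 0 || ab$alpha >= 1) note("abundance.alpha must lie in (0, 1)")
  if (ab$fc_cut <= 0) note("abundance.fc_cut must be > 0")
  cfg$abundance <- ab

  bg <- cfg$background %||% list()
  bg$sig_p <- bg$sig_p %||% 0.05
  if (bg$sig_p <= 0 || bg$sig_p > 1) note("background.sig_p must lie in (0, 1]")
  cfg$background <- bg

  for (f in c("gene_sets", "platelet_list", "orthologue_map")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      note(sprintf("%s does not exist: %s", f, cfg[[f]]))
    }
  }
  cfg$output_dir <- cfg$output_dir %||% "tilcompare_out"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full tumor-versus-blood comparison workflow
#'
#' Stage order follows the study design: ingest/QC (or simulation), DE
#' within each major cell type, identification and removal of background
#' tissue signatures, a repeated final DE pass with the exclusion list,
#' abundance classification, marker/relatedness signatures, and (when an
#' orthologue map and second dataset are available) cross-species
#' conservation. Each stage writes CSV outputs under a named subdirectory
#' of `output_dir`; a JSON manifest records the seed, thresholds and
#' per-stage row counts. Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param cfg A `pipeline_config` from [validate_config()], or a path to a
#'   YAML file.
#' @return The output directory, invisibly.
#' @export
run_full <- function(cfg) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(packageVersion("tilcompare")),
                   seed = cfg$seed, de = cfg$de, abundance = cfg$abundance,
                   background = cfg$background, stages = list())
  stage <- function(name, expr) {
    til_log("stage ", name, " starting")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## -- ingest / simulate ----------------------------------------------------
  truth <- NULL; pair <- NULL
  m <- stage("ingest", {
    if (!is.null(cfg$simulate)) {
      sc_args <- cfg$simulate
      sc_args$seed <- sc_args$seed %||% cfg$seed
      sc <- do.call(sim_config, sc_args)
      if (!is.null(cfg$orthologue_map) || isTRUE(cfg$simulate_species_pair)) {
        pair <- simulate_species_pair(sc)
        truth <- pair$truth
        pair$matrix_a
      } else {
        sim <- simulate_dataset(sc)
        truth <- sim$truth
        sim$matrix
      }
    } else {
      read_10x(cfg$dataset$dir_path, cfg$dataset$meta_path)
    }
  })
  m <- stage("qc", {
    if (!is.null(cfg$qc)) {
      per_tissue <- lapply(c(blood = "blood", tumor = "tumor"), function(tis) {
        th <- cfg$qc[[tis]]
        if (is.null(th)) return(NULL)
        do.call(qc_thresholds, th)
      })
      parts <- lapply(names(per_tissue), function(tis) {
        sub <- m[, SummarizedExperiment::colData(m)$tissue == tis]
        if (is.null(per_tissue[[tis]])) sub
        else apply_qc(sub, per_tissue[[tis]],
                      mito_genes = cfg$mito_genes %||% character())
      })
      do.call(cbind, parts)
    } else m
  })
  dcfg <- de_config(cfg$de$lfc_threshold, cfg$de$alpha,
                    cfg$de$min_cells_expressing, cfg$de$min_count)

  ## -- per-cell-type DE and background signature ----------------------------
  bg_dir <- file.path(out, "background")
  per_ct <- stage("per_celltype_de",
                  suppressWarnings(per_celltype_de(m, cfg = dcfg)))
  sig <- stage("background", {
    s <- identify_background(per_ct, sig_p = cfg$background$sig_p)
    write_tissue_signature(s, bg_dir)
    s
  })
  platelets <- if (!is.null(cfg$platelet_list)) {
    readLines(cfg$platelet_list)
  } else character()
  excl <- final_exclusion_list(sig, platelets)

  ## -- final DE with exclusions ---------------------------------------------
  de_dir <- file.path(out, "de")
  dir.create(de_dir, showWarnings = FALSE)
  de_final <- stage("de", {
    res <- lapply(per_ct_names <- names(per_ct), function(tt) {
      cd <- SummarizedExperiment::colData(m)
      bcs <- rownames(cd)[cd$cell_type == tt]
      run_de(m, cell_subset = bcs, cfg = dcfg, exclude = excl)
    })
    names(res) <- names(per_ct)
    for (tt in names(res)) {
      write.csv(res[[tt]], file.path(de_dir, paste0("de_", tt, ".csv")),
                row.names = FALSE)
    }
    res
  })

  ## -- abundance -------------------------------------------------------------
  ab_dir <- file.path(out, "abundance")
  dir.create(ab_dir, showWarnings = FALSE)
  ab <- stage("abundance", {
    tab <- suppressWarnings(compute_proportions(m))
    cls <- classify_abundance(tab, alpha = cfg$abundance$alpha,
                              fc_cut = cfg$abundance$fc_cut)
    write.csv(tab$table, file.path(ab_dir, "proportions.csv"),
              row.names = FALSE)
    write.csv(cls, file.path(ab_dir, "abundance_classes.csv"),
              row.names = FALSE)
    cls
  })

  ## -- signatures ------------------------------------------------------------
  sig_dir <- file.path(out, "signatures")
  dir.create(sig_dir, showWarnings = FALSE)
  stage("signatures", {
    nm <- normalize_counts(m)
    mk <- find_markers(nm, "cell_type")
    write.csv(mk, file.path(sig_dir, "markers.csv"), row.names = FALSE)
    if (!is.null(cfg$gene_sets)) {
      sets <- read_gene_sets(cfg$gene_sets)
      scores <- lapply(sets, function(gs) {
        suppressWarnings(module_score(nm, gs, seed = cfg$seed))$score
      })
      sc <- data.frame(barcode = colnames(m), scores, check.names = FALSE)
      write.csv(sc, file.path(sig_dir, "module_scores.csv"),
                row.names = FALSE)
    }
    pb <- aggregate_pseudobulk(m, c("sample_id", "tissue", "cell_type"))
    grp <- SummarizedExperiment::colData(pb)$cell_type
    if (length(unique(grp)) >= 3) {
      dend <- relatedness_dendrogram(pb, grp)
      writeLines(dend$newick, file.path(sig_dir, "relatedness.nwk"))
      write.csv(dend$dist, file.path(sig_dir, "relatedness_dist.csv"))
    }
    NULL
  })

  ## -- cross-species ---------------------------------------------------------
  cs_dir <- file.path(out, "cross_species")
  if (!is.null(pair) || !is.null(cfg$orthologue_map)) {
    stage("cross_species", {
      dir.create(cs_dir, showWarnings = FALSE)
      if (!is.null(pair)) {
        omap <- map_orthologues(pair$orthologues)
        ct <- names(per_ct)[1]
        res <- cross_species_de(pair$matrix_a, pair$matrix_b, ct, dcfg)
        rec <- classify_conservation(res$de_a, res$de_b, omap,
                                     res$universe_a, res$universe_b)
        summ <- conservation_summary(rec)
        write.csv(rec, file.path(cs_dir, "conservation_records.csv"),
                  row.names = FALSE)
        write.csv(summ$scatter, file.path(cs_dir, "scatter.csv"),
                  row.names = FALSE)
        write.csv(data.frame(class = names(summ$counts),
                             count = as.integer(summ$counts)),
                  file.path(cs_dir, "class_counts.csv"), row.names = FALSE)
      }
      NULL
    })
  } else {
    til_log("no orthologue map configured; cross-species stage skipped",
            level = "WARN")
    warning("cross-species stage skipped: no orthologue map", call. = FALSE)
  }

  manifest$stages <- list(
    ingest = list(n_genes = nrow(m), n_cells = ncol(m)),
    per_celltype_de = lapply(per_ct, nrow),
    background = list(tumor_associated = length(sig$tumor_associated),
                      blood_associated = length(sig$blood_associated),
                      excluded_total = length(excl)),
    de = lapply(de_final, nrow),
    abundance = list(n_celltypes = nrow(ab)),
    cross_species = if (!is.null(pair)) "run" else "skipped"
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(truth)) {
    saveRDS_free_truth(truth, file.path(out, "ground_truth"))
  }
  invisible(out)
}

#' Per-cell-type DE in two species on their own tested universes
#'
#' Helper for the conservation stage: runs [run_de()] within one cell type
#' in each species and returns both result tables together with the
#' filter-passing gene universes.
#'
#' @param m_a,m_b CountMatrix per species.
#' @param cell_type Cell type to subset in both species.
#' @param cfg `de_config`.
#' @return List: `de_a`, `de_b`, `universe_a`, `universe_b`.
#' @export
cross_species_de <- function(m_a, m_b, cell_type, cfg = de_config()) {
  one <- function(m) {
    cd <- SummarizedExperiment::colData(m)
    bcs <- rownames(cd)[cd$cell_type == cell_type]
    sub <- m[, bcs]
    list(de = run_de(m, cell_subset = bcs, cfg = cfg),
         universe = filter_low_abundance(sub, cfg))
  }
  a <- one(m_a); b <- one(m_b)
  list(de_a = a$de, de_b = b$de, universe_a = a$universe,
       universe_b = b$universe)
}

# Ground truth as plain CSV tables (kept text-only on purpose).
saveRDS_free_truth <- function(truth, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  write.csv(truth$true_de, file.path(dir_path, "true_de.csv"),
            row.names = FALSE)
  writeLines(truth$ambient_gene_ids, file.path(dir_path, "ambient_genes.txt"))
  write.csv(truth$abundance_classes,
            file.path(dir_path, "abundance_classes.csv"), row.names = FALSE)
  invisible(dir_path)
}
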