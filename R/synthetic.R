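#' Configuration for the synthetic two-tissue immune dataset
#'
#' Defines the study design the generator emulates: unpaired blood and tumor
#' samples (defaults 10 and 6, matching the osteosarcoma study design),
#' multiple immune cell types with tissue-dependent composition, and
#' negative-binomial counts with sample-level biological dispersion.
#' Planted structure with known ground truth covers: per-cell-type
#' tumor-vs-blood DE genes, ambient contamination genes mixed into every
#' tumor cell (emulating mRNA released during tissue dissociation and
#' captured in droplets), cell-type abundance shifts including a type absent
#' from blood (mirroring mregDCs), and cell-type marker genes.
#'
#' Counts are generated as a gamma-Poisson hierarchy: each (gene, sample)
#' receives a gamma factor with unit mean and variance `nb_dispersion`, and
#' cells are Poisson given their sample's rate. Marginally each count is
#' negative binomial with variance mu + alpha*mu^2, and pseudobulk sums per
#' (sample, cell type) are exactly NB with dispersion `nb_dispersion` --
#' the model the DE engine assumes.
#'
#' @param n_samples_blood,n_samples_tumor Number of biological samples per
#'   tissue (defaults 10 and 6).
#' @param cell_types data.frame with columns `cell_type`, `blood_weight`,
#'   `tumor_weight`: Dirichlet composition parameters per tissue. A zero
#'   weight plants a tissue-absent ("unique") type. Default: six major
#'   immune types plus an mregDC type absent from blood.
#' @param cells_per_sample Cells drawn per sample (default 1200).
#' @param n_genes Number of genes (default 2000).
#' @param nb_dispersion Biological (between-sample) NB dispersion alpha;
#'   scalar or per-gene vector (default 0.1).
#' @param de_fraction Fraction of genes planted DE per cell type
#'   (default 0.1).
#' @param de_lfc_range Interval of |log2 fold change| for planted effects
#'   (default c(1, 3)); signs are random.
#' @param ambient_genes Number of genes carrying ambient tumor-wide
#'   contamination (default 30).
#' @param contamination_rate Fraction of each tumor cell's library drawn
#'   from the ambient profile (default 0.05).
#' @param absent_celltype Name of the cell type with zero blood weight, or
#'   NA for none. Informational; the weights themselves drive simulation.
#' @param marker_genes_per_type Markers planted per cell type (default 5).
#' @param marker_fold Fold elevation of a marker in its own type (default 8).
#' @param lib_size,lib_sdlog Log-normal library-size model per cell
#'   (defaults 2000 and 0.3).
#' @param species_share,species_divergent,species_private For
#'   [simulate_species_pair()]: fractions of planted responses that are
#'   shared in sign, sign-flipped, or expressed in a single species
#'   (defaults 0.5 / 0.15 / 0.35; must sum to 1).
#' @param n_decoy_pairs Many-to-one decoy orthologue rows added to the map
#'   to exercise 1:1 filtering (default 10).
#' @param seed Master integer seed; split internally into per-purpose
#'   substreams so adding a stage never perturbs earlier draws.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples_blood = 10, n_samples_tumor = 6,
                       cell_types = NULL, cells_per_sample = 1200,
                       n_genes = 2000, nb_dispersion = 0.1,
                       de_fraction = 0.1, de_lfc_range = c(1, 3),
                       ambient_genes = 30, contamination_rate = 0.05,
                       absent_celltype = "mregDC",
                       marker_genes_per_type = 5, marker_fold = 8,
                       lib_size = 2000, lib_sdlog = 0.3,
                       species_share = 0.5, species_divergent = 0.15,
                       species_private = 0.35, n_decoy_pairs = 10,
                       seed = 1L) {
  if (!is.null(cell_types) && !is.data.frame(cell_types)) {
    cell_types <- as.data.frame(cell_types, stringsAsFactors = FALSE)
  }
  if (is.null(cell_types)) {
    cell_types <- data.frame(
      cell_type    = c("CD4_T", "CD8_T", "B_cell", "Monocyte",
                       "Neutrophil", "DC", "mregDC"),
      blood_weight = c(30, 20, 12, 22, 10, 6, 0),
      tumor_weight = c(15, 20, 12, 11, 20, 10, 12),
      stringsAsFactors = FALSE
    )
    if (is.na(absent_celltype) || is.null(absent_celltype)) {
      cell_types <- cell_types[cell_types$cell_type != "mregDC", ]
    }
  }
  stopifnot(all(c("cell_type", "blood_weight", "tumor_weight") %in%
                  names(cell_types)),
            all(cell_types$blood_weight >= 0),
            all(cell_types$tumor_weight >= 0))
  check_prob(de_fraction, "de_fraction")
  check_prob(contamination_rate, "contamination_rate")
  for (f in c(species_share, species_divergent, species_private)) {
    check_prob(f, "species fractions")
  }
  if (abs(species_share + species_divergent + species_private - 1) > 1e-8) {
    stop("species_share + species_divergent + species_private must equal 1",
         call. = FALSE)
  }
  if (ambient_genes >= n_genes) stop("n_genes must exceed ambient_genes",
                                     call. = FALSE)
  if (de_fraction > 0 && de_fraction * n_genes < 1) {
    stop("de_fraction * n_genes < 1: no DE gene can be planted", call. = FALSE)
  }
  structure(list(
    n_samples_blood = n_samples_blood, n_samples_tumor = n_samples_tumor,
    cell_types = cell_types, cells_per_sample = cells_per_sample,
    n_genes = n_genes, nb_dispersion = nb_dispersion,
    de_fraction = de_fraction, de_lfc_range = de_lfc_range,
    ambient_genes = ambient_genes, contamination_rate = contamination_rate,
    absent_celltype = absent_celltype,
    marker_genes_per_type = marker_genes_per_type, marker_fold = marker_fold,
    lib_size = lib_size, lib_sdlog = lib_sdlog,
    species_share = species_share, species_divergent = species_divergent,
    species_private = species_private, n_decoy_pairs = n_decoy_pairs,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Dirichlet draw via normalized gammas; zero weights stay exactly zero.
rdirichlet1 <- function(alpha) {
  x <- numeric(length(alpha))
  pos <- alpha > 0
  x[pos] <- rgamma(sum(pos), shape = alpha[pos], rate = 1)
  x / sum(x)
}

# Planted abundance intent from the Dirichlet weights.
planted_abundance_classes <- function(ct) {
  pb <- ct$blood_weight / sum(ct$blood_weight)
  pt <- ct$tumor_weight / sum(ct$tumor_weight)
  cls <- ifelse(pb == 0 & pt > 0, "unique_tumor",
         ifelse(pt == 0 & pb > 0, "unique_blood",
         ifelse(pt >= 1.5 * pb, "over_tumor",
         ifelse(pb >= 1.5 * pt, "under_tumor", "ns"))))
  data.frame(cell_type = ct$cell_type, class = cls, stringsAsFactors = FALSE)
}

#' Simulate a paired tumor/blood multi-sample count matrix with ground truth
#'
#' See [sim_config()] for the generative model. Fixed seeds give
#' bit-identical output.
#'
#' @param cfg A `sim_config`.
#' @param species Species label stored in the cell metadata.
#' @return A list with `matrix` (a CountMatrix, see [make_count_matrix()])
#'   and `truth`, a ground-truth list with elements `true_de` (gene,
#'   cell_type, log2 fold change for every planted effect),
#'   `ambient_gene_ids`, `abundance_classes`, and `marker_genes`.
#' @export
simulate_dataset <- function(cfg, species = "canine") {
  sim_dataset_impl(cfg, species = species)
}

# Core generator. lfc_override: data.frame(gene, cell_type, lfc) replacing
# the drawn DE truth; zero_genes: ids silenced in every cell (for
# species-private expression); seed_offset shifts the sampling-noise
# substreams (composition, sample effects, cells) but NOT the gene
# architecture, so a paired species shares baseline expression and marker
# structure across orthologues while its noise is independent.
sim_dataset_impl <- function(cfg, species = "canine", lfc_override = NULL,
                             zero_genes = character(), seed_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  types <- cfg$cell_types$cell_type
  n_types <- length(types)
  alpha <- rep_len(cfg$nb_dispersion, cfg$n_genes)

  ## --- substream 1: gene architecture (shared across species) -------------
  arch <- with_seed(derive_seed(cfg$seed, 1L), {
    base_w <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1.25)
    pi_base <- base_w / sum(base_w)
    ## ambient signatures arise from transcripts of non-immune origin, i.e.
    ## genes lowly expressed in the immune cells themselves; planted DE
    ## responses and markers belong on genes the cells actually express,
    ## comfortably above the low-abundance filter.
    lower_half <- genes[rank(base_w, ties.method = "first") <=
                          cfg$n_genes / 2]
    upper_half <- setdiff(genes, lower_half)
    ambient <- sample(lower_half, cfg$ambient_genes)
    eligible <- upper_half
    markers <- lapply(setNames(types, types), function(tt) {
      m <- sample(eligible, min(cfg$marker_genes_per_type, length(eligible)))
      eligible <<- setdiff(eligible, m)
      m
    })
    n_de <- round(cfg$de_fraction * cfg$n_genes)
    de <- lapply(setNames(types, types), function(tt) {
      if (n_de == 0) return(data.frame(gene = character(), lfc = numeric()))
      g <- sample(eligible, min(n_de, length(eligible)))
      lfc <- runif(length(g), cfg$de_lfc_range[1], cfg$de_lfc_range[2]) *
        sample(c(-1, 1), length(g), replace = TRUE)
      data.frame(gene = g, lfc = lfc, stringsAsFactors = FALSE)
    })
    amb_w <- rlnorm(cfg$ambient_genes, 0, 0.5)
    list(pi_base = setNames(pi_base, genes), ambient = ambient,
         markers = markers, de = de,
         amb_profile = setNames(amb_w / sum(amb_w), ambient))
  })
  if (!is.null(lfc_override)) {
    arch$de <- lapply(setNames(types, types), function(tt) {
      d <- lfc_override[lfc_override$cell_type == tt, c("gene", "lfc")]
      rownames(d) <- NULL
      d
    })
  }

  ## expression rate per (gene, cell_type, tissue)
  rate <- function(tt, tissue) {
    r <- arch$pi_base
    r[arch$markers[[tt]]] <- r[arch$markers[[tt]]] * cfg$marker_fold
    if (tissue == "tumor" && nrow(arch$de[[tt]])) {
      d <- arch$de[[tt]]
      r[d$gene] <- r[d$gene] * 2^d$lfc
    }
    r[zero_genes] <- 0
    r
  }

  ## --- substream 2: sample composition ------------------------------------
  samples <- data.frame(
    sample_id = c(sprintf("%s_blood_s%02d", species, seq_len(cfg$n_samples_blood)),
                  sprintf("%s_tumor_s%02d", species, seq_len(cfg$n_samples_tumor))),
    tissue = rep(c("blood", "tumor"),
                 c(cfg$n_samples_blood, cfg$n_samples_tumor)),
    stringsAsFactors = FALSE
  )
  comp <- with_seed(derive_seed(cfg$seed, 2L + seed_offset), {
    vapply(seq_len(nrow(samples)), function(i) {
      w <- if (samples$tissue[i] == "blood") cfg$cell_types$blood_weight
           else cfg$cell_types$tumor_weight
      p <- rdirichlet1(w)
      as.numeric(stats::rmultinom(1, cfg$cells_per_sample, p))
    }, numeric(n_types))
  })
  comp <- matrix(comp, nrow = nrow(samples), ncol = n_types, byrow = TRUE,
                 dimnames = list(samples$sample_id, types))

  ## --- substream 3: sample-level gamma factors (biological dispersion) ----
  gam <- with_seed(derive_seed(cfg$seed, 3L + seed_offset), {
    g <- matrix(1, cfg$n_genes, nrow(samples),
                dimnames = list(genes, samples$sample_id))
    pos <- alpha > 0
    if (any(pos)) {
      sh <- 1 / alpha[pos]
      g[pos, ] <- matrix(rgamma(sum(pos) * nrow(samples),
                                shape = sh, rate = sh),
                         sum(pos), nrow(samples))
    }
    g
  })

  ## --- substream 4: cells -------------------------------------------------
  mats <- with_seed(derive_seed(cfg$seed, 4L + seed_offset), {
    blocks <- vector("list", nrow(samples))
    metas <- vector("list", nrow(samples))
    amb <- setNames(numeric(cfg$n_genes), genes)
    amb[names(arch$amb_profile)] <- arch$amb_profile
    for (i in seq_len(nrow(samples))) {
      sid <- samples$sample_id[i]; tissue <- samples$tissue[i]
      n_cells <- sum(comp[i, ])
      libs <- rlnorm(n_cells, log(cfg$lib_size), cfg$lib_sdlog)
      ct_of_cell <- rep(types, comp[i, ])
      mu <- matrix(0, cfg$n_genes, n_cells)
      for (tt in types[comp[i, types] > 0]) {
        idx <- which(ct_of_cell == tt)
        r <- rate(tt, tissue) * gam[, sid]
        if (tissue == "tumor" && cfg$contamination_rate > 0) {
          r <- (1 - cfg$contamination_rate) * r + cfg$contamination_rate * amb
        }
        mu[, idx] <- outer(r, libs[idx])
      }
      cnt <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
      blocks[[i]] <- Matrix::Matrix(cnt, sparse = TRUE)
      metas[[i]] <- data.frame(
        barcode = sprintf("%s_c%05d", sid, seq_len(n_cells)),
        sample_id = sid, tissue = tissue, cell_type = ct_of_cell,
        species = species, stringsAsFactors = FALSE
      )
    }
    list(counts = do.call(cbind, blocks), meta = do.call(rbind, metas))
  })
  counts <- mats$counts
  rownames(counts) <- genes
  colnames(counts) <- mats$meta$barcode
  rownames(mats$meta) <- mats$meta$barcode

  true_de <- do.call(rbind, lapply(types, function(tt) {
    d <- arch$de[[tt]]
    if (!nrow(d)) return(NULL)
    data.frame(gene = d$gene, cell_type = tt, lfc = d$lfc,
               stringsAsFactors = FALSE)
  }))
  if (is.null(true_de)) {
    true_de <- data.frame(gene = character(), cell_type = character(),
                          lfc = numeric(), stringsAsFactors = FALSE)
  }
  truth <- list(
    true_de = true_de,
    ambient_gene_ids = if (cfg$contamination_rate > 0) arch$ambient
                       else character(),
    abundance_classes = planted_abundance_classes(cfg$cell_types),
    marker_genes = arch$markers
  )
  list(matrix = make_count_matrix(counts, mats$meta), truth = truth)
}

#' Simulate a two-species dataset pair with a 1:1 orthologue map
#'
#' Species A ("canine") is generated by [simulate_dataset()]; species B
#' ("human") reuses the same architecture with renamed gene identifiers.
#' Planted DE responses are partitioned into shared (same sign in B),
#' divergent (opposite sign in B) and species-private (the gene is silenced
#' in the other species, so it fails the low-abundance filter there);
#' private responses are split evenly between the two species. The returned
#' orthologue table additionally contains many-to-one decoy rows that a 1:1
#' filter must remove.
#'
#' @param cfg A `sim_config`; `species_share`, `species_divergent`,
#'   `species_private` control the partition.
#' @return A list: `matrix_a`, `matrix_b` (CountMatrix per species),
#'   `truth` (as [simulate_dataset()], plus `true_de_b`,
#'   `shared_response_genes`, `divergent_response_genes`,
#'   `species_private_genes`), and `orthologues` (data.frame
#'   `gene_a`, `gene_b` including decoys).
#' @export
simulate_species_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  a <- simulate_dataset(cfg, species = "canine")
  de_a <- a$truth$true_de
  pool <- unique(de_a$gene)

  plan <- with_seed(derive_seed(cfg$seed, 50L), {
    n <- length(pool)
    cls <- sample(rep(c("shared", "divergent", "private"),
                      round(n * c(cfg$species_share, cfg$species_divergent,
                                  cfg$species_private)))[seq_len(n)])
    cls[is.na(cls)] <- "shared"
    priv <- pool[cls == "private"]
    priv_a <- priv[seq_len(length(priv)) %% 2 == 1]   # silenced in B
    priv_b <- setdiff(priv, priv_a)                   # silenced in A, DE in B
    non_de <- setdiff(sprintf("gene%04d", seq_len(cfg$n_genes)), pool)
    decoys <- sample(non_de, min(cfg$n_decoy_pairs, length(non_de)))
    list(class = setNames(cls, pool), priv_a = priv_a, priv_b = priv_b,
         decoys = decoys)
  })

  ## species B truth: shared keep sign, divergent flip, A-private dropped,
  ## B-private keep (the gene is only expressed in B).
  de_b <- de_a[!(de_a$gene %in% plan$priv_a), ]
  flip <- plan$class[de_b$gene] == "divergent"
  de_b$lfc[flip] <- -de_b$lfc[flip]

  b <- sim_dataset_impl(cfg, species = "human", lfc_override = de_b,
                        zero_genes = plan$priv_a, seed_offset = 200L)
  ## silence B-private genes in species A by rebuilding A with zeroes
  if (length(plan$priv_b)) {
    a <- sim_dataset_impl(cfg, species = "canine",
                          lfc_override = de_a[!(de_a$gene %in% plan$priv_b), ],
                          zero_genes = plan$priv_b, seed_offset = 0L)
    de_a <- a$truth$true_de
  }

  rename <- function(g) sub("^gene", "hgene", g)
  mat_b <- a_to_b_matrix(b$matrix, rename)
  b$truth$true_de$gene <- rename(b$truth$true_de$gene)
  b$truth$ambient_gene_ids <- rename(b$truth$ambient_gene_ids)
  b$truth$marker_genes <- lapply(b$truth$marker_genes, rename)

  ortho <- data.frame(gene_a = sprintf("gene%04d", seq_len(cfg$n_genes)),
                      gene_b = rename(sprintf("gene%04d", seq_len(cfg$n_genes))),
                      stringsAsFactors = FALSE)
  if (length(plan$decoys)) {
    ortho <- rbind(ortho, data.frame(gene_a = plan$decoys,
                                     gene_b = paste0(rename(plan$decoys), "_alt"),
                                     stringsAsFactors = FALSE))
  }

  truth <- a$truth
  truth$true_de_b <- b$truth$true_de
  truth$shared_response_genes <- names(plan$class)[plan$class == "shared"]
  truth$divergent_response_genes <- names(plan$class)[plan$class == "divergent"]
  truth$species_private_genes <- c(plan$priv_a, plan$priv_b)
  list(matrix_a = a$matrix, matrix_b = mat_b, truth = truth,
       orthologues = ortho)
}

a_to_b_matrix <- function(m, rename) {
  counts <- SummarizedExperiment::assay(m, "counts")
  rownames(counts) <- rename(rownames(counts))
  meta <- as.data.frame(SummarizedExperiment::colData(m))
  make_count_matrix(counts, meta)
}

#' Simulate pseudobulk counts directly under the NB model
#'
#' Bypasses the cell level: one NB draw per (gene, unit) with
#' mean = size_factor * q_g * 2^(lfc_g * [unit is tumor]) and dispersion
#' alpha. Used to calibrate and validate the DE engine against a generator
#' matching its own model exactly.
#'
#' @param n_genes Number of genes.
#' @param n_blood,n_tumor Units per condition (defaults 10 and 6).
#' @param dispersion NB dispersion alpha (scalar or per-gene).
#' @param lfc Per-gene true log2 fold change (recycled; default 0).
#' @param base_mean_meanlog,base_mean_sdlog Log-normal model for the
#'   per-gene baseline q (defaults log(100), 1).
#' @param sf_sdlog Log-normal spread of true size factors (default 0.2).
#' @param seed Integer seed.
#' @return List: `pb` (a pseudobulk `SummarizedExperiment` with `tissue`
#'   and `sample_id` in colData), `lfc` (true per-gene log2FC), `q`
#'   (baselines), `size_factors` (true values).
#' @export
simulate_pseudobulk <- function(n_genes, n_blood = 10, n_tumor = 6,
                                dispersion = 0.1, lfc = 0,
                                base_mean_meanlog = log(100),
                                base_mean_sdlog = 1, sf_sdlog = 0.2,
                                seed = 1L) {
  lfc <- rep_len(lfc, n_genes)
  alpha <- rep_len(dispersion, n_genes)
  with_seed(seed, {
    q <- rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog)
    n_units <- n_blood + n_tumor
    sf <- rlnorm(n_units, 0, sf_sdlog)
    tissue <- rep(c("blood", "tumor"), c(n_blood, n_tumor))
    mu <- outer(q, sf) * 2^(lfc %o% as.numeric(tissue == "tumor"))
    counts <- matrix(0L, n_genes, n_units)
    pos <- alpha > 0
    if (any(pos)) {
      counts[pos, ] <- rnbinom(sum(pos) * n_units,
                               size = rep(1 / alpha[pos], n_units),
                               mu = mu[pos, ])
    }
    if (any(!pos)) {
      counts[!pos, ] <- rpois(sum(!pos) * n_units, mu[!pos, ])
    }
    rownames(counts) <- sprintf("gene%04d", seq_len(n_genes))
    colnames(counts) <- sprintf("%s_s%02d", tissue,
                                c(seq_len(n_blood), seq_len(n_tumor)))
    pb <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(sample_id = colnames(counts),
                                     tissue = tissue,
                                     n_cells = rep(NA_integer_, n_units),
                                     row.names = colnames(counts))
    )
    list(pb = pb, lfc = lfc, q = q, size_factors = sf)
  })
}

#' Write a CountMatrix as a 10x-style fixture
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` (optionally
#' gzip-compressed) and `meta.csv` readable by [read_10x()].
#'
#' @param m CountMatrix.
#' @param dir_path Output directory (created if needed).
#' @param gzip Compress the triplet files.
#' @return `dir_path`, invisibly.
#' @export
write_fixture <- function(m, dir_path, gzip = FALSE) {
  counts <- SummarizedExperiment::assay(m, "counts")
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    stop("refusing to write an empty matrix", call. = FALSE)
  }
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir_path, "matrix.mtx")
  Matrix::writeMM(counts, mtx)
  feat <- data.frame(id = rownames(counts), symbol = rownames(counts),
                     type = "Gene Expression")
  write.table(feat, file.path(dir_path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir_path, "barcodes.tsv"))
  if (gzip) {
    for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
      p <- file.path(dir_path, f)
      con <- gzfile(paste0(p, ".gz"), "wb")
      writeLines(readLines(p), con)
      close(con)
      unlink(p)
    }
  }
  meta <- as.data.frame(SummarizedExperiment::colData(m))
  write.csv(meta, file.path(dir_path, "meta.csv"), row.names = FALSE)
  invisible(dir_path)
}
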