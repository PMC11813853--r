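---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tilcompare` compares tumor-infiltrating immune cells with their
circulating counterparts in droplet scRNA-seq data. This vignette explains
the statistical machinery, the parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions taken where
the underlying protocol left choices open.

## Differential expression: pseudobulk NB with an interval null

Single cells from one biological sample are not independent replicates, so
DE is tested on *pseudobulk*: raw counts summed over all cells of the
analyzed cell type within each (sample, tissue) unit. Samples are unpaired
(blood and tumor donors differ), so the design is a two-group comparison
with one column per biological sample.

Counts per gene and unit are modeled as negative binomial,
`Var = mu + alpha * mu^2`, with a log-link GLM on tissue and a
log-size-factor offset. Size factors come from the median-of-ratios
estimator (median over genes, positive in all units, of the count divided
by the gene's geometric mean). Dispersion estimation is a deliberately
simplified DESeq2-style scheme:

1. method-of-moments start on size-factor-normalized counts;
2. gene-wise maximum likelihood on `log(alpha)` with condition-specific
   means, using the Cox–Reid adjusted likelihood (the
   `0.5 * log det(X'WX)` penalty removes most of the downward bias from
   estimating the two group means);
3. a parametric trend `alpha(mu) = a/mu + b` fitted by iterated gamma
   regression with ratio-based outlier exclusion (falling back to a flat
   median trend if the fit degenerates);
4. empirical-Bayes shrinkage: the posterior mode of `log(alpha)` under a
   normal prior centered at the trend. The prior variance is the MAD-based
   spread of gene-wise log residuals minus the expected sampling variance
   `trigamma((m - p)/2)` (m units, p conditions), floored at 0.25.
5. a floor of 1e-8; genes with identical counts in all units sit at the
   floor.

No outlier refitting (Cook's distances) and no independent filtering are
performed: the analysis BH-adjusts across all tested genes. This is the
conservative, fully reproducible choice; the simplification is validated
by parameter-recovery simulations and by agreement with a DESeq2 reference
run on a committed fixture (log2FC within 0.003, 99% call agreement)
rather than by bit-equality.

The test is a Wald test against the interval null `|log2FC| < theta` with
`theta = 0.58` (about 1.5-fold): `W = max(0, (|log2FC| - theta)/SE)` and
`p = 2 * (1 - pnorm(W))`, capped at 1. Estimates inside the null interval
give `W = 0`, `p = 1` exactly; `theta = 0` recovers the ordinary two-sided
test. Significance is BH-adjusted `p < 0.01`. Because the null already
concedes fold changes up to 1.5, the test is conservative for genes with
small true effects — boundary genes (true |log2FC| = 0.58) reject at raw
p < 0.05 in under 5% of cases.

Before testing, the low-abundance filter removes genes seen with a raw
count strictly greater than `min_count = 1` in fewer than
`min_cells_expressing = 10` cells — evaluated on *single-cell* counts over
the analyzed subset, not on pseudobulk sums, and before any exclusion list
is applied.

### Degenerate fits

A gene with all-zero counts in one tissue drives the GLM coefficient to
the boundary; such fits converge to large estimates with very large
standard errors and are effectively never significant. Fits that fail
outright are reported with `p = 1` and an NA standard error (logged).

## Background tissue signatures

Ambient mRNA released during tissue dissociation is captured by droplets
of every cell type alike, producing artifactual "tumor" DE shared across
cell types. The filter runs DE within each major cell type and flags genes
that are significant at *raw* `p < 0.05` with the same direction in
*every* analyzed type; a gene absent from any type's tested universe is
not flagged. Raw rather than FDR-adjusted p-values are used at this step:
the protocol quotes a plain 0.05 cutoff here (reserving FDR < 0.01 for the
main DE), and the intersection across six or more independent tests is
itself a stringent multiplicity control — under independence the expected
false-flag count is `n_genes * 0.05^k * 2`, far below one gene. Flagged
tumor- and blood-associated sets are excluded, together with an externally
supplied platelet list, and DE is rerun. The per-type evidence table is
exposed for inspection; no model-based per-cell decontamination is
attempted.

## Abundance classification

Comparisons use each sample's cell-type percentages within the analyzed
subset. Per type, a two-sided Wilcoxon rank-sum test compares tissues:
exact when the combined sample count is at most 20 with no ties (the
10-vs-6 study scale is in this regime), otherwise the tie- and
continuity-corrected normal approximation. Fully tied inputs carry no
ranking information and return p = 1. The fold change is
`log2((mean%_tumor + pseudo) / (mean%_blood + pseudo))`. The pseudo-floor
default is one cell's worth of percentage, `100 / max_subset_size`, so a
type absent from one tissue yields a finite but exaggerated fold change —
by design it passes the high cut. Classes: `ns` when `p >= 0.05`
regardless of fold change; otherwise `unique_*` when `|log2FC| > 3`,
`over_/under_tumor` when `|log2FC| < 3`. A significant |log2FC| exactly
equal to 3 is not covered by either strict rule; it takes the conservative
over/under label and is flagged in a `boundary` column.

## Module scores, markers, relatedness

Module scoring follows the published binned-control procedure (24 bins of
mean expression, 100 control genes per signature gene, seeded draws).
Signature genes are excluded from their bin's control candidates, so
adding a constant to a cell's signature expression moves its score by
exactly that constant; a self-controlled set scores ~0. Marker detection
is one-vs-rest Wilcoxon on log-normalized expression with Seurat-style
filters (`min_pct = 0.1`, `min_lfc = 0.25`, positive markers only,
`log2((mean(expm1)+1)/(mean(expm1)+1))` fold changes). The relatedness
dendrogram uses Euclidean distances between per-group means of log1p
size-factor-normalized pseudobulk and average linkage; only the distance
was prescribed, so the linkage is a configurable package choice.

Normalization behind all per-cell quantities is counts-per-10k followed by
`log1p`; the protocol did not name its normalization, and this conventional
choice keeps "normalized value > 0" exactly equivalent to "raw count > 0",
which positivity counts rely on.

## Cross-species conservation

Orthologue tables are reduced to strict 1:1 pairs (any symbol on either
side appearing in more than one pair is removed with all its pairs). After
DE per species on each species' filter-passing universe: `conserved` =
significant in at least one species, expressed in both, same direction;
`divergent` = opposite direction; `ambiguous` = significant in exactly one
and not expressed (i.e. failing the low-abundance filter, which subsumes
zero counts) in the other; `ns` = expressed in both, significant in
neither. Pairs significant in neither and missing from one universe are
dropped with a logged count. Headline percentages divide by genes DE in at
least one species (conserved + divergent + ambiguous). A non-significant
partner with |log2FC| <= 1e-9 has no usable direction; such pairs are kept
as conserved but flagged separately rather than silently inflating
divergence.

## The synthetic generator

The generator emulates the study design: 10 blood and 6 tumor samples
(unpaired), ~1200 cells per sample across six major immune types plus an
mregDC-like type with zero blood weight, 2000 genes, log-normal library
sizes (median 2000). Counts follow a gamma–Poisson hierarchy: each
(gene, sample) gets a gamma factor with unit mean and variance
`nb_dispersion` (default 0.1, typical of between-sample biological
variability in pseudobulk), and cells are Poisson given their sample rate.
Pseudobulk sums are then *exactly* NB with dispersion `nb_dispersion` —
the model the DE engine assumes — and single-cell counts are marginally NB
as well. Per-sample composition is Dirichlet-multinomial; a zero Dirichlet
weight plants a tissue-absent type.

Planted structure: per-cell-type DE genes (default 10% of genes,
|log2FC| uniform on [1, 3], random signs) drawn from the upper half of the
baseline-expression distribution — true infiltration responses belong on
genes the cells express, and this keeps them clear of the low-abundance
filter boundary; ambient genes (default 30 at 5% contamination) drawn from
the lower half — ambient signatures originate from non-immune transcripts
the immune cells barely express, which is also what makes them detectable.
Contamination mixes a fixed ambient profile into every tumor cell's rate
with weight `contamination_rate`, identically across cell types — exactly
the signature the background filter's all-types intersection detects. A
paired species shares the gene architecture (orthologues keep baseline
expression and markers) while sampling noise, composition and gamma
factors are independent; planted responses are partitioned into shared
(same sign), divergent (flipped sign) and species-private (the gene is
silenced in the other species), with decoy many-to-one orthologue rows to
exercise the 1:1 filter.

One master seed is split into fixed per-purpose substreams (architecture,
composition, sample effects, cells), so adding a downstream draw never
perturbs earlier ones and equal seeds give bit-identical data.

Not emulated: gene–gene correlation, cell-cycle or doublet structure,
batch effects, UMI saturation. Passing tests therefore demonstrate that
the *statistical rules* behave as specified under the assumed NB model,
not that the pipeline is robust to every artifact of real droplet data.

## Validation scale

The test-suite and acceptance runs use: 2000-gene, 6-vs-10-unit pseudobulk
simulations for calibration and recovery; a fixed 200-gene fixture for the
reference-oracle comparison; full 16-sample, 2000-gene, ~19k-cell datasets
for background-signature recovery; 20 seeded replicates for abundance
rates; and a 2000-orthologue two-species pair (two cell types, 400 cells
per sample) for conservation recovery. These sizes give Monte-Carlo error
well inside the asserted tolerances while keeping a full run in minutes on
one CPU.

## Known limitations

- The dispersion scheme omits DESeq2's outlier refitting and independent
  filtering; very small unit counts (2–3 samples per group) rely heavily
  on the shrinkage prior.
- No log2FC shrinkage (apeglm-style) is applied; reported fold changes are
  MLEs and noisy for weakly expressed genes.
- Only unpaired two-group contrasts are supported; no covariates.
- The abundance classifier inherits Wilcoxon's discreteness at small n:
  with 6 vs 10 samples the attainable significance levels are coarse.
- Orthologue mapping is symbol-level; paralog resolution and expression
  thresholds finer than the low-abundance filter are out of scope.
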