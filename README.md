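# clonotrace

Paired tumour–blood T-cell receptor (TCR) repertoire analysis and an
expression-signature survival biomarker, for single-cell immuno-oncology
studies where a pre-treatment tumour biopsy is matched with serial blood
draws (weeks 0/3/6) from the same patients.

The package is aimed at analysts of 10x V(D)J + 5' expression cohorts
who need, downstream of CellRanger/Seurat:

* **Ingestion and filtering** — parse `filtered_contig_annotations.csv`
  tables, apply gene/UMI/mitochondrial cell QC (biopsy and PBMC
  presets), call clonotypes from productive CDR3 nucleotide sequences
  (paired-chain or any-chain identity), exclude NK/γδ/MAIT
  ("restrictive TCR") cells, and remove clonotypes observed in more
  than one patient.
* **Repertoire diversity** — per sample and per T-cell phenotype:
  clonality `1 − H/ln S` (complement of normalized Shannon evenness),
  richness `S/N`, the Gini index of the clone-size distribution
  `G = Σᵢⱼ|nᵢ − nⱼ| / (2 S² n̄)`, and dominant-clonotype classification
  (≥ 5 cells and/or ≥ 1% of the repertoire).
* **Sharing and tracking** — exact clonotype intersection between a
  patient's tumour and week-0 blood with proportions normalized per
  TCR and per cell on both sides, per-phenotype shared fractions, the
  asymmetric shared-TCR trajectory weight `|K_a ∩ K_b| / |K_a|`, and
  longitudinal tracking of tumour-derived clonotypes through week
  0/3/6 blood.
* **Pseudotime statistics** — exact two-sample Kolmogorov–Smirnov
  comparisons of cell distributions along a supplied pseudotime, and
  binned density / richness / Gini profiles per lineage.
* **Survival biomarker** — built-in 36-gene effector-memory CD8
  (TEMRA) and 16-gene CXCL10⁺ macrophage signatures (52-gene union),
  per-sample ssGSEA scoring of bulk expression, median or maximally
  selected rank-statistic cut-points, Kaplan–Meier curves with median
  survival and the two-group log-rank test.
* **Synthetic cohorts** — a seeded generator
  (`generateCohort()`/`writeCohort()`) producing paired tumour +
  serial-blood clonotype tables with planted, exactly known sharing,
  phenotype structure, pseudotime and a bulk expression + survival
  set, so the full pipeline is testable without restricted patient
  data.

See the vignette (`vignettes/clonotype-sharing-biomarker.Rmd`) for the
models, parameter defaults and design rationale.

## Worked example

```r
library(clonotrace)

coh <- generateCohort(cohortConfig(seed = 42))
cells <- cohortCells(coh)

## per-sample tumour repertoire diversity
tum <- cells[cells$compartment == "tumour", ]
head(repertoireMetricsTable(buildClonotypeTables(tum)))
#>   sample_id n_cells n_clonotypes clonality richness  gini
#> 1   P01_TUM    1000          594    0.0542    0.594 0.352
#> 2   P02_TUM    1000          514    0.0743    0.514 0.418
#> 3   P03_TUM    1000          580    0.0717    0.580 0.368
#> 4   P04_TUM    1000          611    0.0584    0.611 0.344

## tumour-blood sharing, stratified by response
sharing <- baselineSharing(cells)
aggregate(prop_shared_tcrs_blood ~ response, sharing$summary, mean)
#>        response prop_shared_tcrs_blood
#> 1 non_responder                0.00166
#> 2     responder                0.00905

## expression biomarker: score, median split, survival comparison
sc <- ssgseaScores(bulkExpr(coh), builtinSignatures()$combined)
grp <- splitByMedian(sc)
sv <- survivalData(coh)
km <- kmLogrank(sv$pfs_time, sv$pfs_event, grp[sv$sample_id])
km$median
#>      high       low
#> 19.482176  4.987048
km$logrank_p
#> [1] 8.62e-13
```

Each tumour of 1000 T cells resolves into ~500–600 clonotypes (low
clonality, moderate Gini — mildly expanded repertoires). Simulated
responders share ~0.9% of their blood TCRs with the tumour versus
~0.2% in non-responders, and the biomarker-high stratum planted in the
bulk expression shows a median progression-free survival of ~19 vs ~5
months with an overwhelming log-rank separation — the effect sizes the
generator plants, recovered by the pipeline.

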