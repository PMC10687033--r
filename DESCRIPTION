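Package: clonotrace
Title: Paired Tumour-Blood T-Cell Clonotype Sharing, Repertoire Diversity
    and Enrichment-Based Survival Biomarkers
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-cell T-cell receptor (TCR) repertoire analysis
    in paired tumour biopsy and peripheral-blood cohorts: ingestion of 10x
    V(D)J contig tables with productive-chain clonotype calling and cell QC,
    per-sample and per-phenotype repertoire diversity statistics (clonality,
    normalized Shannon evenness, richness, Gini index, dominant-clonotype
    classification), tumour-blood clonotype sharing with longitudinal
    tracking across serial blood draws, pseudotime density comparisons via
    the two-sample Kolmogorov-Smirnov test, and a bulk-expression validation
    pipeline scoring built-in effector-memory CD8 T-cell and inflammatory
    macrophage gene signatures per sample (ssGSEA) with median or maximally
    selected rank-statistic cut-points and Kaplan-Meier / log-rank survival
    comparison. A seeded synthetic-cohort generator with full ground truth
    supports end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    data.table,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, ImmunoOncology, Survival
RoxygenNote: 7.3.3
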