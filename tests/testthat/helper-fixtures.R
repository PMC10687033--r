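# In-code fixtures: toy contig CSVs and hand-built cell tables.

write_toy_contigs <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "barcode,is_cell,chain,cdr3,cdr3_nt,productive,raw_clonotype_id"
  writeLines(c(header, rows), path)
  path
}

# minimal metadata for a set of barcodes in one sample
toy_meta <- function(barcodes, sample_id = "S1", patient_id = "P1",
                     compartment = "tumour", timepoint = "W0",
                     phenotype = "CD8 TEM", response = "responder") {
  data.frame(barcode = barcodes, sample_id = sample_id,
             patient_id = patient_id, compartment = compartment,
             timepoint = timepoint, phenotype = phenotype,
             response = response, pseudotime = NA_real_,
             lineage = NA_character_, stringsAsFactors = FALSE)
}

# hand-built cell table: one row per cell
toy_cells <- function(keys, sample_id = "S1", patient_id = "P1",
                      compartment = "tumour", timepoint = "W0",
                      phenotype = "CD8 TEM", response = "responder",
                      pseudotime = NA_real_, lineage = NA_character_) {
  data.frame(barcode = sprintf("bc%03d", seq_along(keys)),
             sample_id = sample_id, patient_id = patient_id,
             compartment = compartment, timepoint = timepoint,
             phenotype = phenotype, response = response,
             pseudotime = pseudotime, lineage = lineage,
             clonotype_key = keys, stringsAsFactors = FALSE)
}

small_cohort_config <- function(seed = 1, ...) {
  cohortConfig(n_patients = 6, cells_per_tumour = 250,
               cells_per_pbmc = 400, n_samples_bulk = 40,
               n_genes_bulk = 300, seed = seed, ...)
}
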