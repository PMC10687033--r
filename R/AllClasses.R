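#' @import methods
NULL

#' ClonotypeTable: clone-size distribution of one repertoire stratum
#'
#' Holds the clonotype -> cell-count map for one stratum (a sample, or a
#' sample x T-cell-phenotype combination). This is the frequency vector
#' \eqn{p_i = n_i / N} that all repertoire diversity statistics consume.
#'
#' @slot sample_id single sample identifier.
#' @slot phenotype single phenotype label, or \code{NA_character_} when the
#'   stratum is a whole sample.
#' @slot counts named numeric vector of per-clonotype cell counts
#'   \eqn{n_i \ge 1}; names are clonotype keys.
#'
#' @seealso [buildClonotypeTables()], [repertoireMetrics()]
#' @export
setClass("ClonotypeTable",
  representation(
    sample_id = "character",
    phenotype = "character",
    counts    = "numeric"
  ),
  prototype(sample_id = NA_character_, phenotype = NA_character_,
            counts = numeric(0))
)

setValidity("ClonotypeTable", function(object) {
  msg <- character(0)
  cnt <- object@counts
  if (length(object@sample_id) != 1L)
    msg <- c(msg, "sample_id must be length 1")
  if (length(object@phenotype) != 1L)
    msg <- c(msg, "phenotype must be length 1")
  if (length(cnt)) {
    if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
      msg <- c(msg, "counts must be named by non-empty clonotype keys")
    else if (anyDuplicated(names(cnt)))
      msg <- c(msg, "clonotype keys must be unique")
    if (any(cnt < 1) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be integers >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClonotypeTable
#'
#' @param counts named numeric vector of cell counts per clonotype key.
#' @param sample_id sample identifier (default \code{NA}).
#' @param phenotype optional phenotype label for sample x phenotype strata.
#' @return A [ClonotypeTable-class] object.
#' @examples
#' tab <- ClonotypeTable(c(a = 2, b = 1, c = 2), sample_id = "S1")
#' nCells(tab)        # 5
#' nClonotypes(tab)   # 3
#' @export
ClonotypeTable <- function(counts, sample_id = NA_character_,
                           phenotype = NA_character_) {
  new("ClonotypeTable", sample_id = as.character(sample_id),
      phenotype = as.character(phenotype), counts = counts)
}

#' GeneSignature: a named, ordered set of gene symbols
#'
#' @slot name signature name.
#' @slot genes character vector of unique, non-empty gene symbols.
#' @seealso [builtinSignatures()], [ssgseaScores()]
#' @export
setClass("GeneSignature",
  representation(name = "character", genes = "character")
)

setValidity("GeneSignature", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (!length(object@genes) || any(!nzchar(object@genes)))
    msg <- c(msg, "genes must be non-empty symbols")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene symbols must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param genes character vector of unique gene symbols.
#' @return A [GeneSignature-class] object.
#' @export
GeneSignature <- function(name, genes) {
  new("GeneSignature", name = name, genes = as.character(genes))
}

#' CohortConfig: parameters of the synthetic paired tumour/blood cohort
#'
#' Bundles every knob of [generateCohort()]. Defaults emulate the study
#' conditions of an advanced-HCC immunotherapy cohort: paired pre-treatment
#' tumour biopsies with serial week 0/3/6 blood draws, a skewed (Zipf-like)
#' clone-size distribution, response-dependent tumour-to-blood clonotype
#' sharing (2\% of tumour clonotypes seeded into blood for responders vs
#' 0.5\% for non-responders), effector-memory-skewed phenotype mixes in
#' responders, and a bulk expression + survival validation set where a
#' planted "biomarker-high" stratum has signature genes up-shifted and
#' longer exponential survival.
#'
#' @slot n_patients number of patients.
#' @slot frac_responders proportion of patients labelled responder.
#' @slot cells_per_tumour T cells with a productive TCR per tumour biopsy.
#' @slot cells_per_pbmc T cells per blood sample and timepoint.
#' @slot clone_size_alpha exponent of the discrete power-law clone-size
#'   distribution, \eqn{P(k) \propto k^{-\alpha}}; smaller values give
#'   heavier tails (more clonal repertoires).
#' @slot sharing_rate_resp probability a tumour clonotype of a responder is
#'   seeded into that patient's week-0 blood.
#' @slot sharing_rate_nonresp same for non-responders.
#' @slot phenotype_mix_resp named probability vector over phenotype labels
#'   for responder tumours.
#' @slot phenotype_mix_nonresp same for non-responder tumours.
#' @slot pheno_concordance probability a blood cell carrying a
#'   tumour-shared clonotype mirrors the tumour phenotype.
#' @slot persistence probability a blood clonotype persists to the next
#'   timepoint (week 0 to 3, week 3 to 6).
#' @slot n_genes_bulk number of genes in the bulk expression matrix.
#' @slot n_samples_bulk number of bulk samples.
#' @slot signature_shift log-scale mean shift of signature genes in
#'   biomarker-high samples.
#' @slot survival_scale_high,survival_scale_low exponential scales (months)
#'   of progression-free survival in the high / low stratum.
#' @slot censor_rate probability a survival time is censored.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(
    n_patients = "integer", frac_responders = "numeric",
    cells_per_tumour = "integer", cells_per_pbmc = "integer",
    clone_size_alpha = "numeric",
    sharing_rate_resp = "numeric", sharing_rate_nonresp = "numeric",
    phenotype_mix_resp = "numeric", phenotype_mix_nonresp = "numeric",
    pheno_concordance = "numeric", persistence = "numeric",
    n_genes_bulk = "integer", n_samples_bulk = "integer",
    signature_shift = "numeric",
    survival_scale_high = "numeric", survival_scale_low = "numeric",
    censor_rate = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  prop <- c(frac_responders = object@frac_responders,
            sharing_rate_resp = object@sharing_rate_resp,
            sharing_rate_nonresp = object@sharing_rate_nonresp,
            pheno_concordance = object@pheno_concordance,
            persistence = object@persistence,
            censor_rate = object@censor_rate)
  bad <- prop < 0 | prop > 1
  if (any(bad))
    msg <- c(msg, paste0("proportions out of [0,1]: ",
                         paste(names(prop)[bad], collapse = ", ")))
  for (nm in c("n_patients", "cells_per_tumour", "cells_per_pbmc",
               "n_genes_bulk", "n_samples_bulk"))
    if (slot(object, nm) < 1L)
      msg <- c(msg, paste0(nm, " must be a positive count"))
  for (nm in c("phenotype_mix_resp", "phenotype_mix_nonresp")) {
    mix <- slot(object, nm)
    if (is.null(names(mix)) || any(mix < 0) ||
        abs(sum(mix) - 1) > 1e-8)
      msg <- c(msg, paste0(nm, " must be a named distribution summing to 1"))
  }
  if (object@clone_size_alpha <= 0)
    msg <- c(msg, "clone_size_alpha must be positive")
  if (object@survival_scale_high <= 0 || object@survival_scale_low <= 0)
    msg <- c(msg, "survival scales must be positive")
  if (object@cells_per_tumour < length(object@phenotype_mix_resp))
    msg <- c(msg, "cells_per_tumour smaller than the number of phenotypes")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a generated cohort with full ground truth
#'
#' @slot cells data.frame of cell-level records (one row per T cell with a
#'   productive TCR): \code{barcode, sample_id, patient_id, compartment,
#'   timepoint, phenotype, response, pseudotime, lineage, clonotype_key}.
#' @slot bulk_expr nonnegative genes x samples expression matrix.
#' @slot survival data.frame \code{sample_id, arm, os_time, os_event,
#'   pfs_time, pfs_event}.
#' @slot truth list of generating ground truth: per-patient shared clonotype
#'   keys and realized sharing rates, the planted biomarker stratum, and the
#'   response labels actually used.
#' @slot config the [CohortConfig-class] used.
#' @seealso [generateCohort()], [writeCohort()]
#' @export
setClass("SyntheticCohort",
  representation(
    cells = "data.frame", bulk_expr = "matrix", survival = "data.frame",
    truth = "list", config = "CohortConfig"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character(0)
  need <- c("barcode", "sample_id", "patient_id", "compartment", "timepoint",
            "phenotype", "response", "pseudotime", "lineage", "clonotype_key")
  miss <- setdiff(need, names(object@cells))
  if (length(miss))
    msg <- c(msg, paste0("cells missing columns: ",
                         paste(miss, collapse = ", ")))
  sv <- object@survival
  if (nrow(sv) && (any(sv$os_time <= 0) || any(sv$pfs_time <= 0)))
    msg <- c(msg, "survival times must be positive")
  if (any(object@bulk_expr < 0))
    msg <- c(msg, "bulk_expr must be nonnegative")
  if (length(msg)) msg else TRUE
})
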