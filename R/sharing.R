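## Tumour <-> blood clonotype sharing at baseline, per-phenotype shared
## fractions, longitudinal tracking of tumour-derived clonotypes through
## serial blood draws, and the shared-TCR trajectory connection weight.

#' Baseline tumour-blood clonotype sharing per patient
#'
#' For every patient with both a tumour repertoire and a week-0 blood
#' sample, intersects the exact clonotype key sets and reports the shared
#' set with proportions normalized four ways: by unique tumour TCRs, by
#' unique blood TCRs, and by cells (blood and tumour) carrying a shared
#' key. Cross-patient clonotypes should already have been removed (see
#' [dropCrossPatientClonotypes()]).
#'
#' Patients lacking either compartment are omitted with a message. A
#' patient with several tumour biopsies of the same nodule is merged into
#' one tumour repertoire when \code{merge_duplicates} is \code{TRUE}
#' (default); otherwise duplicate samples for one (patient, compartment,
#' timepoint) raise an error.
#'
#' @param cells clonotype-annotated cell data.frame covering tumour and
#'   blood compartments.
#' @param merge_duplicates merge multiple samples per (patient,
#'   compartment, timepoint)?
#' @return list with
#'   \describe{
#'     \item{summary}{data.frame, one row per patient: \code{patient_id,
#'       response, n_shared, n_tcrs_tumour, n_tcrs_blood,
#'       prop_shared_tcrs_tumour, prop_shared_tcrs_blood,
#'       prop_shared_cells_blood, prop_shared_cells_tumour}.}
#'     \item{shared_keys}{named list, patient -> shared clonotype keys.}
#'     \item{per_phenotype_tumour}{named list, patient -> named vector of
#'       per-phenotype shared-cell fractions in the tumour.}
#'   }
#' @export
baselineSharing <- function(cells, merge_duplicates = TRUE) {
  tum <- cells[cells$compartment == "tumour", , drop = FALSE]
  bld <- cells[cells$compartment == "pbmc" &
                 !is.na(cells$timepoint) & cells$timepoint == "W0", ,
               drop = FALSE]
  if (!merge_duplicates) {
    for (d in list(tum, bld)) {
      ns <- tapply(d$sample_id, d$patient_id,
                   function(s) length(unique(s)))
      if (any(ns > 1))
        stop("multiple samples for one (patient, compartment, timepoint); ",
             "set merge_duplicates = TRUE to pool them")
    }
  }
  patients <- sort(unique(cells$patient_id))
  usable <- patients[patients %in% tum$patient_id &
                       patients %in% bld$patient_id]
  skipped <- setdiff(patients, usable)
  if (length(skipped))
    message("omitting patient(s) without paired tumour / week-0 blood: ",
            paste(skipped, collapse = ", "))
  rows <- vector("list", length(usable))
  shared_keys <- stats::setNames(vector("list", length(usable)), usable)
  per_pheno <- shared_keys
  for (i in seq_along(usable)) {
    p <- usable[i]
    tc <- tum[tum$patient_id == p, , drop = FALSE]
    bc <- bld[bld$patient_id == p, , drop = FALSE]
    kt <- unique(tc$clonotype_key)
    kb <- unique(bc$clonotype_key)
    sh <- intersect(kt, kb)
    shared_keys[[i]] <- sh
    per_pheno[[i]] <- phenotypeSharedFraction(tc, sh)
    rows[[i]] <- data.frame(
      patient_id = p,
      response = if ("response" %in% names(tc)) tc$response[1]
                 else NA_character_,
      n_shared = length(sh),
      n_tcrs_tumour = length(kt), n_tcrs_blood = length(kb),
      prop_shared_tcrs_tumour = length(sh) / length(kt),
      prop_shared_tcrs_blood = length(sh) / length(kb),
      prop_shared_cells_blood = mean(bc$clonotype_key %in% sh),
      prop_shared_cells_tumour = mean(tc$clonotype_key %in% sh),
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, rows)
  if (is.null(summary)) summary <- data.frame()
  rownames(summary) <- NULL
  list(summary = summary, shared_keys = shared_keys,
       per_phenotype_tumour = per_pheno)
}

#' Per-phenotype fraction of cells carrying a shared clonotype
#'
#' For each phenotype present in \code{cells}, the fraction of its cells
#' whose clonotype key belongs to \code{shared_keys}. Phenotypes with zero
#' cells are naturally absent.
#'
#' @param cells cell data.frame (typically one patient, one compartment).
#' @param shared_keys character vector of shared clonotype keys.
#' @param compartment optional filter, \code{"tumour"} or \code{"pbmc"}.
#' @return named numeric vector, phenotype -> fraction in [0, 1].
#' @export
phenotypeSharedFraction <- function(cells, shared_keys,
                                    compartment = NULL) {
  if (!is.null(compartment))
    cells <- cells[cells$compartment == compartment, , drop = FALSE]
  if (!nrow(cells)) return(stats::setNames(numeric(0), character(0)))
  hit <- cells$clonotype_key %in% shared_keys
  res <- tapply(hit, cells$phenotype, mean)
  stats::setNames(as.numeric(res), names(res))
}

#' Track tumour-derived clonotypes through serial blood samples
#'
#' Collects the unique clonotype keys of tumour cells with the given
#' source phenotype, then for every blood timepoint counts the blood cells
#' (restricted to \code{denominator_phenotypes}; by default every
#' phenotype whose label starts with "CD8") carrying one of those keys,
#' divided by the timepoint's denominator cell count. Timepoints with no
#' blood sample are absent from the result, not zero.
#'
#' @param tumour_cells tumour-compartment cell data.frame of one patient
#'   (or pooled patients).
#' @param blood_cells blood-compartment cell data.frame spanning one or
#'   more of W0/W3/W6.
#' @param source_phenotype tumour phenotype whose clonotypes are tracked.
#' @param denominator_phenotypes blood phenotypes forming the denominator;
#'   \code{NULL} selects all CD8 phenotypes.
#' @return data.frame, one row per observed timepoint: \code{timepoint,
#'   n_matching, n_total, fraction}, with the tracked keys in attribute
#'   \code{"source_keys"}.
#' @export
trackClonotypes <- function(tumour_cells, blood_cells, source_phenotype,
                            denominator_phenotypes = NULL) {
  valid <- sort(unique(c(tumour_cells$phenotype, blood_cells$phenotype)))
  if (!source_phenotype %in% tumour_cells$phenotype)
    stop("unknown source phenotype ", shQuote(source_phenotype),
         "; valid labels: ", paste(valid, collapse = ", "))
  if (is.null(denominator_phenotypes))
    denominator_phenotypes <- grep("^CD8", valid, value = TRUE)
  bad <- setdiff(denominator_phenotypes, valid)
  if (length(bad))
    stop("unknown denominator phenotype(s) ",
         paste(shQuote(bad), collapse = ", "),
         "; valid labels: ", paste(valid, collapse = ", "))
  keys <- unique(tumour_cells$clonotype_key[
    tumour_cells$phenotype == source_phenotype])
  bd <- blood_cells[blood_cells$phenotype %in% denominator_phenotypes &
                      !is.na(blood_cells$timepoint), , drop = FALSE]
  tps <- intersect(c("W0", "W3", "W6"), unique(bd$timepoint))
  out <- do.call(rbind, lapply(tps, function(tp) {
    d <- bd[bd$timepoint == tp, , drop = FALSE]
    n <- sum(d$clonotype_key %in% keys)
    data.frame(timepoint = tp, n_matching = n, n_total = nrow(d),
               fraction = n / nrow(d), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(timepoint = character(0), n_matching = integer(0),
                      n_total = integer(0), fraction = numeric(0))
  attr(out, "source_keys") <- keys
  out
}

#' Shared-TCR connection weight between two phenotypes
#'
#' The number of unique clonotypes shared by two phenotypes divided by the
#' number of unique clonotypes in the phenotype located first on the
#' trajectory (\code{pheno_a}) - an asymmetric overlap used to weight
#' edges between T-cell states.
#'
#' @param pheno_a [ClonotypeTable-class] of the upstream phenotype.
#' @param pheno_b [ClonotypeTable-class] of the downstream phenotype.
#' @return proportion in [0, 1].
#' @export
sharedTcrWeight <- function(pheno_a, pheno_b) {
  ka <- clonotypeKeys(pheno_a)
  kb <- clonotypeKeys(pheno_b)
  if (!length(ka)) stop("upstream phenotype has no clonotypes")
  length(intersect(ka, kb)) / length(ka)
}
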