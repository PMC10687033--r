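#' @rdname ClonotypeTable-class
#' @param x a \code{ClonotypeTable} (or \code{SyntheticCohort} where noted).
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname ClonotypeTable-class
#' @export
setGeneric("nClonotypes", function(x) standardGeneric("nClonotypes"))

#' @rdname ClonotypeTable-class
#' @export
setGeneric("clonotypeCounts", function(x) standardGeneric("clonotypeCounts"))

#' @rdname ClonotypeTable-class
#' @export
setGeneric("clonotypeFreqs", function(x) standardGeneric("clonotypeFreqs"))

#' @rdname ClonotypeTable-class
#' @export
setGeneric("clonotypeKeys", function(x) standardGeneric("clonotypeKeys"))

#' @rdname GeneSignature-class
#' @param x a \code{GeneSignature}.
#' @export
setGeneric("signatureName", function(x) standardGeneric("signatureName"))

#' @rdname GeneSignature-class
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname SyntheticCohort-class
#' @param x a \code{SyntheticCohort}.
#' @export
setGeneric("cohortCells", function(x) standardGeneric("cohortCells"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("bulkExpr", function(x) standardGeneric("bulkExpr"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

setMethod("nCells", "ClonotypeTable", function(x) sum(x@counts))
setMethod("nClonotypes", "ClonotypeTable", function(x) length(x@counts))
setMethod("clonotypeCounts", "ClonotypeTable", function(x) x@counts)
setMethod("clonotypeFreqs", "ClonotypeTable",
          function(x) x@counts / sum(x@counts))
setMethod("clonotypeKeys", "ClonotypeTable", function(x) names(x@counts))

setMethod("signatureName", "GeneSignature", function(x) x@name)
setMethod("signatureGenes", "GeneSignature", function(x) x@genes)

#' @rdname GeneSignature-class
#' @export
setMethod("length", "GeneSignature", function(x) length(x@genes))

setMethod("cohortCells", "SyntheticCohort", function(x) x@cells)
setMethod("bulkExpr", "SyntheticCohort", function(x) x@bulk_expr)
setMethod("survivalData", "SyntheticCohort", function(x) x@survival)
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
setMethod("nCells", "SyntheticCohort", function(x) nrow(x@cells))

setMethod("show", "ClonotypeTable", function(object) {
  cat("ClonotypeTable for sample", object@sample_id)
  if (!is.na(object@phenotype)) cat(" /", object@phenotype)
  cat("\n ", length(object@counts), "clonotypes,", sum(object@counts),
      "cells; largest clone:",
      if (length(object@counts)) max(object@counts) else 0, "cells\n")
})

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature", shQuote(object@name), "with",
      length(object@genes), "genes\n ",
      paste(utils::head(object@genes, 8), collapse = ", "),
      if (length(object@genes) > 8) "..." else "", "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cfg <- object@config
  cat("SyntheticCohort:", cfg@n_patients, "patients (",
      object@truth$n_responders, "responders ),",
      nrow(object@cells), "cells;",
      nrow(object@bulk_expr), "x", ncol(object@bulk_expr),
      "bulk matrix;", nrow(object@survival), "survival records\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@n_patients, "patients,",
      object@cells_per_tumour, "tumour /", object@cells_per_pbmc,
      "blood cells; alpha =", object@clone_size_alpha,
      "; sharing", object@sharing_rate_resp, "(resp) vs",
      object@sharing_rate_nonresp, "(non-resp); seed", object@seed, "\n")
})
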