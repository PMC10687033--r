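## Per-sample and per-phenotype TCR repertoire diversity statistics:
## clonality (1 - normalized Shannon evenness), richness, Gini index and
## dominant-clonotype classification.

#' Build clonotype tables per sample (and phenotype)
#'
#' Tallies cells into one [ClonotypeTable-class] per sample, or per
#' sample x phenotype stratum. Empty strata are omitted.
#'
#' @param cells cell data.frame carrying \code{clonotype_key} (see
#'   [callClonotypes()]).
#' @param by_phenotype split each sample further by phenotype?
#' @return named list of \code{ClonotypeTable}s; names are
#'   \code{sample_id} or \code{sample_id.phenotype}.
#' @export
buildClonotypeTables <- function(cells, by_phenotype = FALSE) {
  stopifnot("clonotype_key" %in% names(cells))
  f <- if (by_phenotype)
    list(cells$sample_id, cells$phenotype) else list(cells$sample_id)
  strata <- split(cells, f, drop = TRUE, sep = "\r")
  out <- lapply(strata, function(d) {
    cnt <- table(d$clonotype_key)
    ClonotypeTable(stats::setNames(as.numeric(cnt), names(cnt)),
                   sample_id = d$sample_id[1],
                   phenotype = if (by_phenotype) d$phenotype[1]
                               else NA_character_)
  })
  names(out) <- gsub("\r", ".", names(out), fixed = TRUE)
  out
}

#' Normalized Shannon evenness of a repertoire
#'
#' Evenness is the Shannon entropy of the clonotype frequencies divided by
#' its maximum, \eqn{H / \ln S} with \eqn{H = -\sum_i p_i \ln p_i}
#' (natural logarithm). A repertoire with a single clonotype is defined to
#' have evenness 0 (the limit of a two-clone table as one frequency tends
#' to 1), i.e. it is maximally clonal.
#'
#' @param table a [ClonotypeTable-class].
#' @return evenness in [0, 1].
#' @seealso [clonality()]
#' @export
shannonEvenness <- function(table) {
  n <- clonotypeCounts(table)
  if (!length(n)) stop("empty clonotype table")
  S <- length(n)
  if (S == 1L) return(0)
  p <- n / sum(n)
  H <- -sum(p * log(p))
  min(max(H / log(S), 0), 1)
}

#' Clonality of a repertoire
#'
#' Defined as the complement of evenness, \code{1 - shannonEvenness(table)}:
#' 0 for a perfectly even repertoire, 1 for a single expanded clone.
#'
#' @inheritParams shannonEvenness
#' @return clonality in [0, 1].
#' @export
clonality <- function(table) 1 - shannonEvenness(table)

#' Gini index of the clone-size distribution
#'
#' The (uncorrected) Gini coefficient of the clone-size vector,
#' \deqn{G = \sum_i \sum_j |n_i - n_j| / (2 S^2 \bar n),}
#' 0 when all clones are the same size, approaching 1 under extreme
#' expansion. The uncorrected estimator (no \eqn{S/(S-1)} factor) is the
#' default for comparability with the classical inequality-index
#' definition; set \code{corrected = TRUE} for the unbiased version.
#'
#' @inheritParams shannonEvenness
#' @param corrected apply the small-sample \eqn{S/(S-1)} correction?
#' @return Gini index in [0, 1).
#' @export
giniIndex <- function(table, corrected = FALSE) {
  n <- clonotypeCounts(table)
  if (!length(n)) stop("empty clonotype table")
  S <- length(n)
  if (S == 1L) return(0)
  x <- sort(n)
  G <- 2 * sum(seq_len(S) * x) / (S * sum(x)) - (S + 1) / S
  if (corrected) G <- G * S / (S - 1)
  G
}

#' All repertoire diversity metrics for one stratum
#'
#' Bundles clonality, evenness, richness and Gini index with the stratum
#' sizes. Richness is the number of unique clonotypes divided by the
#' number of cells carrying a (productive) TCR, \eqn{S/N};
#' \code{richness_mode = "singleton_cells"} instead divides by the number
#' of cells whose clonotype is a singleton (the alternative reading of
#' "cells with a unique TCR").
#'
#' @inheritParams shannonEvenness
#' @param richness_mode \code{"all_cells"} (default, \eqn{S/N}) or
#'   \code{"singleton_cells"}.
#' @return one-row data.frame: \code{sample_id, phenotype, n_cells,
#'   n_clonotypes, clonality, evenness, richness, gini}.
#' @export
repertoireMetrics <- function(table,
                              richness_mode = c("all_cells",
                                                "singleton_cells")) {
  richness_mode <- match.arg(richness_mode)
  n <- clonotypeCounts(table)
  if (!length(n)) stop("empty clonotype table")
  S <- length(n)
  N <- sum(n)
  ev <- shannonEvenness(table)
  denom <- if (richness_mode == "all_cells") N else sum(n[n == 1])
  data.frame(
    sample_id = table@sample_id, phenotype = table@phenotype,
    n_cells = N, n_clonotypes = S,
    clonality = 1 - ev, evenness = ev,
    richness = if (denom > 0) S / denom else NA_real_,
    gini = giniIndex(table),
    stringsAsFactors = FALSE
  )
}

#' @rdname repertoireMetrics
#' @param tables a list of \code{ClonotypeTable}s, as from
#'   [buildClonotypeTables()].
#' @param ... passed to \code{repertoireMetrics}.
#' @return \code{repertoireMetricsTable}: one row per stratum.
#' @export
repertoireMetricsTable <- function(tables, ...) {
  out <- do.call(rbind, lapply(tables, repertoireMetrics, ...))
  rownames(out) <- NULL
  out
}

#' Classify dominant clonotypes
#'
#' A clonotype is dominant when it is carried by at least \code{min_cells}
#' T cells (\code{rule = "min_cells"}), when it represents at least
#' \code{min_fraction} of the stratum's repertoire
#' (\code{rule = "min_fraction"}), or under either criterion
#' (\code{rule = "either"}).
#'
#' @inheritParams shannonEvenness
#' @param rule dominance rule.
#' @param min_cells cell-count threshold (inclusive).
#' @param min_fraction repertoire-fraction threshold (inclusive).
#' @return named logical vector over clonotype keys.
#' @export
classifyDominant <- function(table,
                             rule = c("min_cells", "min_fraction", "either"),
                             min_cells = 5, min_fraction = 0.01) {
  rule <- match.arg(rule)
  stopifnot(min_cells > 0, min_fraction > 0)
  n <- clonotypeCounts(table)
  by_cells <- n >= min_cells
  by_frac <- n / sum(n) >= min_fraction
  switch(rule,
         min_cells = by_cells,
         min_fraction = by_frac,
         either = by_cells | by_frac)
}
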