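## Bulk-expression validation pipeline: per-sample single-sample gene-set
## enrichment (ssGSEA), median or maximally-selected-rank-statistic
## cut-points on the scores, and Kaplan-Meier / log-rank survival
## comparison of the resulting high/low groups.

#' Read a genes x samples expression matrix
#'
#' Either a TSV whose first column holds gene symbols, or a MatrixMarket
#' triplet file accompanied by row (gene) and column (sample) name files,
#' one name per line.
#'
#' @param path TSV path, or \code{.mtx} path when \code{genes} and
#'   \code{samples} are given.
#' @param genes,samples optional paths to MatrixMarket row/column names.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path, genes = NULL, samples = NULL) {
  if (!is.null(genes) || !is.null(samples)) {
    if (is.null(genes) || is.null(samples))
      stop("MatrixMarket input needs both gene and sample name files")
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(genes); cn <- readLines(samples)
    if (nrow(m) != length(rn) || ncol(m) != length(cn))
      stop("matrix dimensions do not match the name files")
    dimnames(m) <- list(rn, cn)
    return(m)
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a survival table
#'
#' @param path CSV with columns \code{sample_id, arm, os_time, os_event,
#'   pfs_time, pfs_event}.
#' @return data.frame of the six columns.
#' @export
readSurvivalTable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "arm", "os_time", "os_event",
            "pfs_time", "pfs_event")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("survival table lacks column(s): ", paste(miss, collapse = ", "))
  x[need]
}

#' Per-sample single-sample gene-set enrichment (ssGSEA) scores
#'
#' For every sample, genes are ranked by expression (average ranks for
#' ties) and walked in decreasing order; the running-sum statistic is the
#' cumulative weighted empirical CDF of in-set genes (weights
#' \eqn{r^{\tau}} on the expression rank \eqn{r}, largest rank = highest
#' expression, \eqn{\tau} = \code{weight_exponent}) minus the cumulative
#' CDF of out-of-set genes, and the score is the sum of this running
#' difference over all positions. With \code{normalize = TRUE} all scores
#' of the signature are divided by their range across samples.
#'
#' Gene symbols are matched case-insensitively after trimming; signature
#' symbols absent from the matrix are dropped with a warning.
#'
#' @param expr genes x samples numeric matrix with gene rownames.
#' @param signature a [GeneSignature-class].
#' @param weight_exponent rank-weighting exponent \eqn{\tau}.
#' @param normalize divide scores by their cross-sample range?
#' @return data.frame: \code{sample_id, signature, score}.
#' @export
ssgseaScores <- function(expr, signature, weight_exponent = 0.25,
                         normalize = TRUE) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2)
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  sym <- toupper(trimws(rownames(expr)))
  want <- toupper(trimws(signatureGenes(signature)))
  inset <- sym %in% want
  missing <- setdiff(want, sym)
  if (length(missing) == length(want))
    stop("no gene of signature ", shQuote(signatureName(signature)),
         " found in the expression matrix")
  if (length(missing))
    warning(length(missing), " gene(s) of signature ",
            shQuote(signatureName(signature)),
            " absent from the matrix: ",
            paste(missing, collapse = ", "))
  if (all(inset))
    stop("signature covers every gene in the matrix; ",
         "no out-of-set genes to compare against")
  G <- nrow(expr)
  n_out <- sum(!inset)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    e <- expr[, j]
    r <- rank(e)                          # largest rank = most expressed
    ord <- order(e, decreasing = TRUE)
    in_ord <- inset[ord]
    w <- (r[ord]^weight_exponent) * in_ord
    cdf_in <- cumsum(w) / sum(w)
    cdf_out <- cumsum(!in_ord) / n_out
    sum(cdf_in - cdf_out)
  }, numeric(1))
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
    else if (ncol(expr) > 1)
      warning("all scores identical; normalization skipped")
  }
  data.frame(sample_id = colnames(expr),
             signature = signatureName(signature),
             score = scores, stringsAsFactors = FALSE)
}

#' Split samples at the median enrichment score
#'
#' Samples scoring strictly above the median are labelled \code{"high"};
#' scores at or below the median go to \code{"low"} (ties at the median
#' are assigned low, keeping the high group strictly above it).
#'
#' @param scores data.frame from [ssgseaScores()], or a named numeric
#'   vector of per-sample scores.
#' @return named character vector, sample -> \code{"high"}/\code{"low"}.
#' @export
splitByMedian <- function(scores) {
  s <- .asScoreVector(scores)
  if (length(s) < 2) stop("need at least 2 samples")
  if (diff(range(s)) == 0)
    stop("all scores identical; no median split possible")
  med <- stats::median(s)
  stats::setNames(ifelse(s > med, "high", "low"), names(s))
}

.asScoreVector <- function(scores) {
  if (is.data.frame(scores))
    stats::setNames(scores$score, scores$sample_id)
  else scores
}

#' Maximally selected rank-statistic cut-point on survival
#'
#' Scans every observed score whose induced low/high split keeps both
#' groups between \code{min_prop} and \code{max_prop} of the cohort, and
#' for each candidate computes the standardized two-group log-rank
#' statistic \eqn{|O - E| / \sqrt{V}} (hypergeometric variance). The
#' returned cut-point maximizes the standardized statistic; samples with
#' score at or below the cut-point form the low group. No
#' selection-adjusted p-value is computed; compare the resulting groups
#' with [kmLogrank()].
#'
#' @param scores as in [splitByMedian()].
#' @param time,event numeric survival times and 0/1 event indicators,
#'   aligned with \code{scores}.
#' @param min_prop,max_prop admissible group-size range as fractions of n.
#' @return list: \code{cutpoint}, \code{statistic}, and the full
#'   \code{scan} (data.frame \code{candidate, statistic}).
#' @export
maxstatCutpoint <- function(scores, time, event,
                            min_prop = 0.1, max_prop = 0.9) {
  s <- .asScoreVector(scores)
  n <- length(s)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 10 || sum(event) < 1)
    stop("need at least 10 subjects with at least one event")
  cand <- sort(unique(s))
  n_low <- vapply(cand, function(c) sum(s <= c), numeric(1))
  ok <- n_low / n >= min_prop & n_low / n <= max_prop &
    (n - n_low) / n >= min_prop & (n - n_low) / n <= max_prop
  cand <- cand[ok]
  if (!length(cand))
    stop("no admissible cut-point for min_prop = ", min_prop,
         ", max_prop = ", max_prop)
  stat <- vapply(cand, function(c)
    .logrankScore(time, event, s <= c), numeric(1))
  best <- which.max(stat)
  list(cutpoint = cand[best], statistic = stat[best],
       scan = data.frame(candidate = cand, statistic = stat))
}

## standardized two-group log-rank statistic |U|/sqrt(V); g1 is a logical
## group indicator
.logrankScore <- function(time, event, g1) {
  dt <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in dt) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    U <- U + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  abs(U) / sqrt(V)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimate per group (via the survival package), the
#' median survival of each group (smallest time at which the estimate
#' drops to 0.5 or below; \code{NA} when never reached) and the two-group
#' log-rank chi-square with its p-value from a chi-square distribution
#' with one degree of freedom. With no events anywhere the curves stay at
#' 1, medians are absent and the test is the null result (chi2 0, p 1).
#'
#' @param time,event numeric survival times and 0/1 event indicators.
#' @param group vector with exactly two distinct labels.
#' @return list: \code{curves} (data.frame \code{group, time, n_risk,
#'   n_event, surv}), \code{median} (named numeric), \code{logrank_chi2},
#'   \code{logrank_p}, \code{groups}.
#' @export
kmLogrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0)) stop("survival times must be positive")
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2)
    stop("exactly two groups required, got: ", paste(lev, collapse = ", "))
  if (any(vapply(lev, function(l) sum(group == l), numeric(1)) == 0))
    stop("each group needs at least one subject")
  g <- factor(as.character(group), levels = lev)
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  ns <- summary(fit, censored = TRUE)
  curves <- data.frame(
    group = sub("^g=", "", as.character(ns$strata)),
    time = ns$time, n_risk = ns$n.risk, n_event = ns$n.event,
    surv = ns$surv, stringsAsFactors = FALSE)
  ## median = smallest time with S(t) <= 0.5 (no midpoint interpolation
  ## at exact ties, unlike survfit's quantile convention)
  med <- vapply(lev, function(l) {
    cv <- curves[curves$group == l, ]
    hit <- cv$time[cv$surv <= 0.5 + 1e-12]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  if (sum(event) == 0) {
    chi2 <- 0; p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    chi2 <- sd$chisq
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(curves = curves, median = med,
       logrank_chi2 = chi2, logrank_p = p, groups = lev)
}
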