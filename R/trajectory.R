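## Response-stratified statistics along a supplied pseudotime axis:
## two-sample Kolmogorov-Smirnov comparison of cell distributions and
## binned diversity/density profiles. Pseudotime is an input column,
## never inferred here.

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Exact statistic \eqn{D = \sup_t |F_1(t) - F_2(t)|} from a merged-sort
#' sweep of both empirical CDFs (right-continuous; the supremum is taken
#' over the observed points of both samples, so ties are handled
#' exactly). The two-sided p-value uses the asymptotic Kolmogorov
#' distribution with effective size \eqn{n = n_1 n_2 / (n_1 + n_2)}:
#' \deqn{p = 2 \sum_{k \ge 1} (-1)^{k-1} e^{-2 k^2 n D^2}.}
#'
#' @param a,b numeric vectors (e.g. pseudotime values of two groups).
#' @return list with \code{D}, \code{p_value}, \code{n1}, \code{n2}.
#' @examples
#' ksCompare(c(0.1, 0.2), c(0.8, 0.9))  # disjoint supports: D = 1
#' @export
ksCompare <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    stop("samples must be finite and non-missing")
  n1 <- length(a); n2 <- length(b)
  z <- sort(c(a, b))
  D <- max(abs(findInterval(z, sort(a)) / n1 -
                 findInterval(z, sort(b)) / n2))
  n_eff <- n1 * n2 / (n1 + n2)
  p <- if (D == 0) 1 else .kolmogorovQ(sqrt(n_eff) * D)
  list(D = D, p_value = p, n1 = n1, n2 = n2)
}

## upper tail of the Kolmogorov distribution, Q(x) = 2 sum (-1)^(k-1)
## exp(-2 k^2 x^2), clamped to (0, 1]
.kolmogorovQ <- function(x) {
  k <- seq_len(100)
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(q, .Machine$double.xmin), 1)
}

#' Binned pseudotime profile of a repertoire metric
#'
#' Splits the pseudotime range of \code{cells} into \code{n_bins}
#' equal-width bins and computes, per bin, either the cell density
#' (bin count / total), the shared-cell density (restricted to cells
#' whose clonotype key is in \code{shared_keys}, normalized by the total
#' number of such cells), or a repertoire statistic (richness, Gini) on
#' the bin's clonotype table. Bins holding fewer than \code{min_cells}
#' cells are reported with \code{NA} values (absent, not zero).
#'
#' @param cells cell data.frame with finite \code{pseudotime} (and
#'   \code{clonotype_key} for clonotype-based metrics).
#' @param n_bins number of equal-width bins (>= 2).
#' @param metric one of \code{"density"}, \code{"shared_density"},
#'   \code{"richness"}, \code{"gini"}.
#' @param shared_keys clonotype keys defining shared cells (required for
#'   \code{"shared_density"}).
#' @param min_cells minimum bin occupancy below which the bin value is
#'   suppressed.
#' @return data.frame: \code{bin_mid, value, n_cells}, one row per bin.
#' @export
binnedProfile <- function(cells, n_bins = 20,
                          metric = c("density", "shared_density",
                                     "richness", "gini"),
                          shared_keys = NULL, min_cells = 5) {
  metric <- match.arg(metric)
  stopifnot(n_bins >= 2)
  pt <- cells$pseudotime
  if (is.null(pt) || anyNA(pt) || any(!is.finite(pt)))
    stop("cells must carry finite pseudotime")
  if (metric %in% c("richness", "gini") &&
      is.null(cells$clonotype_key))
    stop("metric ", shQuote(metric), " requires clonotype keys")
  if (metric == "shared_density" && is.null(shared_keys))
    stop("shared_density requires shared_keys")
  rng <- range(pt)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(pt, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  n_shared_total <- if (metric == "shared_density")
    sum(cells$clonotype_key %in% shared_keys) else NA_integer_
  out <- lapply(seq_len(n_bins), function(i) {
    d <- cells[bin == i, , drop = FALSE]
    n <- nrow(d)
    value <- if (n < min_cells) NA_real_ else switch(metric,
      density = n / nrow(cells),
      shared_density = if (n_shared_total > 0)
        sum(d$clonotype_key %in% shared_keys) / n_shared_total else 0,
      richness = length(unique(d$clonotype_key)) / n,
      gini = giniIndex(ClonotypeTable(
        stats::setNames(as.numeric(table(d$clonotype_key)),
                        names(table(d$clonotype_key))))))
    data.frame(bin_mid = mids[i], value = value, n_cells = n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
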