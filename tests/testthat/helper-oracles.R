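# Independent brute-force oracles. Deliberately literal: loops and direct
# summation, sharing no code with the package implementations they check.

oracle_evenness <- function(counts) {
  S <- length(counts)
  if (S == 1) return(0)
  p <- counts / sum(counts)
  H <- 0
  for (pi in p) H <- H - pi * log(pi)
  H / log(S)
}

oracle_gini <- function(counts) {
  S <- length(counts)
  if (S == 1) return(0)
  tot <- 0
  for (i in seq_len(S)) for (j in seq_len(S))
    tot <- tot + abs(counts[i] - counts[j])
  tot / (2 * S^2 * mean(counts))
}

oracle_ks_D <- function(a, b) {
  best <- 0
  for (t in c(a, b)) {
    d <- abs(mean(a <= t) - mean(b <= t))
    if (d > best) best <- d
  }
  best
}

# literal position-by-position running sum for one sample
oracle_ssgsea_sample <- function(e, inset, tau) {
  r <- rank(e)
  ord <- order(e, decreasing = TRUE)
  num_in <- 0; num_out <- 0
  tot_in <- sum((r^tau)[inset])
  tot_out <- sum(!inset)
  score <- 0
  for (pos in ord) {
    if (inset[pos]) num_in <- num_in + r[pos]^tau
    else num_out <- num_out + 1
    score <- score + num_in / tot_in - num_out / tot_out
  }
  score
}

oracle_ssgsea <- function(expr, inset, tau = 0.25) {
  vapply(seq_len(ncol(expr)),
         function(j) oracle_ssgsea_sample(expr[, j], inset, tau),
         numeric(1))
}

# risk-table log-rank: O, E, V accumulated over distinct event times
oracle_logrank <- function(time, event, g1) {
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chi2 = if (V > 0) (O - E)^2 / V else 0, O = O, E = E, V = V)
}

# product-limit estimate at the sorted distinct times
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# exhaustive maxstat scan through survival::survdiff (independent route)
oracle_maxstat <- function(s, time, event, min_prop = 0.1,
                           max_prop = 0.9) {
  cand <- sort(unique(s))
  n <- length(s)
  out <- data.frame(candidate = numeric(0), statistic = numeric(0))
  for (c in cand) {
    nl <- sum(s <= c)
    if (nl / n < min_prop || nl / n > max_prop ||
        (n - nl) / n < min_prop || (n - nl) / n > max_prop) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ I(s <= c))
    out <- rbind(out, data.frame(candidate = c,
                                 statistic = sqrt(sd$chisq)))
  }
  out
}

# random clonotype table for property sweeps
rand_table <- function(max_S = 30, max_n = 20) {
  S <- sample(1:max_S, 1)
  cnt <- sample(1:max_n, S, replace = TRUE)
  names(cnt) <- paste0("k", seq_len(S))
  ClonotypeTable(cnt, sample_id = "S1")
}
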