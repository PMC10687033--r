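## Seeded generator of a full synthetic paired tumour / serial-blood
## cohort with exact ground truth, plus writers/readers that round-trip
## through the package's own file formats. The generator emulates the
## *structure* of a paired single-cell TCR study - skewed clone sizes,
## response-dependent tumour->blood seeding, phenotype-biased expansion,
## clonotype persistence across timepoints, three-lineage pseudotime, and
## a bulk expression + survival validation set - not real transcriptomes.

.phenotypes <- c("CD8 TN", "CD8 TEM", "CD8 TEMRA", "CD8 TEX", "CD8 TRM")
.terminal_lineage <- c("CD8 TEMRA" = "TEMRA", "CD8 TEX" = "TEX",
                       "CD8 TRM" = "TRM")

#' Construct a CohortConfig
#'
#' See [CohortConfig-class] for the meaning of every field. Defaults
#' describe a 20-patient cohort (60\% responders, matching a 12-vs-8
#' response split), 1000 tumour and 2000 blood T cells per sample, Zipf
#' clone sizes with exponent 2.5, tumour-to-blood sharing rates of 2\%
#' (responders) vs 0.5\% (non-responders), TEMRA-skewed responder
#' phenotype mixes, 80\% clonotype persistence between blood draws, and a
#' 120-sample bulk set with a one-log-unit signature shift and 24- vs
#' 6-month exponential PFS scales.
#'
#' @param n_patients,frac_responders,cells_per_tumour,cells_per_pbmc see
#'   [CohortConfig-class].
#' @param clone_size_alpha,sharing_rate_resp,sharing_rate_nonresp see
#'   [CohortConfig-class].
#' @param phenotype_mix_resp,phenotype_mix_nonresp named distributions
#'   over phenotype labels.
#' @param pheno_concordance,persistence see [CohortConfig-class].
#' @param n_genes_bulk,n_samples_bulk,signature_shift see
#'   [CohortConfig-class].
#' @param survival_scale_high,survival_scale_low,censor_rate,seed see
#'   [CohortConfig-class].
#' @return a validated [CohortConfig-class].
#' @export
cohortConfig <- function(n_patients = 20, frac_responders = 0.6,
                         cells_per_tumour = 1000, cells_per_pbmc = 2000,
                         clone_size_alpha = 2.5,
                         sharing_rate_resp = 0.02,
                         sharing_rate_nonresp = 0.005,
                         phenotype_mix_resp = c("CD8 TN" = 0.15,
                                                "CD8 TEM" = 0.25,
                                                "CD8 TEMRA" = 0.30,
                                                "CD8 TEX" = 0.20,
                                                "CD8 TRM" = 0.10),
                         phenotype_mix_nonresp = c("CD8 TN" = 0.20,
                                                   "CD8 TEM" = 0.40,
                                                   "CD8 TEMRA" = 0.05,
                                                   "CD8 TEX" = 0.25,
                                                   "CD8 TRM" = 0.10),
                         pheno_concordance = 0.8, persistence = 0.8,
                         n_genes_bulk = 2000, n_samples_bulk = 120,
                         signature_shift = 1.0,
                         survival_scale_high = 24,
                         survival_scale_low = 6,
                         censor_rate = 0.2, seed = 1L) {
  new("CohortConfig",
      n_patients = as.integer(n_patients),
      frac_responders = frac_responders,
      cells_per_tumour = as.integer(cells_per_tumour),
      cells_per_pbmc = as.integer(cells_per_pbmc),
      clone_size_alpha = clone_size_alpha,
      sharing_rate_resp = sharing_rate_resp,
      sharing_rate_nonresp = sharing_rate_nonresp,
      phenotype_mix_resp = phenotype_mix_resp,
      phenotype_mix_nonresp = phenotype_mix_nonresp,
      pheno_concordance = pheno_concordance,
      persistence = persistence,
      n_genes_bulk = as.integer(n_genes_bulk),
      n_samples_bulk = as.integer(n_samples_bulk),
      signature_shift = signature_shift,
      survival_scale_high = survival_scale_high,
      survival_scale_low = survival_scale_low,
      censor_rate = censor_rate,
      seed = as.integer(seed))
}

## truncated discrete power law: P(k) proportional to k^(-alpha), k <= kmax
.rzipf <- function(n, alpha, kmax) {
  if (n == 0) return(integer(0))
  k <- seq_len(kmax)
  sample.int(kmax, n, replace = TRUE, prob = k^(-alpha))
}

## clone sizes summing exactly to n_cells
.cloneSizes <- function(n_cells, alpha, kmax) {
  if (n_cells <= 0) return(integer(0))
  sizes <- integer(0)
  while (sum(sizes) < n_cells)
    sizes <- c(sizes, .rzipf(max(64, ceiling(n_cells / 4)), alpha, kmax))
  cs <- cumsum(sizes)
  k <- which(cs >= n_cells)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cs[k] - n_cells)
  sizes[sizes > 0]
}

## n CDR3 nucleotide strings, globally unique within a cohort: the first
## 12 nt encode a running counter in base 4 (A/C/G/T digits), the
## remainder (21-33 nt, keeping total length a multiple of 3) is random
.randCDR3 <- function(n, pool_env) {
  if (n == 0) return(character(0))
  ids <- pool_env$counter + seq_len(n) - 1L
  pool_env$counter <- pool_env$counter + n
  digits <- matrix("A", nrow = n, ncol = 12)
  nt <- c("A", "C", "G", "T")
  v <- ids
  for (d in 12:1) {
    digits[, d] <- nt[v %% 4L + 1L]
    v <- v %/% 4L
  }
  prefix <- do.call(paste0, asplit(digits, 2))
  len <- sample(seq(21, 33, by = 3), n, replace = TRUE)
  rest <- character(n)
  for (L in unique(len)) {
    idx <- which(len == L)
    chars <- matrix(sample(nt, length(idx) * L, replace = TRUE),
                    nrow = length(idx))
    rest[idx] <- do.call(paste0, asplit(chars, 2))
  }
  paste0(prefix, rest)
}

## n clonotype keys (sorted TRA/TRB CDR3nt pairs, "_"-joined)
.makeKeys <- function(n, pool_env) {
  cdr3 <- .randCDR3(2 * n, pool_env)
  a <- cdr3[seq_len(n)]
  b <- cdr3[n + seq_len(n)]
  ifelse(a < b, paste(a, b, sep = "_"), paste(b, a, sep = "_"))
}

#' Generate a synthetic paired tumour/blood cohort with ground truth
#'
#' Fully deterministic given \code{config@seed}. Per patient: tumour
#' clone sizes are drawn from a truncated discrete power law
#' (\eqn{P(k) \propto k^{-\alpha}}); each tumour clonotype is planted
#' into the patient's week-0 blood with the response-dependent sharing
#' rate (the planted key is identical in both compartments, so ground
#' truth for sharing is exact set membership); planted clonotypes of
#' responders are preferentially labelled TEMRA in both compartments;
#' blood clonotypes persist to weeks 3 and 6 with probability
#' \code{persistence}, topped up with fresh background clonotypes;
#' tumour cells get a lineage (terminal phenotypes map to their own
#' lineage, naive/effector-memory cells sit on the shared trunk) and a
#' pseudotime, with responder TEMRA-lineage cells shifted toward the
#' lineage end. Bulk samples in a planted biomarker-high stratum have
#' the 52 built-in signature genes up-shifted by \code{signature_shift}
#' (log scale) and draw exponential survival times with the longer
#' scale; times are censored at rate \code{censor_rate}.
#'
#' @param config a [CohortConfig-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(n_patients = 4,
#'                                    cells_per_tumour = 200,
#'                                    cells_per_pbmc = 300,
#'                                    n_samples_bulk = 40,
#'                                    n_genes_bulk = 300))
#' coh
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n_pat <- config@n_patients
  n_resp <- round(n_pat * config@frac_responders)
  pids <- sprintf("P%02d", seq_len(n_pat))
  responses <- stats::setNames(
    rep(c("responder", "non_responder"), c(n_resp, n_pat - n_resp)), pids)
  pool <- new.env(parent = emptyenv())
  pool$counter <- 0L

  per_patient <- vector("list", n_pat)
  truth_pat <- stats::setNames(vector("list", n_pat), pids)
  for (i in seq_len(n_pat)) {
    pid <- pids[i]
    resp <- responses[[i]] == "responder"
    mix <- if (resp) config@phenotype_mix_resp
           else config@phenotype_mix_nonresp
    rate <- if (resp) config@sharing_rate_resp
            else config@sharing_rate_nonresp

    ## ---- tumour repertoire
    sizes <- .cloneSizes(config@cells_per_tumour, config@clone_size_alpha,
                         config@cells_per_tumour)
    n_cl <- length(sizes)
    keys <- .makeKeys(n_cl, pool)
    shared <- stats::runif(n_cl) < rate
    ph <- sample(names(mix), n_cl, replace = TRUE, prob = mix)
    if (resp && any(shared)) {
      bias <- stats::runif(sum(shared)) < config@pheno_concordance
      ph[shared][bias] <- "CD8 TEMRA"
    }
    tum <- .expandClones(keys, sizes, ph, pid, paste0(pid, "_TUM"),
                         "tumour", "W0", responses[[i]])
    tum$lineage <- ifelse(tum$phenotype %in% names(.terminal_lineage),
                          .terminal_lineage[tum$phenotype],
                          sample(unname(.terminal_lineage), nrow(tum),
                                 replace = TRUE))
    tum$pseudotime <- .drawPseudotime(tum$phenotype)
    late <- resp & tum$lineage == "TEMRA" & tum$phenotype == "CD8 TEMRA"
    tum$pseudotime[late] <- 1 - (1 - tum$pseudotime[late]) * 0.5

    ## ---- blood, week 0: planted shared clonotypes + background
    planted_keys <- keys[shared]
    planted_ph <- ph[shared]
    mirror <- stats::runif(length(planted_keys)) < config@pheno_concordance
    blood_mix <- mix
    blood_mix["CD8 TEX"] <- 0              # exhausted cells are TME-only
    blood_mix <- blood_mix / sum(blood_mix)
    bph <- ifelse(mirror, planted_ph,
                  sample(names(blood_mix), length(planted_keys),
                         replace = TRUE, prob = blood_mix))
    kmax_b <- max(2L, config@cells_per_pbmc %/% 10L)
    psizes <- .rzipf(length(planted_keys), config@clone_size_alpha, kmax_b)
    budget <- config@cells_per_pbmc - sum(psizes)
    if (budget < 0) {                      # planted clones exceed sample
      psizes <- pmax(1L, psizes %/% 2L)
      budget <- max(0L, config@cells_per_pbmc - sum(psizes))
    }
    bl <- list(keys = planted_keys, sizes = psizes, ph = bph)
    if (budget > 0) {
      bsizes <- .cloneSizes(budget, config@clone_size_alpha, kmax_b)
      bkeys <- .makeKeys(length(bsizes), pool)
      bl$keys <- c(bl$keys, bkeys)
      bl$sizes <- c(bl$sizes, bsizes)
      bl$ph <- c(bl$ph, sample(names(blood_mix), length(bsizes),
                               replace = TRUE, prob = blood_mix))
    }
    samples <- list(tum, .expandClones(bl$keys, bl$sizes, bl$ph, pid,
                                       paste0(pid, "_PB_W0"), "pbmc",
                                       "W0", responses[[i]]))
    shared_at <- list(W0 = planted_keys)

    ## ---- blood, weeks 3 and 6: persistence + fresh background
    prev <- bl
    for (tp in c("W3", "W6")) {
      keep <- stats::runif(length(prev$keys)) < config@persistence
      cur <- list(keys = prev$keys[keep], ph = prev$ph[keep])
      cur$sizes <- .rzipf(length(cur$keys), config@clone_size_alpha,
                          kmax_b)
      budget <- config@cells_per_pbmc - sum(cur$sizes)
      if (budget > 0) {
        bsizes <- .cloneSizes(budget, config@clone_size_alpha, kmax_b)
        bkeys <- .makeKeys(length(bsizes), pool)
        cur$keys <- c(cur$keys, bkeys)
        cur$sizes <- c(cur$sizes, bsizes)
        cur$ph <- c(cur$ph, sample(names(blood_mix), length(bsizes),
                                   replace = TRUE, prob = blood_mix))
      }
      samples <- c(samples, list(
        .expandClones(cur$keys, cur$sizes, cur$ph, pid,
                      paste0(pid, "_PB_", tp), "pbmc", tp,
                      responses[[i]])))
      shared_at[[tp]] <- intersect(planted_keys, cur$keys)
      prev <- cur
    }

    per_patient[[i]] <- data.table::rbindlist(samples)
    truth_pat[[i]] <- list(
      response = responses[[i]],
      shared_keys = planted_keys,
      n_tumour_clonotypes = n_cl,
      realized_sharing = length(planted_keys) / n_cl,
      shared_at = shared_at)
  }
  cells <- as.data.frame(data.table::rbindlist(per_patient))

  ## ---- bulk expression + survival validation set
  bulk <- .generateBulk(config)

  truth <- list(
    response = responses, n_responders = n_resp,
    patients = truth_pat,
    bulk_high = bulk$high_samples,
    signature_genes = bulk$signature_genes)
  new("SyntheticCohort", cells = cells, bulk_expr = bulk$expr,
      survival = bulk$survival, truth = truth, config = config)
}

## one row per cell for a clone-size vector
.expandClones <- function(keys, sizes, ph, pid, sample_id, compartment,
                          timepoint, response) {
  n <- sum(sizes)
  data.frame(
    barcode = sprintf("%s-%05d", sample_id, seq_len(n)),
    sample_id = sample_id, patient_id = pid,
    compartment = compartment, timepoint = timepoint,
    phenotype = rep.int(ph, sizes), response = response,
    pseudotime = NA_real_, lineage = NA_character_,
    clonotype_key = rep.int(keys, sizes),
    stringsAsFactors = FALSE)
}

## stage-dependent pseudotime: naive cells early, effector-memory on the
## trunk, terminal phenotypes in the distal part of their lineage
.drawPseudotime <- function(phenotype) {
  n <- length(phenotype)
  pt <- stats::runif(n, 0.4, 1)
  naive <- phenotype == "CD8 TN"
  em <- phenotype == "CD8 TEM"
  pt[naive] <- stats::runif(sum(naive), 0, 0.25)
  pt[em] <- stats::runif(sum(em), 0.15, 0.5)
  pt
}

.generateBulk <- function(config) {
  sig <- signatureGenes(builtinSignatures()$combined)
  if (config@n_genes_bulk < 2L * length(sig))
    stop("infeasible config: n_genes_bulk must be at least twice the ",
         "combined signature size (", 2L * length(sig), ")")
  genes <- c(sig, sprintf("GENE%05d", seq_len(config@n_genes_bulk -
                                                length(sig))))
  n <- config@n_samples_bulk
  sids <- sprintf("BULK%03d", seq_len(n))
  stratum <- sample(rep(c("high", "low"), length.out = n))
  mu <- stats::rnorm(config@n_genes_bulk, 0, 1)
  loge <- matrix(stats::rnorm(config@n_genes_bulk * n, mu, 1),
                 nrow = config@n_genes_bulk, ncol = n)
  loge[seq_along(sig), stratum == "high"] <-
    loge[seq_along(sig), stratum == "high"] + config@signature_shift
  expr <- exp(loge)
  dimnames(expr) <- list(genes, sids)

  scale <- ifelse(stratum == "high", config@survival_scale_high,
                  config@survival_scale_low)
  pfs <- stats::rexp(n, rate = 1 / scale)
  os <- stats::rexp(n, rate = 1 / (1.5 * scale))
  cens_p <- stats::runif(n) < config@censor_rate
  cens_o <- stats::runif(n) < config@censor_rate
  survd <- data.frame(
    sample_id = sids, arm = "atezo_bev",
    os_time = ifelse(cens_o, os * stats::runif(n), os),
    os_event = as.integer(!cens_o),
    pfs_time = ifelse(cens_p, pfs * stats::runif(n), pfs),
    pfs_event = as.integer(!cens_p),
    stringsAsFactors = FALSE)
  ## guard against numerically zero censored times
  survd$os_time <- pmax(survd$os_time, 1e-6)
  survd$pfs_time <- pmax(survd$pfs_time, 1e-6)
  list(expr = expr, survival = survd,
       high_samples = sids[stratum == "high"], signature_genes = sig)
}

#' Write a synthetic cohort to disk
#'
#' Emits one 10x-dialect contig CSV per sample (under
#' \code{dir/contigs/}), a cell metadata TSV, the bulk expression TSV,
#' the survival CSV and the ground-truth JSON. The files round-trip
#' losslessly through [readContigs()], [readCellMeta()] /
#' [callClonotypes()] and [readCohort()].
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return character vector of the files written (the manifest),
#'   invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "contigs"), recursive = TRUE,
             showWarnings = FALSE)
  cells <- cohortCells(cohort)
  files <- character(0)
  for (sid in unique(cells$sample_id)) {
    d <- cells[cells$sample_id == sid, , drop = FALSE]
    cdr3s <- strsplit(d$clonotype_key, "_", fixed = TRUE)
    nchain <- lengths(cdr3s)
    contig <- data.frame(
      barcode = rep.int(d$barcode, nchain),
      is_cell = "True",
      chain = unlist(lapply(nchain, function(k)
        c("TRA", "TRB", rep("other", max(0, k - 2)))[seq_len(k)])),
      cdr3 = "",
      cdr3_nt = unlist(cdr3s),
      productive = "True",
      raw_clonotype_id = rep.int(match(d$clonotype_key,
                                       unique(d$clonotype_key)), nchain),
      stringsAsFactors = FALSE)
    f <- file.path(dir, "contigs",
                   paste0(sid, "_filtered_contig_annotations.csv"))
    utils::write.csv(contig, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  meta <- cells[setdiff(names(cells), "clonotype_key")]
  f_meta <- file.path(dir, "cells_meta.tsv")
  utils::write.table(meta, f_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  f_bulk <- file.path(dir, "bulk_expr.tsv")
  expr <- bulkExpr(cohort)
  utils::write.table(
    data.frame(gene = rownames(expr), expr, check.names = FALSE),
    f_bulk, sep = "\t", quote = FALSE, row.names = FALSE)
  f_surv <- file.path(dir, "survival.csv")
  utils::write.csv(survivalData(cohort), f_surv, row.names = FALSE,
                   quote = FALSE)
  f_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(cohortTruth(cohort), f_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- c(files, f_meta, f_bulk, f_surv, f_truth)
  invisible(manifest)
}

#' Read a written cohort back through the ingestion pipeline
#'
#' Re-reads every contig CSV and the metadata TSV of a directory written
#' by [writeCohort()], calls clonotypes, and loads the bulk matrix,
#' survival table and truth JSON.
#'
#' @param dir directory written by [writeCohort()].
#' @param identity_mode passed to [callClonotypes()].
#' @return list: \code{cells}, \code{bulk_expr}, \code{survival},
#'   \code{truth}.
#' @export
readCohort <- function(dir, identity_mode = "paired") {
  cfiles <- list.files(file.path(dir, "contigs"),
                       pattern = "_filtered_contig_annotations\\.csv$",
                       full.names = TRUE)
  if (!length(cfiles)) stop("no contig files under ", dir)
  contigs <- data.table::rbindlist(lapply(cfiles, function(f) {
    sid <- sub("_filtered_contig_annotations\\.csv$", "", basename(f))
    readContigs(f, sid)
  }))
  meta <- readCellMeta(file.path(dir, "cells_meta.tsv"))
  cells <- callClonotypes(as.data.frame(contigs), meta,
                          identity_mode = identity_mode)
  list(cells = cells,
       bulk_expr = readExpressionMatrix(file.path(dir, "bulk_expr.tsv")),
       survival = readSurvivalTable(file.path(dir, "survival.csv")),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
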