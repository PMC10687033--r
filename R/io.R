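## Readers for the 10x V(D)J contig dialect, cell metadata and QC tables,
## plus the cell-level filters that turn contigs into analysis-ready
## clonotype-annotated cells.

.meta_cols <- c("barcode", "sample_id", "patient_id", "compartment",
                "timepoint", "phenotype", "response", "pseudotime", "lineage")

## phenotype labels excluded from TCR analysis: cell types whose receptor is
## not a conventional alpha/beta TCR (NK), or is semi-invariant (MAIT) or
## gamma-delta. Matched against annotation labels.
.restrictive_pattern <- "(^|[ _])(NK|GD|MAIT|gamma.?delta)([ _-]|$)"

#' Read a 10x filtered contig annotation table
#'
#' Parses a CSV in the 10x \code{filtered_contig_annotations.csv} dialect.
#' Only the \code{barcode}, \code{chain}, \code{cdr3_nt} and
#' \code{productive} columns are used; extra columns are ignored. The
#' \code{productive} flag is parsed from the dialect's "True"/"true"/"TRUE"
#' spellings; anything else (including "None" and "False") is
#' non-productive.
#'
#' @param path path to the contig CSV.
#' @param sample_id sample identifier attached to every contig.
#' @return data.frame with columns \code{barcode, chain, cdr3_nt,
#'   productive, sample_id}; chains other than TRA/TRB are relabelled
#'   \code{"other"}. A header-only file yields zero rows.
#' @export
readContigs <- function(path, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!file.exists(path)) stop("contig file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       check.names = FALSE, colClasses = "character")
  need <- c("barcode", "chain", "cdr3_nt", "productive")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("contig file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(
    barcode = x$barcode,
    chain = ifelse(x$chain %in% c("TRA", "TRB"), x$chain, "other"),
    cdr3_nt = x$cdr3_nt,
    productive = tolower(trimws(x$productive)) == "true",
    sample_id = rep(sample_id, nrow(x)),
    stringsAsFactors = FALSE
  )
  if (any(out$productive & !nzchar(out$cdr3_nt)))
    stop("productive contig with empty cdr3_nt in ", path)
  if (any(!nzchar(out$barcode)))
    stop("empty barcode in ", path)
  out
}

#' Read a cell metadata table
#'
#' Tab-separated, one row per (barcode, sample). Required columns:
#' \code{barcode, sample_id, patient_id, compartment, timepoint, phenotype,
#' response}; optional \code{pseudotime} (nonnegative real, present only
#' with \code{lineage}) and \code{lineage}.
#'
#' @param path path to the TSV.
#' @return data.frame with the standard metadata columns; missing optional
#'   columns are filled with \code{NA}.
#' @export
readCellMeta <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- setdiff(.meta_cols, c("pseudotime", "lineage"))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("metadata file lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(x$pseudotime)) x$pseudotime <- NA_real_
  if (is.null(x$lineage)) x$lineage <- NA_character_
  x$pseudotime <- as.numeric(x$pseudotime)
  if (anyDuplicated(x[c("barcode", "sample_id")]))
    stop("duplicated (barcode, sample_id) in metadata")
  bad <- !x$compartment %in% c("tumour", "pbmc")
  if (any(bad))
    stop("unknown compartment value(s): ",
         paste(unique(x$compartment[bad]), collapse = ", "))
  bad <- !is.na(x$timepoint) & !x$timepoint %in% c("W0", "W3", "W6")
  if (any(bad))
    stop("unknown timepoint value(s): ",
         paste(unique(x$timepoint[bad]), collapse = ", "))
  if (any(!is.na(x$pseudotime) & is.na(x$lineage)))
    stop("pseudotime present without lineage")
  x[intersect(.meta_cols, names(x))]
}

#' Read a per-barcode QC table
#'
#' @param path TSV with columns \code{barcode, n_genes, n_umi, pct_mito}.
#' @return data.frame of the four columns.
#' @export
readQCTable <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "n_genes", "n_umi", "pct_mito")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("QC table lacks required column(s): ", paste(miss, collapse = ", "))
  if (any(x$n_genes < 0) || any(x$n_umi < 0) ||
      any(x$pct_mito < 0) || any(x$pct_mito > 100))
    stop("QC values out of range (counts >= 0, pct_mito in [0,100])")
  x[need]
}

#' Named QC threshold presets
#'
#' Two presets mirror the cell-quality cut-offs used for tumour biopsies
#' (mitochondrial content up to 50\%, tolerant of stressed liver tissue)
#' and for PBMCs (15\%): barcodes with fewer than 200 or more than 6000
#' detected genes, or fewer than 400 UMIs, are removed in both.
#'
#' @param name \code{"biopsy"} or \code{"pbmc"}.
#' @return list with \code{min_genes, max_genes, min_umi, max_pct_mito}.
#' @export
qcPreset <- function(name = c("biopsy", "pbmc")) {
  name <- match.arg(name)
  list(min_genes = 200, max_genes = 6000, min_umi = 400,
       max_pct_mito = if (name == "biopsy") 50 else 15)
}

#' Filter barcodes on gene/UMI/mitochondrial thresholds
#'
#' Retains rows with \code{min_genes <= n_genes <= max_genes},
#' \code{n_umi >= min_umi} and \code{pct_mito <= max_pct_mito}, preserving
#' input order. Idempotent.
#'
#' @param rows data.frame as returned by [readQCTable()].
#' @param min_genes,max_genes inclusive detected-gene bounds.
#' @param min_umi minimum UMI count.
#' @param max_pct_mito maximum mitochondrial percentage.
#' @return the retained rows.
#' @examples
#' qc <- data.frame(barcode = c("a", "b", "c"),
#'                  n_genes = c(150, 500, 7000),
#'                  n_umi = 1000, pct_mito = 5)
#' qcFilterCells(qc, 200, 6000, 400, 50)  # keeps only "b"
#' @export
qcFilterCells <- function(rows, min_genes = 200, max_genes = 6000,
                          min_umi = 400, max_pct_mito = 50) {
  stopifnot(min_genes > 0, max_genes > 0, min_umi > 0, max_pct_mito > 0,
            min_genes < max_genes)
  keep <- rows$n_genes >= min_genes & rows$n_genes <= max_genes &
    rows$n_umi >= min_umi & rows$pct_mito <= max_pct_mito
  rows[keep, , drop = FALSE]
}

#' Call clonotypes from productive contigs
#'
#' Assigns every cell a clonotype key from its productive CDR3 nucleotide
#' sequences: clonotypes are cells with identical CDR3nt content. Cells
#' without any productive contig are dropped, as are cells annotated as
#' NK, gamma-delta or MAIT (restrictive, non-conventional TCRs) and cells
#' with no phenotype annotation.
#'
#' With \code{identity_mode = "paired"} (default, the CellRanger
#' convention) the key is the lexicographically sorted, "_"-joined set of
#' the cell's productive CDR3nt strings, so two cells match only when
#' their whole chain sets agree. With \code{"any_chain"} cells sharing any
#' single CDR3nt are merged into one clonotype (connected components over
#' shared chains); the component is keyed by its lexicographically
#' smallest CDR3nt.
#'
#' @param contigs data.frame from [readContigs()] (possibly several samples
#'   row-bound together).
#' @param meta data.frame from [readCellMeta()] covering the barcodes.
#' @param identity_mode \code{"paired"} or \code{"any_chain"}.
#' @return data.frame of cells (metadata columns plus
#'   \code{clonotype_key}), with a \code{"tally"} attribute counting cells
#'   dropped at each step (\code{no_meta}, \code{no_productive},
#'   \code{restrictive}, \code{na_phenotype}).
#' @export
callClonotypes <- function(contigs, meta,
                           identity_mode = c("paired", "any_chain")) {
  identity_mode <- match.arg(identity_mode)
  prod <- contigs[contigs$productive & nzchar(contigs$cdr3_nt), ,
                  drop = FALSE]
  cell_id <- paste(prod$barcode, prod$sample_id, sep = "\r")
  cdr3_by_cell <- split(prod$cdr3_nt, cell_id)
  ## paired key: sorted unique productive CDR3nt set, "_"-joined
  keys <- vapply(cdr3_by_cell,
                 function(s) paste(sort(unique(s)), collapse = "_"),
                 character(1))
  if (identity_mode == "any_chain") {
    keys <- .anyChainKeys(cdr3_by_cell)
  }
  ids <- names(cdr3_by_cell)
  parts <- matrix(unlist(strsplit(ids, "\r", fixed = TRUE)),
                  ncol = 2, byrow = TRUE)
  cells <- data.frame(barcode = parts[, 1], sample_id = parts[, 2],
                      clonotype_key = unname(keys),
                      stringsAsFactors = FALSE)

  n_contig_cells <- length(unique(paste(contigs$barcode, contigs$sample_id,
                                        sep = "\r")))
  tally <- c(no_productive = n_contig_cells - nrow(cells),
             no_meta = 0L, restrictive = 0L, na_phenotype = 0L)

  m <- merge(cells, meta, by = c("barcode", "sample_id"), all.x = TRUE,
             sort = FALSE)
  for (nm in setdiff(.meta_cols, names(m)))
    m[[nm]] <- if (nm == "pseudotime") NA_real_ else NA_character_
  no_meta <- is.na(m$patient_id)
  if (any(no_meta)) {
    warning(sum(no_meta), " cell(s) with productive TCR absent from ",
            "metadata; dropped")
    tally["no_meta"] <- sum(no_meta)
    m <- m[!no_meta, , drop = FALSE]
  }
  restrictive <- !is.na(m$phenotype) &
    grepl(.restrictive_pattern, m$phenotype, ignore.case = TRUE)
  tally["restrictive"] <- sum(restrictive)
  m <- m[!restrictive, , drop = FALSE]
  na_pheno <- is.na(m$phenotype)
  if (any(na_pheno)) {
    message(sum(na_pheno), " cell(s) without phenotype annotation dropped")
    tally["na_phenotype"] <- sum(na_pheno)
    m <- m[!na_pheno, , drop = FALSE]
  }
  out <- m[c(.meta_cols, "clonotype_key")]
  rownames(out) <- NULL
  attr(out, "tally") <- tally
  out
}

## connected components of cells over shared CDR3nt strings; component key
## is its lexicographically smallest CDR3nt
.anyChainKeys <- function(cdr3_by_cell) {
  cdr3 <- sort(unique(unlist(cdr3_by_cell)))
  parent <- seq_along(cdr3)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (s in cdr3_by_cell) {
    idx <- match(unique(s), cdr3)
    if (length(idx) > 1) {
      r <- find(idx[1])
      for (j in idx[-1]) {
        rj <- find(j)
        if (rj != r) parent[max(r, rj)] <- min(r, rj)
      }
    }
  }
  roots <- vapply(seq_along(cdr3), find, integer(1))
  comp_key <- cdr3[roots]  # root index is minimal, so root cdr3 is minimal
  vapply(cdr3_by_cell,
         function(s) min(comp_key[match(unique(s), cdr3)]),
         character(1))
}

#' Remove clonotypes observed in more than one patient
#'
#' Clonotype keys seen in two or more distinct patients are most plausibly
#' technical artefacts or public, non-tumour-reactive TCRs and are removed
#' from every cell before any sharing analysis.
#'
#' @param cells cell data.frame with \code{clonotype_key} and
#'   \code{patient_id}.
#' @return list with \code{cells} (the surviving rows) and \code{removed}
#'   (character vector of removed clonotype keys).
#' @export
dropCrossPatientClonotypes <- function(cells) {
  stopifnot(all(c("clonotype_key", "patient_id") %in% names(cells)))
  npat <- rowsum(as.integer(!duplicated(
    paste(cells$clonotype_key, cells$patient_id, sep = "\r"))),
    cells$clonotype_key)
  removed <- rownames(npat)[npat[, 1] >= 2]
  keep <- !cells$clonotype_key %in% removed
  list(cells = cells[keep, , drop = FALSE], removed = removed)
}

#' Write / read a cell table
#'
#' Plain-TSV round trip for clonotype-annotated cell tables.
#'
#' @param cells cell data.frame.
#' @param path output TSV path.
#' @return \code{writeCellTable} returns \code{path} invisibly;
#'   \code{readCellTable} returns the cell data.frame.
#' @export
writeCellTable <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  x$pseudotime <- as.numeric(x$pseudotime)
  x
}
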