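## Built-in marker-gene signatures for the bulk-expression validation
## pipeline, plus a plain-text signature file reader.

.sig_temra <- c(
  "GZMH", "GNLY", "NKG7", "FGFBP2", "GZMB", "CST7", "CCL5", "PRF1",
  "CX3CR1", "CTSW", "GZMA", "KLRD1", "GZMM", "CD3D", "CD8A", "CD52",
  "PTPRC", "CD3G", "HCST", "CD3E", "PLEK", "KLRG1", "RAC2", "LCK",
  "CD247", "HOPX", "KRLK1", "BIN2", "S100A4", "CORO1A", "IL2RG",
  "ITGB2", "IFITM1", "EMP3", "TRBC1", "FLNA"
)

.sig_macro_cxcl10 <- c(
  "CXCL10", "CXCL9", "GBP1", "TYMP", "CALHM6", "CCL2", "TNFSF13B",
  "WARS", "CCL8", "IL4I1", "ICAM1", "LILRB4", "CXCL11", "SOD2",
  "LAP3", "STAT1"
)

## legacy / mistyped symbols and their current HGNC names
.symbol_aliases <- c(KRLK1 = "KLRK1", WARS = "WARS1")

#' Built-in predictive-biomarker gene signatures
#'
#' Returns the three signatures of the bulk validation pipeline: the
#' 36-gene cytotoxic effector-memory CD8 T-cell (TEMRA) signature, the
#' 16-gene inflammatory CXCL10+ macrophage signature, and their 52-gene
#' union (the combined treatment-response biomarker). Symbols are kept as
#' published, including the legacy spellings \code{KRLK1} and \code{WARS};
#' \code{fix_symbols = TRUE} rewrites those to their current HGNC names
#' (\code{KLRK1}, \code{WARS1}).
#'
#' @param fix_symbols rewrite legacy symbols via the built-in alias table?
#' @return named list of three [GeneSignature-class] objects:
#'   \code{TEMRA}, \code{MacroCXCL10}, \code{combined}.
#' @examples
#' sigs <- builtinSignatures()
#' vapply(sigs, length, integer(1))  # 36, 16, 52
#' @export
builtinSignatures <- function(fix_symbols = FALSE) {
  fix <- function(g) {
    if (!fix_symbols) return(g)
    hit <- g %in% names(.symbol_aliases)
    g[hit] <- .symbol_aliases[g[hit]]
    g
  }
  temra <- fix(.sig_temra)
  macro <- fix(.sig_macro_cxcl10)
  list(
    TEMRA = GeneSignature("TEMRA", temra),
    MacroCXCL10 = GeneSignature("MacroCXCL10", macro),
    combined = GeneSignature("combined", union(temra, macro))
  )
}

#' Read gene signatures from a plain-text file
#'
#' One symbol per line; a line starting with \code{#} opens a new
#' signature and names it.
#'
#' @param path signature file.
#' @return named list of [GeneSignature-class] objects.
#' @export
readSignatures <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^#", lines)
  if (!length(lines) || !hdr[1])
    stop("signature file must open with a '#'-prefixed name header")
  grp <- cumsum(hdr)
  out <- lapply(split(lines, grp), function(block) {
    GeneSignature(sub("^#\\s*", "", block[1]), block[-1])
  })
  stats::setNames(out, vapply(out, signatureName, character(1)))
}
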