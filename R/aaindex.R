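.threeToOne <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Default table of 100 amino-acid property scales
#'
#' Builds a 100 x 20 matrix of physicochemical amino-acid indices
#' (hydrophobicity, polarity, transfer free energy, ...) from the AAindex
#' catalogue shipped with the \pkg{seqinr} package, keeping the first 100
#' scales with complete (finite) values. Columns are the 20 standard amino
#' acids in alphabetical one-letter order; rownames are AAindex accession
#' ids. The weighted-sign encoder only requires 100 finite scales, not a
#' particular choice, and any 100 x 20 table may be substituted via
#' [readAAIndexTable()].
#'
#' @param n number of scales (default 100).
#' @return numeric matrix `n` x 20.
#' @export
defaultAAIndexTable <- function(n = 100L) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  idx <- env$aaindex
  keep <- vapply(idx, function(e) all(is.finite(e$I)), logical(1))
  idx <- idx[keep]
  if (length(idx) < n) stop("catalogue has fewer than ", n, " complete scales")
  idx <- idx[seq_len(n)]
  m <- t(vapply(idx, function(e) {
    v <- e$I
    names(v) <- .threeToOne[names(v)]
    v[aminoAcidAlphabet()]
  }, numeric(20L)))
  colnames(m) <- aminoAcidAlphabet()
  rownames(m) <- names(idx)
  validateAAIndexTable(m)
  m
}

#' Validate an amino-acid index table
#'
#' @param table numeric matrix, scales x 20 amino acids (alphabetical
#'   one-letter column order).
#' @param nRows required number of scales (default 100; `NA` to skip).
#' @return `table`, invisibly, or an error.
#' @export
validateAAIndexTable <- function(table, nRows = 100L) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("AAindex table must be a numeric matrix")
  if (ncol(table) != 20L ||
      !identical(colnames(table), aminoAcidAlphabet()))
    stop("AAindex table needs 20 columns named by the alphabetical ",
         "one-letter amino-acid codes")
  if (!is.na(nRows) && nrow(table) != nRows)
    stop("AAindex table must have exactly ", nRows, " rows, got ",
         nrow(table))
  if (!all(is.finite(table)))
    stop("AAindex table contains non-finite values")
  invisible(table)
}

#' Read / write an amino-acid index table as TSV
#'
#' Format: header `index_id` plus the 20 one-letter codes; one row per scale.
#'
#' @param path file path.
#' @param nRows required number of scales for validation (default 100).
#' @return `readAAIndexTable` returns the numeric matrix.
#' @export
readAAIndexTable <- function(path, nRows = 100L) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, aminoAcidAlphabet(), drop = FALSE])
  rownames(m) <- tab[[1]]
  validateAAIndexTable(m, nRows)
  m
}

#' @rdname readAAIndexTable
#' @param table numeric matrix as returned by [defaultAAIndexTable()].
#' @export
writeAAIndexTable <- function(table, path) {
  df <- data.frame(index_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
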