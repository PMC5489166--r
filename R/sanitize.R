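#' The 20 standard amino acids
#'
#' One-letter codes in fixed alphabetical order; all composition vectors in
#' the package are indexed in this order.
#' @return character vector of length 20.
#' @export
aminoAcidAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Sanitize protein sequences to the 20-letter alphabet
#'
#' Uppercases sequences and resolves non-standard letters (B, J, O, U, X, Z
#' and the stop symbol `*`) according to `policy`:
#' \describe{
#'   \item{drop}{remove every non-standard character (default);}
#'   \item{map}{map ambiguity codes to their nearest standard residue
#'     (B to D, Z to E, U to C, O to K, J to L) and drop X and `*`;}
#'   \item{reject}{raise an error naming the offending sequence.}
#' }
#' Composition-based encoders are defined over the 20-letter alphabet, so
#' dropping preserves the composition arithmetic.
#'
#' @param x character vector of sequences.
#' @param policy one of "drop", "map", "reject".
#' @return character vector of sanitized sequences.
#' @export
sanitizeSequences <- function(x, policy = c("drop", "map", "reject")) {
  policy <- match.arg(policy)
  x <- toupper(as.character(x))
  std <- paste(aminoAcidAlphabet(), collapse = "")
  if (policy == "reject") {
    bad <- grepl(sprintf("[^%s]", std), x)
    if (any(bad)) {
      stop("non-standard residues in sequence(s): ",
           paste(which(bad), collapse = ", "))
    }
    return(x)
  }
  if (policy == "map") {
    x <- chartr("BZUOJ", "DECKL", x)
  }
  gsub(sprintf("[^%s]", std), "", x)
}
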