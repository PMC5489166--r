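#' The six subcellular compartments
#'
#' The predictor covers six human subcellular compartments. Labels are fixed
#' and carry stable integer codes 0 to 5 in this order: cell membrane,
#' cytoplasm, endoplasmic reticulum/Golgi, mitochondrion, nucleus,
#' extracellular.
#'
#' @return `subcellLocations()` returns the character vector of the six
#'   canonical labels; `locationCodes()` returns the named integer codes.
#' @examples
#' subcellLocations()
#' locationCodes()
#' @export
subcellLocations <- function() {
  c("CELL_MEMBRANE", "CYTOPLASM", "ER_GOLGI",
    "MITOCHONDRION", "NUCLEUS", "EXTRACELLULAR")
}

#' @rdname subcellLocations
#' @export
locationCodes <- function() {
  stats::setNames(0:5, subcellLocations())
}

# Synonyms accepted on input; canonical labels emitted on output.
.locationSynonyms <- function() {
  canon <- subcellLocations()
  list(
    CELL_MEMBRANE = c("cell membrane", "cell_membrane", "membrane",
                      "plasma membrane", "plasma_membrane"),
    CYTOPLASM     = c("cytoplasm", "cytosol"),
    ER_GOLGI      = c("er/golgi", "er_golgi", "er golgi", "ergolgi",
                      "endoplasmic reticulum/golgi",
                      "endoplasmic_reticulum/golgi",
                      "endoplasmic reticulum", "golgi"),
    MITOCHONDRION = c("mitochondrion", "mitochondria", "mitochondrial"),
    NUCLEUS       = c("nucleus", "nuclear"),
    EXTRACELLULAR = c("extracellular", "secreted", "extracellular space")
  )
}

#' Normalize location labels to canonical form
#'
#' Matches labels case-insensitively against the six canonical names, their
#' integer codes, and a list of common synonyms ("er/golgi",
#' "endoplasmic reticulum/golgi", "cytosol", ...).
#'
#' @param labels character vector of labels (or integer codes 0-5).
#' @return character vector of canonical labels.
#' @export
normalizeLocation <- function(labels) {
  canon <- subcellLocations()
  if (is.numeric(labels)) {
    bad <- labels[!labels %in% 0:5]
    if (length(bad)) stop("unknown location code(s): ",
                          paste(unique(bad), collapse = ", "))
    return(canon[labels + 1L])
  }
  syn <- .locationSynonyms()
  out <- character(length(labels))
  low <- tolower(trimws(labels))
  for (i in seq_along(low)) {
    hit <- canon[tolower(canon) == low[i]]
    if (!length(hit)) {
      hit <- names(syn)[vapply(syn, function(s) low[i] %in% s, logical(1))]
    }
    if (!length(hit)) stop("unknown location label: '", labels[i], "'")
    out[i] <- hit[1]
  }
  out
}

# logical n x 6 matrix from a list of per-protein label sets
.locationMatrixFromSets <- function(sets, ids) {
  canon <- subcellLocations()
  m <- matrix(FALSE, length(sets), 6L,
              dimnames = list(ids, canon))
  for (i in seq_along(sets)) {
    if (length(sets[[i]])) m[i, normalizeLocation(sets[[i]])] <- TRUE
  }
  m
}

.locationSetsFromMatrix <- function(m) {
  canon <- colnames(m)
  lapply(seq_len(nrow(m)), function(i) canon[m[i, ]])
}
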