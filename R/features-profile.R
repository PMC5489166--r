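#' Aggregate a surface-accessibility profile over the four regions
#'
#' Per region (full, N-terminal 30, middle third, C-terminal 50): mean
#' relative surface accessibility, mean absolute surface accessibility
#' scaled by `asaCap` (a 250 square-Angstrom cap keeps the feature in about
#' [0, 1]), and the fraction of exposed residues — 12 values. A missing
#' profile yields a zero block with attribute `missing = TRUE` rather than
#' an error, so prediction never aborts mid-batch.
#'
#' @param profile per-residue data frame with columns `RSA`, `ASA`, `class`
#'   (`"E"` exposed / `"B"` buried), or `NULL`.
#' @param len sequence length (to check the one-row-per-residue invariant
#'   and slice regions).
#' @param asaCap scaling constant for ASA (default 250).
#' @return named numeric vector of length 12.
#' @export
aggregateSA <- function(profile, len, asaCap = 250) {
  regs <- regionIndices(len)
  nm <- as.vector(vapply(names(regs), function(r)
    paste0("sa_", r, c("_meanRSA", "_meanASA", "_fracExposed")),
    character(3L)))
  if (is.null(profile)) {
    out <- stats::setNames(numeric(12L), nm)
    attr(out, "missing") <- TRUE
    return(out)
  }
  if (nrow(profile) != len)
    stop("SA profile has ", nrow(profile), " rows for ", len, " residues")
  out <- unlist(lapply(regs, function(idx) {
    c(mean(profile$RSA[idx]),
      mean(profile$ASA[idx]) / asaCap,
      mean(profile$class[idx] == "E"))
  }), use.names = FALSE)
  stats::setNames(out, nm)
}

#' Find the most similar reference protein
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1 — the
#' protein-BLAST defaults) of the query against every reference sequence;
#' the best raw score wins, ties broken by lexicographically smallest
#' reference id. Returns `NULL` when the best score falls below `minScore`.
#' An external similarity tool can be substituted by supplying `scores`
#' (a named numeric vector of precomputed query-vs-reference scores) in
#' which case no alignment is run.
#'
#' @param query a single sequence (character) or a 1-protein
#'   [ProteinSet-class].
#' @param reference a [ProteinSet-class] of reference proteins.
#' @param exclude character ids never returned (e.g. the query's own id at
#'   training time, to keep features leave-self-out).
#' @param minScore minimum alignment score for a hit (default 50).
#' @param scores optional named numeric vector of externally computed
#'   scores, bypassing the built-in alignment.
#' @return list with `id` and `score`, or `NULL` if no hit.
#' @export
similaritySearch <- function(query, reference, exclude = character(0),
                             minScore = 50, scores = NULL) {
  if (length(reference) == 0L) stop("empty reference set")
  if (is(query, "ProteinSet")) query <- as.character(proteinSequences(query))[1]
  refSeqs <- proteinSequences(reference)
  keep <- !(names(refSeqs) %in% exclude)
  if (!any(keep)) return(NULL)
  refSeqs <- refSeqs[keep]
  if (is.null(scores)) {
    scores <- Biostrings::pairwiseAlignment(
      refSeqs, Biostrings::AAString(query), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    names(scores) <- names(refSeqs)
  } else {
    scores <- scores[names(scores) %in% names(refSeqs)]
    if (!length(scores)) return(NULL)
  }
  best <- max(scores)
  if (best < minScore) return(NULL)
  hit <- sort(names(scores)[scores == best])[1]
  list(id = hit, score = unname(best))
}

#' Sequence similarity profile block
#'
#' The SSP of a query is the sequence-derived feature block (composition,
#' weighted sign aa-index, PseAAC) of its most similar reference protein;
#' when no reference scores above threshold the query's own block is used
#' and the matched id equals the query id. At training time pass
#' `excludeSelf = TRUE` so a training protein never borrows its own features
#' (leave-self-out, avoiding label leakage).
#'
#' @param queryId id of the query protein.
#' @param querySeq query sequence (character).
#' @param queryBlock the query's own sequence feature block (numeric).
#' @param reference a [ProteinSet-class]; `referenceBlocks` a matrix of the
#'   references' cached sequence blocks (rownames = ids).
#' @param referenceBlocks numeric matrix of cached reference blocks.
#' @param excludeSelf logical: exclude `queryId` from the reference.
#' @param minScore alignment score threshold, see [similaritySearch()].
#' @return list with `block` (numeric vector, layout identical to the
#'   sequence block), `matchedId` and `score` (`NA` when self-fallback).
#' @export
computeSSP <- function(queryId, querySeq, queryBlock, reference,
                       referenceBlocks, excludeSelf = FALSE, minScore = 50) {
  hit <- similaritySearch(querySeq, reference,
                          exclude = if (excludeSelf) queryId else character(0),
                          minScore = minScore)
  if (is.null(hit)) {
    return(list(block = queryBlock, matchedId = queryId, score = NA_real_))
  }
  list(block = referenceBlocks[hit$id, ], matchedId = hit$id,
       score = hit$score)
}
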