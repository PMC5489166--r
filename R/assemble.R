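#' Feature assembly configuration
#'
#' Collects every tunable of the feature encoders in one list. Defaults:
#' the three sequence encoders are always on; the surface-accessibility
#' block is on (zero-filled for proteins without a profile); the sequence
#' similarity profile is off by default because it requires a quadratic
#' alignment pass over the reference set, and is enabled for
#' similarity-profile analyses; GO features are on with 35 selected terms.
#'
#' @param useSA include the 12 surface-accessibility aggregates.
#' @param useSSP include the sequence-similarity-profile block (a full copy
#'   of the sequence block layout taken from the most similar reference).
#' @param useGO include the binary GO-term block.
#' @param goK number of GO terms selected by [regularMRMR()] (default 35;
#'   capped at the number of usable candidates).
#' @param goRankDepth ranking depth before truncation at `goK` (default 50).
#' @param lambda,omega PseAAC parameters (defaults 8 and 0.05).
#' @param epsilon zero floor before the weighted-sign log (default 1e-6).
#' @param asaCap ASA scaling constant in square Angstrom (default 250).
#' @param sspMinScore minimum alignment score for a similarity hit.
#' @param aaindexTable 100 x 20 scales matrix; `NULL` means
#'   [defaultAAIndexTable()].
#' @param sanitize non-standard-residue policy, see [sanitizeSequences()].
#' @return named list of class-free configuration values.
#' @export
featureConfig <- function(useSA = TRUE, useSSP = FALSE, useGO = TRUE,
                          goK = 35L, goRankDepth = 50L,
                          lambda = 8L, omega = 0.05, epsilon = 1e-6,
                          asaCap = 250, sspMinScore = 50,
                          aaindexTable = NULL,
                          sanitize = "drop") {
  list(useSA = useSA, useSSP = useSSP, useGO = useGO,
       goK = as.integer(goK), goRankDepth = as.integer(goRankDepth),
       lambda = as.integer(lambda), omega = omega, epsilon = epsilon,
       asaCap = asaCap, sspMinScore = sspMinScore,
       aaindexTable = aaindexTable, sanitize = sanitize)
}

.configTable <- function(config) {
  if (is.null(config$aaindexTable)) defaultAAIndexTable()
  else validateAAIndexTable(config$aaindexTable, NA)
}

#' Assemble the full feature matrix for a ProteinSet
#'
#' Concatenates, per protein and in fixed order: the sequence block
#' (region-wise composition, weighted sign aa-index, PseAAC), the optional
#' surface-accessibility block, the optional sequence-similarity-profile
#' block, and the optional binary GO block. The block map records every
#' span; the layout is identical at train and predict time given the same
#' configuration and GO spec.
#'
#' @param x a [ProteinSet-class].
#' @param config a [featureConfig()] list.
#' @param goSpec ordered character vector of selected GO ids (required when
#'   `config$useGO`; fixed at training time).
#' @param reference a [ProteinSet-class] used for the similarity profile and
#'   the GO similarity fallback. Defaults to `x` itself (training time) —
#'   combine with `leaveSelfOut = TRUE` so no protein borrows its own
#'   features.
#' @param leaveSelfOut logical: exclude each query's own id from similarity
#'   hits (training time).
#' @return a [FeatureMatrix-class].
#' @export
assembleFeatures <- function(x, config = featureConfig(), goSpec = NULL,
                             reference = NULL, leaveSelfOut = is.null(reference)) {
  stopifnot(is(x, "ProteinSet"))
  table <- .configTable(config)
  if (is.null(reference)) reference <- x
  seqs <- proteinSequences(x)
  sb <- .sequenceBlockMatrix(seqs, table, config$lambda, config$omega,
                             config$epsilon)
  blocks <- list(seq = sb$values)
  if (isTRUE(config$useSA)) {
    w <- Biostrings::width(seqs)
    profs <- x@saProfiles
    sa <- t(vapply(seq_along(profs), function(i)
      aggregateSA(profs[[i]], w[i], config$asaCap), numeric(12L)))
    rownames(sa) <- names(seqs)
    blocks$sa <- sa
  }
  if (isTRUE(config$useSSP)) {
    refBlocks <- if (identical(reference, x)) sb$values else
      .sequenceBlockMatrix(proteinSequences(reference), table,
                           config$lambda, config$omega, config$epsilon)$values
    ssp <- matrix(0, length(seqs), ncol(sb$values))
    matched <- character(length(seqs))
    for (i in seq_along(seqs)) {
      r <- computeSSP(names(seqs)[i], as.character(seqs[[i]]),
                      sb$values[i, ], reference, refBlocks,
                      excludeSelf = leaveSelfOut,
                      minScore = config$sspMinScore)
      ssp[i, ] <- r$block
      matched[i] <- r$matchedId
    }
    colnames(ssp) <- paste0("ssp_", colnames(sb$values))
    rownames(ssp) <- names(seqs)
    attr(ssp, "matchedIds") <- matched
    blocks$ssp <- ssp
  }
  if (isTRUE(config$useGO)) {
    if (is.null(goSpec))
      stop("useGO is TRUE but no goSpec supplied; run regularMRMR first")
    terms <- x@goTerms
    refTerms <- goAnnotations(reference)
    annotated <- names(refTerms)[lengths(refTerms) > 0L]
    go <- t(vapply(seq_along(seqs), function(i) {
      fb <- NULL
      if (!length(terms[[i]]) && length(annotated)) {
        excl <- if (leaveSelfOut) names(seqs)[i] else character(0)
        pool <- setdiff(annotated, excl)
        if (length(pool)) {
          hit <- similaritySearch(as.character(seqs[[i]]), reference[pool],
                                  minScore = config$sspMinScore)
          if (!is.null(hit)) fb <- refTerms[[hit$id]]
        }
      }
      goFeatureVector(terms[[i]], goSpec, fb)
    }, numeric(length(goSpec))))
    rownames(go) <- names(seqs)
    blocks$go <- go
  }
  vals <- do.call(cbind, blocks)
  lens <- c(vapply(seq_len(nrow(sb$blockMap)), function(i)
    sb$blockMap$end[i] - sb$blockMap$start[i] + 1L, integer(1)),
    if (isTRUE(config$useSA)) 12L,
    if (isTRUE(config$useSSP)) ncol(blocks$ssp),
    if (isTRUE(config$useGO)) ncol(blocks$go))
  blockNames <- c(sb$blockMap$block,
                  if (isTRUE(config$useSA)) "sa",
                  if (isTRUE(config$useSSP)) "ssp",
                  if (isTRUE(config$useGO)) "go")
  ends <- cumsum(lens)
  bm <- data.frame(block = blockNames, start = ends - lens + 1L, end = ends,
                   stringsAsFactors = FALSE)
  cfg <- config
  cfg$aaindexTable <- NULL   # table identity kept via fingerprint
  cfg$aaindexIds <- rownames(table)
  new("FeatureMatrix", values = vals, blockMap = bm, config = cfg)
}

#' Export a feature matrix as TSV
#'
#' Writes the matrix with a `# block:start-end` header comment per block.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output path.
#' @export
writeFeatureMatrix <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bm <- blockMap(fm)
  writeLines(sprintf("# %s:%d-%d", bm$block, bm$start, bm$end), con)
  df <- data.frame(id = rownames(featureValues(fm)), featureValues(fm),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
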