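#' @rdname ProteinSet-class
#' @param x,object a `ProteinSet`.
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

#' @rdname ProteinSet-class
#' @export
setGeneric("locationMatrix", function(x) standardGeneric("locationMatrix"))

#' @rdname ProteinSet-class
#' @export
setGeneric("locationSets", function(x) standardGeneric("locationSets"))

#' @rdname ProteinSet-class
#' @export
setGeneric("goAnnotations", function(x) standardGeneric("goAnnotations"))

#' @rdname ProteinSet-class
#' @export
setGeneric("saProfiles", function(x) standardGeneric("saProfiles"))

#' @rdname FeatureMatrix-class
#' @param x a `FeatureMatrix`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("blockMap", function(x) standardGeneric("blockMap"))

#' @rdname LocPredictions-class
#' @param x a `LocPredictions`.
#' @export
setGeneric("predictedSets", function(x) standardGeneric("predictedSets"))

#' @rdname LocPredictions-class
#' @export
setGeneric("evidenceScores", function(x) standardGeneric("evidenceScores"))

setMethod("proteinSequences", "ProteinSet", function(x) x@sequences)
setMethod("locationMatrix", "ProteinSet", function(x) x@locations)
setMethod("locationSets", "ProteinSet",
          function(x) stats::setNames(.locationSetsFromMatrix(x@locations),
                                      names(x@sequences)))
setMethod("goAnnotations", "ProteinSet",
          function(x) stats::setNames(x@goTerms, names(x@sequences)))
setMethod("saProfiles", "ProteinSet",
          function(x) stats::setNames(x@saProfiles, names(x@sequences)))

#' @rdname ProteinSet-class
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @rdname ProteinSet-class
#' @export
setMethod("names", "ProteinSet", function(x) names(x@sequences))

#' @rdname ProteinSet-class
#' @param i index vector (integer, logical or protein ids).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  if (is.logical(i)) i <- which(i)
  new("ProteinSet",
      sequences = x@sequences[i],
      locations = x@locations[i, , drop = FALSE],
      goTerms = x@goTerms[i],
      saProfiles = x@saProfiles[i])
})

setMethod("show", "ProteinSet", function(object) {
  n <- length(object)
  nlab <- sum(rowSums(object@locations) > 0)
  nmulti <- sum(rowSums(object@locations) > 1)
  cat("ProteinSet with", n, "proteins (", nlab, "labeled,",
      nmulti, "multiplex )\n")
  cat("  length range:", paste(range(Biostrings::width(object@sequences)),
                               collapse = "-"), "\n")
  cat("  GO-annotated:", sum(lengths(object@goTerms) > 0),
      "| SA profiles:", sum(!vapply(object@saProfiles, is.null, logical(1))),
      "\n")
  cnt <- colSums(object@locations)
  cat("  instances per location:",
      paste(sprintf("%s=%d", abbreviate(names(cnt), 6), cnt),
            collapse = " "), "\n")
})

setMethod("featureValues", "FeatureMatrix", function(x) x@values)
setMethod("blockMap", "FeatureMatrix", function(x) x@blockMap)

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "proteins x",
      ncol(object@values), "features\n")
  bm <- object@blockMap
  for (i in seq_len(nrow(bm)))
    cat(sprintf("  %-12s [%d-%d]\n", bm$block[i], bm$start[i], bm$end[i]))
})

setMethod("show", "Layer1Ensemble", function(object) {
  cat("Layer1Ensemble:", length(object@models), "binary SVM sub-models\n")
  tab <- table(object@specs$location)[unique(object@specs$location)]
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "GannModel", function(object) {
  cat("GannModel:", nrow(object@W1) - 1L, "inputs ->",
      ncol(object@W1), "hidden ->", ncol(object@W2), "outputs\n")
  cat("  generations:", length(object@history),
      "| best MSE:", format(min(object@history), digits = 4), "\n")
})

setMethod("show", "LocPredictions", function(object) {
  cat("LocPredictions (", object@combiner, ") for", length(object@ids),
      "proteins\n")
  cat("  multiplex calls:", sum(lengths(object@sets) > 1), "\n")
})

setMethod("show", "SubLocModel", function(object) {
  cat("SubLocModel: two-layer subcellular localization predictor\n")
  cat("  layer 1:", length(object@layer1@models), "SVMs |",
      length(object@layer1@featureNames), "features\n")
  cat("  GO terms selected:", length(object@goSpec), "\n")
  cat("  reference proteins:", length(object@reference), "\n")
})

#' Predicted sets as a data frame
#'
#' @param x a `LocPredictions`.
#' @param row.names,optional,... passed through (unused).
#' @return data.frame with columns `id` and `predicted` (comma-separated
#'   canonical labels).
#' @export
setMethod("as.data.frame", "LocPredictions",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(id = x@ids,
               predicted = vapply(x@sets, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  })

setMethod("predictedSets", "LocPredictions",
          function(x) stats::setNames(x@sets, x@ids))
setMethod("evidenceScores", "LocPredictions",
          function(x) x@scores)
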