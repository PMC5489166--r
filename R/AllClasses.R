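#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   letterFrequency pairwiseAlignment width subseq
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' ProteinSet: a labelled collection of protein sequences
#'
#' The central container of the package: amino-acid sequences
#' (a [Biostrings::AAStringSet]) plus, per protein, an optional set of
#' subcellular locations (a logical membership matrix over the six
#' compartments), optional GO term annotations, and optional per-residue
#' surface-accessibility profiles.
#'
#' @slot sequences an `AAStringSet`, one entry per protein, names are ids.
#' @slot locations logical matrix, proteins x 6 compartments; all-`FALSE`
#'   rows mark unlabeled query proteins.
#' @slot goTerms list of character vectors of GO identifiers (may be empty).
#' @slot saProfiles list of per-residue data frames with columns
#'   `residue_index`, `aa`, `class`, `RSA`, `ASA`, or `NULL` entries.
#'
#' @seealso [ProteinSet()] for construction, [simulateProteome()] for
#'   synthetic data.
#' @export
setClass("ProteinSet",
  slots = c(
    sequences  = "AAStringSet",
    locations  = "matrix",
    goTerms    = "list",
    saProfiles = "list"
  )
)

setValidity("ProteinSet", function(object) {
  n <- length(object@sequences)
  msgs <- character(0)
  if (any(Biostrings::width(object@sequences) == 0L))
    msgs <- c(msgs, "sequences must be non-empty")
  std <- paste(aminoAcidAlphabet(), collapse = "")
  bad <- grepl(sprintf("[^%s]", std), as.character(object@sequences))
  if (any(bad))
    msgs <- c(msgs, paste0("sequence(s) contain non-standard residues: ",
                           paste(utils::head(which(bad), 5), collapse = ", ")))
  if (!is.logical(object@locations) ||
      nrow(object@locations) != n || ncol(object@locations) != 6L)
    msgs <- c(msgs, "locations must be a logical n x 6 matrix")
  if (!identical(colnames(object@locations), subcellLocations()))
    msgs <- c(msgs, "locations columns must be the six canonical labels")
  if (length(object@goTerms) != n)
    msgs <- c(msgs, "goTerms must have one entry per protein")
  if (length(object@saProfiles) != n)
    msgs <- c(msgs, "saProfiles must have one entry per protein")
  w <- Biostrings::width(object@sequences)
  for (i in seq_len(n)) {
    p <- object@saProfiles[[i]]
    if (!is.null(p) && nrow(p) != w[i]) {
      msgs <- c(msgs, sprintf("saProfiles[[%d]] has %d rows for %d residues",
                              i, nrow(p), w[i]))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences named character vector or `AAStringSet` of amino-acid
#'   sequences.
#' @param locations optional: a list of per-protein location label sets, or
#'   a logical membership matrix over the six compartments. `NULL` marks all
#'   proteins unlabeled.
#' @param goTerms optional list of character vectors of GO ids.
#' @param saProfiles optional list of per-residue SA data frames.
#' @param sanitize sanitization policy for non-standard residues, see
#'   [sanitizeSequences()].
#' @return a [ProteinSet-class] object.
#' @examples
#' ps <- ProteinSet(c(p1 = "MKVLATPW"), locations = list("nucleus"))
#' locationSets(ps)
#' @export
ProteinSet <- function(sequences, locations = NULL, goTerms = NULL,
                       saProfiles = NULL,
                       sanitize = c("drop", "map", "reject")) {
  sanitize <- match.arg(sanitize)
  if (is(sequences, "AAStringSet")) {
    ids <- names(sequences)
    seqs <- as.character(sequences)
  } else {
    ids <- names(sequences)
    seqs <- as.character(sequences)
  }
  if (is.null(ids)) ids <- paste0("protein_", seq_along(seqs))
  seqs <- sanitizeSequences(seqs, sanitize)
  n <- length(seqs)
  if (is.null(locations)) {
    locm <- matrix(FALSE, n, 6L, dimnames = list(ids, subcellLocations()))
  } else if (is.matrix(locations)) {
    locm <- locations
    rownames(locm) <- ids
    colnames(locm) <- subcellLocations()
    storage.mode(locm) <- "logical"
  } else {
    locm <- .locationMatrixFromSets(locations, ids)
  }
  if (is.null(goTerms)) goTerms <- rep(list(character(0)), n)
  if (is.null(saProfiles)) saProfiles <- vector("list", n)
  new("ProteinSet",
      sequences = Biostrings::AAStringSet(stats::setNames(seqs, ids)),
      locations = locm, goTerms = goTerms, saProfiles = saProfiles)
}

#' FeatureMatrix: assembled numeric features with a block map
#'
#' A numeric matrix (proteins x features) together with a block map recording
#' which column span belongs to which encoder, and the assembly
#' configuration.
#'
#' @slot values numeric matrix, rownames are protein ids.
#' @slot blockMap data.frame with columns `block`, `start`, `end`.
#' @slot config list: the feature configuration used for assembly.
#' @export
setClass("FeatureMatrix",
  slots = c(values = "matrix", blockMap = "data.frame", config = "list")
)

setValidity("FeatureMatrix", function(object) {
  bm <- object@blockMap
  if (!all(c("block", "start", "end") %in% names(bm)))
    return("blockMap needs columns block, start, end")
  if (nrow(bm)) {
    spans <- unlist(Map(seq.int, bm$start, bm$end))
    if (anyDuplicated(spans) || length(spans) != ncol(object@values) ||
        !setequal(spans, seq_len(ncol(object@values))))
      return("blockMap spans must be disjoint and cover all columns")
  }
  TRUE
})

#' Layer1Ensemble: per-location binary SVM sub-models
#'
#' The one-to-one layer: for each compartment an odd number (3-9) of binary
#' SVMs sharing that compartment's positives, each assigned a disjoint chunk
#' of its negatives so that the union of chunks covers every negative.
#'
#' @slot models list of fitted `e1071::svm` objects in fixed
#'   (location, model index) order.
#' @slot specs data.frame: one row per sub-model with `location`,
#'   `model_index`, `n_pos`, `n_neg`, `ratio`.
#' @slot partition list: per-location positive/negative id bookkeeping.
#' @slot featureNames character: column layout the ensemble was trained on.
#' @export
setClass("Layer1Ensemble",
  slots = c(models = "list", specs = "data.frame", partition = "list",
            featureNames = "character")
)

#' GannModel: a feed-forward network evolved by a genetic algorithm
#'
#' Weights of a single-hidden-layer sigmoid network (inputs = first-layer
#' decision values, 6 outputs) optimized by a generational GA with
#' tournament selection, uniform crossover, Gaussian mutation, clipping to
#' the weight bounds, and elitism of one.
#'
#' @slot W1 input-to-hidden weights ((d+1) x hidden, first row is bias).
#' @slot W2 hidden-to-output weights ((hidden+1) x 6, first row is bias).
#' @slot config the [gannConfig()] list used for training.
#' @slot history numeric: best mean-squared error per generation
#'   (non-increasing under elitism).
#' @export
setClass("GannModel",
  slots = c(W1 = "matrix", W2 = "matrix", config = "list",
            history = "numeric")
)

setValidity("GannModel", function(object) {
  w <- c(object@W1, object@W2)
  if (any(w < object@config$minW - 1e-12) ||
      any(w > object@config$maxW + 1e-12))
    return("weights outside [minW, maxW]")
  if (length(object@history) > 1L && any(diff(object@history) > 1e-12))
    return("best MSE history must be non-increasing (elitism)")
  TRUE
})

#' LocPredictions: per-protein predicted location sets
#'
#' @slot ids character protein ids.
#' @slot sets list of predicted location label sets (each non-empty).
#' @slot scores numeric matrix (proteins x 6) of per-location evidence
#'   (network activations or positive-vote fractions).
#' @slot combiner character: which combiner produced the sets.
#' @export
setClass("LocPredictions",
  slots = c(ids = "character", sets = "list", scores = "matrix",
            combiner = "character")
)

setValidity("LocPredictions", function(object) {
  if (length(object@ids) != length(object@sets))
    return("ids and sets lengths differ")
  if (any(lengths(object@sets) == 0L))
    return("every prediction set must be non-empty")
  TRUE
})

#' SubLocModel: a trained two-layer localization predictor
#'
#' Bundles the first-layer SVM ensemble, the two second-layer combiners
#' (GANN and majority vote), the feature configuration, the selected GO term
#' spec, and the reference sequences used for similarity-based fallbacks.
#'
#' @slot layer1 a [Layer1Ensemble-class].
#' @slot gann a [GannModel-class].
#' @slot featureConfig list, see [featureConfig()].
#' @slot goSpec character: ordered selected GO ids (empty if GO disabled).
#' @slot goScores numeric: selection scores parallel to `goSpec`.
#' @slot reference a [ProteinSet-class] of training proteins (used for the
#'   similarity profile and GO fallback at prediction time), possibly empty.
#' @slot seeds integer seeds recorded for reproducibility.
#' @export
setClass("SubLocModel",
  slots = c(layer1 = "Layer1Ensemble", gann = "GannModel",
            featureConfig = "list", goSpec = "character",
            goScores = "numeric", reference = "ProteinSet",
            featureCenter = "numeric", featureScale = "numeric",
            seeds = "integer")
)
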