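#' Train the full two-layer localization predictor
#'
#' End-to-end training on a labeled [ProteinSet-class]: GO-term selection by
#' [regularMRMR()] (when enabled), feature assembly with leave-self-out
#' similarity fallbacks, first-layer SVM training on the partition plan,
#' and second-layer training. The network combiner is trained on
#' out-of-fold first-layer decision values (an internal `gannFolds`-fold
#' loop), so its training rows never come from sub-models that saw the same
#' protein; the first layer in the returned model is fit on the full
#' training set.
#'
#' @param x a labeled [ProteinSet-class] (every protein needs >= 1
#'   location).
#' @param config a [featureConfig()] list.
#' @param mPerLocation per-location sub-model counts, see
#'   [defaultPartitionPlan()].
#' @param gann a [gannConfig()] list.
#' @param svmParams extra [e1071::svm] arguments.
#' @param gannFolds folds of the internal out-of-fold loop (default 5; use
#'   `0` to train the network on resubstituted outputs instead).
#' @param seed master seed.
#' @return a [SubLocModel-class].
#' @export
trainSubLocModel <- function(x, config = featureConfig(),
                             mPerLocation = c(5L, 5L, 5L, 5L, 7L, 5L),
                             gann = gannConfig(), svmParams = list(),
                             gannFolds = 5L, seed = 1L) {
  stopifnot(is(x, "ProteinSet"))
  Y <- locationMatrix(x)
  if (!all(rowSums(Y) >= 1L))
    stop("training requires every protein to have at least one location")
  goSpec <- character(0); goScores <- numeric(0)
  if (isTRUE(config$useGO)) {
    cand <- sort(unique(unlist(goAnnotations(x))))
    if (!length(cand)) stop("useGO is TRUE but no protein has GO terms")
    M <- vapply(cand, function(tm)
      vapply(goAnnotations(x), function(tt) tm %in% tt, logical(1)) * 1,
      numeric(length(x)))
    rank <- suppressMessages(regularMRMR(
      M, Y, k = min(config$goRankDepth, ncol(M),
                    sum(apply(M, 2L, function(cc)
                      length(unique(cc)) > 1L)))))
    k <- min(config$goK, length(rank$ids))
    goSpec <- rank$ids[seq_len(k)]
    goScores <- rank$scores[seq_len(k)]
  }
  fm <- assembleFeatures(x, config, goSpec = if (length(goSpec)) goSpec,
                         reference = x, leaveSelfOut = TRUE)
  std <- .standardize(featureValues(fm))
  X <- std$X
  plan <- defaultPartitionPlan(Y, mPerLocation, seed = seed)
  ensemble <- trainLayer1(X, plan, svmParams)
  # out-of-fold decision values for unbiased network training
  if (gannFolds >= 2L) {
    fold <- .stratifiedFolds(Y, gannFolds, seed + 7L)
    oof <- matrix(NA_real_, nrow(X), sum(mPerLocation),
                  dimnames = list(rownames(X), NULL))
    for (g in seq_len(gannFolds)) {
      itr <- which(fold != g); ite <- which(fold == g)
      p <- defaultPartitionPlan(Y[itr, , drop = FALSE], mPerLocation,
                                seed = seed + 50L + g)
      e <- trainLayer1(X[itr, , drop = FALSE], p, svmParams)
      oof[ite, ] <- predictLayer1(e, X[ite, , drop = FALSE])$decision
    }
    gannX <- oof
  } else {
    gannX <- predictLayer1(ensemble, X)$decision
  }
  g2 <- trainGANN(gannX, Y, gann)
  new("SubLocModel", layer1 = ensemble, gann = g2,
      featureConfig = fm@config, goSpec = goSpec, goScores = goScores,
      reference = x, featureCenter = std$center, featureScale = std$scale,
      seeds = c(seed = as.integer(seed), gann = as.integer(gann$seed)))
}

#' Predict subcellular locations for query proteins
#'
#' Featurizes the queries with the model's stored configuration (similarity
#' fallbacks against the model's reference set), runs the first-layer
#' ensemble, and combines with the requested second-layer predictor.
#' `"default"` uses the network's set when it predicts exactly one
#' location and the vote set otherwise.
#'
#' @param model a [SubLocModel-class].
#' @param x a [ProteinSet-class] (labels, GO terms and SA profiles optional).
#' @param combiner `"default"`, `"gann"` or `"vote"`.
#' @return a [LocPredictions-class]; with `combiner = "default"` the
#'   per-protein sets of both combiners are also attached as attribute
#'   `components`.
#' @export
predictSubLoc <- function(model, x,
                          combiner = c("default", "gann", "vote")) {
  combiner <- match.arg(combiner)
  stopifnot(is(model, "SubLocModel"), is(x, "ProteinSet"))
  cfg <- model@featureConfig
  short <- Biostrings::width(proteinSequences(x)) < 80L
  if (any(short))
    warning(sum(short), " query protein(s) shorter than 80 residues; ",
            "regions clamp and prediction proceeds")
  if (isTRUE(cfg$useGO) && !length(model@goSpec))
    stop("model bundle is missing its selected GO term list")
  fm <- assembleFeatures(x, cfg,
                         goSpec = if (length(model@goSpec)) model@goSpec,
                         reference = model@reference, leaveSelfOut = FALSE)
  Xq <- .applyStandardize(featureValues(fm), model@featureCenter,
                          model@featureScale)
  out <- predictLayer1(model@layer1, Xq)
  pg <- predictGANN(model@gann, out$decision)
  pv <- predictVote(out$vote, out$specs)
  res <- switch(combiner, gann = pg, vote = pv,
                default = combinePredictions(pg, pv))
  if (combiner == "default") attr(res, "components") <- list(gann = pg,
                                                             vote = pv)
  res
}

# assembleFeatures drops the table but keeps its ids; restore for reuse
.modelConfig <- function(model) model@featureConfig

#' Save / load a trained model bundle
#'
#' The bundle records the model, feature layout, selected GO terms, a
#' fingerprint of the similarity reference set, and the seeds, plus a
#' checksum; loading verifies the format, version and checksum and restores
#' a model giving bit-identical predictions.
#'
#' @param model a [SubLocModel-class].
#' @param path file path for the bundle.
#' @return `saveSubLocModel` returns `path` invisibly; `loadSubLocModel`
#'   returns the [SubLocModel-class].
#' @export
saveSubLocModel <- function(model, path) {
  stopifnot(is(model, "SubLocModel"))
  payload <- serialize(model, NULL, version = 2L)
  tmp <- tempfile()
  writeBin(payload, tmp)
  md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  bundle <- list(format = "SubLocModel-bundle", bundleVersion = 1L,
                 checksum = md5,
                 nReference = length(model@reference),
                 goCount = length(model@goSpec),
                 seeds = model@seeds,
                 payload = payload)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname saveSubLocModel
#' @export
loadSubLocModel <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "SubLocModel-bundle"))
    stop("not a model bundle: ", path)
  if (!identical(bundle$bundleVersion, 1L))
    stop("unsupported bundle version: ", bundle$bundleVersion)
  tmp <- tempfile()
  writeBin(bundle$payload, tmp)
  md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  if (!identical(md5, bundle$checksum))
    stop("bundle checksum mismatch: file corrupted or tampered")
  model <- unserialize(bundle$payload)
  if (!is(model, "SubLocModel")) stop("bundle payload is not a model")
  if (isTRUE(model@featureConfig$useGO) && !length(model@goSpec))
    stop("bundle is missing its selected GO term list")
  model
}
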