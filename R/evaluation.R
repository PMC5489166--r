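.truthSets <- function(truths) {
  if (is(truths, "ProteinSet")) return(locationSets(truths))
  if (is.matrix(truths))
    return(stats::setNames(.locationSetsFromMatrix(truths),
                           rownames(truths)))
  truths
}

.predSets <- function(predictions) {
  if (is(predictions, "LocPredictions"))
    return(stats::setNames(predictions@sets, predictions@ids))
  predictions
}

#' Absolute true success rate
#'
#' The strictest multi-label accuracy: a protein scores 1 iff its predicted
#' location set equals its true set exactly — no under-prediction, no
#' over-prediction — and the rate is the mean score over the N evaluated
#' proteins.
#'
#' @param predictions a [LocPredictions-class] or a named list of predicted
#'   label sets.
#' @param truths a [ProteinSet-class], a logical membership matrix, or a
#'   named list of true label sets. Every prediction id must be present.
#' @return the rate in [0, 1], with attributes `correct` and `total`.
#' @export
atsr <- function(predictions, truths) {
  pred <- .predSets(predictions)
  truth <- .truthSets(truths)
  missing <- setdiff(names(pred), names(truth))
  if (length(missing))
    stop("no truth for id(s): ", paste(utils::head(missing, 5),
                                       collapse = ", "))
  delta <- vapply(names(pred), function(id)
    setequal(pred[[id]], truth[[id]]), logical(1))
  out <- mean(delta)
  attr(out, "correct") <- sum(delta)
  attr(out, "total") <- length(delta)
  out
}

#' Per-location absolute true success rate
#'
#' For each compartment, restricts to the proteins whose TRUE set contains
#' it and reports the fraction of those with an exact-set-match prediction
#' (so a multiplex protein predicted half-right counts as a failure in each
#' of its compartments' rows). Compartments with no member proteins are
#' absent from the result.
#'
#' @inheritParams atsr
#' @return data.frame with columns `location`, `rate`, `correct`, `total`.
#' @export
perLocationATSR <- function(predictions, truths) {
  pred <- .predSets(predictions)
  truth <- .truthSets(truths)
  delta <- vapply(names(pred), function(id)
    setequal(pred[[id]], truth[[id]]), logical(1))
  rows <- lapply(subcellLocations(), function(l) {
    member <- vapply(names(pred), function(id) l %in% truth[[id]],
                     logical(1))
    if (!any(member)) return(NULL)
    data.frame(location = l, rate = mean(delta[member]),
               correct = sum(delta[member]), total = sum(member))
  })
  do.call(rbind, rows)
}

#' Singleplex / multiplex breakdown
#'
#' Partitions proteins by true plexity (exactly one compartment vs two or
#' more) and reports the absolute true success rate within each partition;
#' the two partitions' correct counts always decompose the overall correct
#' count.
#'
#' @inheritParams atsr
#' @return data.frame with rows `singleplex`, `multiplex`, `overall` and
#'   columns `rate`, `correct`, `total` (rate is `NA` for an empty
#'   partition).
#' @export
plexBreakdown <- function(predictions, truths) {
  pred <- .predSets(predictions)
  truth <- .truthSets(truths)
  delta <- vapply(names(pred), function(id)
    setequal(pred[[id]], truth[[id]]), logical(1))
  plex <- vapply(names(pred), function(id) length(truth[[id]]), integer(1))
  one <- plex == 1L
  mk <- function(sel) data.frame(
    rate = if (any(sel)) mean(delta[sel]) else NA_real_,
    correct = sum(delta[sel]), total = sum(sel))
  out <- rbind(singleplex = mk(one), multiplex = mk(!one),
               overall = mk(rep(TRUE, length(delta))))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "rate", "correct", "total")]
}

#' Full evaluation report
#'
#' @inheritParams atsr
#' @return list with `overall` (rate, correct, total), `perLocation`
#'   (data.frame) and `plex` (data.frame).
#' @export
evalReport <- function(predictions, truths) {
  a <- atsr(predictions, truths)
  list(overall = list(rate = as.numeric(a),
                      correct = attr(a, "correct"),
                      total = attr(a, "total")),
       perLocation = perLocationATSR(predictions, truths),
       plex = plexBreakdown(predictions, truths))
}

# Greedy multi-label stratification: assign proteins to folds so that each
# compartment's members spread as evenly as possible. Rarest-label-first,
# deterministic given seed (ties broken by current fold sizes then RNG).
.stratifiedFolds <- function(Y, folds, seed) {
  set.seed(seed)
  n <- nrow(Y)
  fold <- integer(n)
  remaining <- rep(TRUE, n)
  counts <- matrix(0L, folds, ncol(Y))
  sizes <- integer(folds)
  desire <- colSums(Y) / folds
  while (any(remaining)) {
    avail <- colSums(Y[remaining, , drop = FALSE])
    avail[avail == 0L] <- NA
    if (all(is.na(avail))) {
      # label-free leftovers: balance fold sizes
      for (i in which(remaining)) {
        f <- which.min(sizes + stats::runif(folds, 0, 1e-6))
        fold[i] <- f; sizes[f] <- sizes[f] + 1L; remaining[i] <- FALSE
      }
      break
    }
    l <- which.min(avail)
    idx <- which(remaining & Y[, l])
    idx <- idx[order(stats::runif(length(idx)))]
    for (i in idx) {
      need <- desire[l] - counts[, l]
      f <- which(need == max(need))
      if (length(f) > 1L) f <- f[which.min(sizes[f])]
      f <- f[1]
      fold[i] <- f
      counts[f, ] <- counts[f, ] + Y[i, ]
      sizes[f] <- sizes[f] + 1L
      remaining[i] <- FALSE
    }
  }
  fold
}

#' Nested two-layer cross-validation
#'
#' Outer `folds`-fold split stratified over the six compartments. Within
#' each outer-training set, the second layer is trained on OUT-OF-FOLD
#' first-layer outputs produced by an inner `folds`-fold loop, so no
#' protein's second-layer training row ever comes from sub-models that saw
#' that protein; the first layer is then refit on the full outer-training
#' set and the held-out fold is evaluated end to end. GO-term selection,
#' when enabled, is refit inside each outer-training set. The function
#' returns reports for both combiners plus the leakage audit.
#'
#' @param x a labeled [ProteinSet-class].
#' @param config a [featureConfig()] list.
#' @param folds number of outer (and inner) folds, default 5.
#' @param seed master seed; all fold splits and sub-seeds derive from it.
#' @param mPerLocation per-location sub-model counts
#'   (see [defaultPartitionPlan()]).
#' @param gann a [gannConfig()]; its seed is re-derived per outer fold.
#' @param svmParams extra [e1071::svm] arguments.
#' @return list with `gann`, `vote`, `default` evaluation reports
#'   ([evalReport()]), per-fold rates, the pooled predictions, and
#'   `leakageAudit` (logical: TRUE when no layer-2 training row was produced
#'   by sub-models that saw its protein).
#' @export
nestedCV <- function(x, config = featureConfig(), folds = 5L, seed = 1L,
                     mPerLocation = c(5L, 5L, 5L, 5L, 7L, 5L),
                     gann = gannConfig(), svmParams = list()) {
  stopifnot(is(x, "ProteinSet"), folds >= 2L)
  Y <- locationMatrix(x)
  if (!all(rowSums(Y) >= 1L)) stop("nestedCV needs a fully labeled set")
  ids <- names(x)
  outer <- .stratifiedFolds(Y, folds, seed)
  predG <- predV <- predD <- list()
  audit <- TRUE
  foldRates <- data.frame()
  for (f in seq_len(folds)) {
    trIdx <- which(outer != f); teIdx <- which(outer == f)
    xtr <- x[trIdx]; xte <- x[teIdx]
    Ytr <- Y[trIdx, , drop = FALSE]
    missingLoc <- colSums(Ytr) == 0L
    if (any(missingLoc))
      warning("fold ", f, ": no training positives for ",
              paste(colnames(Y)[missingLoc], collapse = ", "))
    # GO selection inside the outer-training set only
    goSpec <- NULL
    cfgF <- config
    if (isTRUE(config$useGO)) {
      cand <- sort(unique(unlist(goAnnotations(xtr))))
      M <- if (length(cand))
        vapply(cand, function(tm)
          vapply(goAnnotations(xtr), function(tt) tm %in% tt,
                 logical(1)) * 1,
          numeric(length(xtr)))
      else matrix(0, length(xtr), 0L)
      usable <- if (ncol(M)) sum(apply(M, 2L, function(cc)
        length(unique(cc)) > 1L)) else 0L
      k <- min(config$goK, usable)
      if (k >= 1L) {
        goSpec <- suppressMessages(regularMRMR(M, Ytr, k = k))$ids
      } else {
        cfgF$useGO <- FALSE
      }
    }
    Ftr <- assembleFeatures(xtr, cfgF, goSpec = goSpec,
                            reference = xtr, leaveSelfOut = TRUE)
    std <- .standardize(featureValues(Ftr))
    Xtr <- std$X
    # inner loop: out-of-fold layer-1 outputs for layer-2 training
    inner <- .stratifiedFolds(Ytr, folds, seed + 1000L + f)
    oof <- matrix(NA_real_, nrow(Xtr), sum(mPerLocation),
                  dimnames = list(rownames(Xtr), NULL))
    for (g in seq_len(folds)) {
      itr <- which(inner != g); ite <- which(inner == g)
      plan <- defaultPartitionPlan(Ytr[itr, , drop = FALSE], mPerLocation,
                                   seed = seed + 100L * f + g)
      ens <- trainLayer1(Xtr[itr, , drop = FALSE], plan, svmParams)
      seen <- unique(unlist(lapply(plan, function(sp)
        c(sp$pos_ids, sp$neg_ids))))
      if (length(intersect(seen, rownames(Xtr)[ite]))) audit <- FALSE
      out <- predictLayer1(ens, Xtr[ite, , drop = FALSE])
      oof[ite, ] <- out$decision
    }
    # layer 2 on out-of-fold rows; layer 1 refit on the full outer-train
    gcfg <- gann; gcfg$seed <- gann$seed + f
    g2 <- trainGANN(oof, Ytr, gcfg)
    plan <- defaultPartitionPlan(Ytr, mPerLocation, seed = seed + 10L * f)
    ens <- trainLayer1(Xtr, plan, svmParams)
    Fte <- assembleFeatures(xte, cfgF, goSpec = goSpec,
                            reference = xtr, leaveSelfOut = FALSE)
    oute <- predictLayer1(ens, .applyStandardize(featureValues(Fte),
                                                 std$center, std$scale))
    pg <- predictGANN(g2, oute$decision)
    pv <- predictVote(oute$vote, oute$specs)
    pd <- combinePredictions(pg, pv)
    predG[[f]] <- pg; predV[[f]] <- pv; predD[[f]] <- pd
    truthF <- locationSets(xte)
    foldRates <- rbind(foldRates, data.frame(
      fold = f, gann = as.numeric(atsr(pg, truthF)),
      vote = as.numeric(atsr(pv, truthF)),
      default = as.numeric(atsr(pd, truthF))))
  }
  pool <- function(ps) {
    new("LocPredictions",
        ids = unlist(lapply(ps, slot, "ids")),
        sets = do.call(c, lapply(ps, slot, "sets")),
        scores = do.call(rbind, lapply(ps, slot, "scores")),
        combiner = ps[[1]]@combiner)
  }
  truth <- locationSets(x)
  pg <- pool(predG); pv <- pool(predV); pd <- pool(predD)
  list(gann = evalReport(pg, truth),
       vote = evalReport(pv, truth),
       default = evalReport(pd, truth),
       foldRates = foldRates,
       predictions = list(gann = pg, vote = pv, default = pd),
       leakageAudit = audit)
}
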