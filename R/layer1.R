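# z-score standardization with training-set parameters; constant columns
# are left at zero so the RBF kernel ignores them
.standardize <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

.applyStandardize <- function(X, center, scale) {
  sweep(sweep(X, 2L, center), 2L, scale, "/")
}

# decision values of a binary pos/neg SVM, oriented so positive = "pos"
.decisionValues <- function(fit, X) {
  dv <- attr(stats::predict(fit, X, decision.values = TRUE),
             "decision.values")
  if (identical(colnames(dv)[1], "neg/pos")) dv <- -dv
  dv[, 1]
}

#' Plan negative partitions for one location's sub-models
#'
#' All proteins annotated to the location are shared positives of its `m`
#' sub-models; the remaining proteins (the negatives) are shuffled by `seed`
#' and split into `m` near-equal disjoint chunks, so every negative is used
#' by exactly one sub-model and no negative information is lost. `m` must be
#' odd (majority voting over the sub-models can then never tie) and between
#' 3 and 9. The realized negatives-per-positive ratio of each chunk is
#' recorded; when a `targetRatio` is given it is bookkeeping only — chunk
#' size wins so that coverage stays complete.
#'
#' @param Y logical membership matrix (proteins x 6), rownames = ids.
#' @param location one of [subcellLocations()].
#' @param m odd number of sub-models in 3..9.
#' @param seed RNG seed for the negative shuffle.
#' @param targetRatio optional target negatives-per-positive ratio, recorded
#'   alongside the realized ratio.
#' @return list of `m` sub-model specs: `location`, `model_index`,
#'   `pos_ids`, `neg_ids`, `ratio`.
#' @export
planPartitions <- function(Y, location, m, seed = 1L, targetRatio = NULL) {
  location <- normalizeLocation(location)
  if (m %% 2L == 0L) stop("m must be odd, got ", m)
  if (m < 3L || m > 9L) stop("m must be in 3..9, got ", m)
  ids <- rownames(Y)
  pos <- ids[Y[, location]]
  neg <- ids[!Y[, location]]
  if (!length(pos)) stop("no positives for ", location)
  if (length(neg) < m)
    stop("fewer negatives (", length(neg), ") than sub-models (", m, ")")
  set.seed(seed)
  neg <- sample(neg)
  chunk <- rep(seq_len(m), each = length(neg) %/% m)
  chunk <- c(chunk, seq_len(length(neg) - length(chunk)))
  chunk <- sort(chunk)
  lapply(seq_len(m), function(i) {
    ni <- neg[chunk == i]
    list(location = location, model_index = i, pos_ids = pos, neg_ids = ni,
         ratio = length(ni) / length(pos),
         target_ratio = if (is.null(targetRatio)) NA_real_ else targetRatio)
  })
}

#' Default partition plan over all six locations
#'
#' Per-location sub-model counts default to (5, 5, 5, 5, 7, 5) in
#' compartment-code order — all odd, within 3..9, totalling 32 sub-models.
#'
#' @param Y logical membership matrix (proteins x 6).
#' @param mPerLocation named or positional integer vector of per-location
#'   sub-model counts.
#' @param seed RNG seed for the negative shuffles (one offset per location).
#' @return flat list of sub-model specs in fixed (location, index) order.
#' @export
defaultPartitionPlan <- function(Y, mPerLocation = c(5L, 5L, 5L, 5L, 7L, 5L),
                                 seed = 1L) {
  locs <- subcellLocations()
  if (is.null(names(mPerLocation))) names(mPerLocation) <- locs
  do.call(c, lapply(seq_along(locs), function(k)
    planPartitions(Y, locs[k], mPerLocation[[locs[k]]],
                   seed = seed + k)))
}

#' Sweep the negative ratio and sub-model count for one location
#'
#' Grid search over (ratio, m): for each setting, `folds`-fold
#' cross-validated membership accuracy of the location's majority-voted
#' sub-ensemble, where each sub-model sees all fold-train positives and a
#' disjoint negative chunk subsampled to at most `ratio` negatives per
#' positive. Ties break to the smaller m, then the smaller ratio.
#'
#' @param X numeric feature matrix (rownames = ids).
#' @param Y logical membership matrix.
#' @param location one of [subcellLocations()].
#' @param ratioGrid numeric vector of negatives-per-positive ratios.
#' @param mGrid integer vector of odd sub-model counts.
#' @param folds CV folds (default 3).
#' @param seed RNG seed.
#' @param svmParams list of [e1071::svm] arguments.
#' @return list with `ratio`, `m` and the full `score` matrix (m x ratio).
#' @export
chooseRatioAndM <- function(X, Y, location, ratioGrid, mGrid, folds = 3L,
                            seed = 1L, svmParams = list()) {
  stopifnot(length(ratioGrid) >= 1L, length(mGrid) >= 1L)
  if (any(mGrid %% 2L == 0L)) stop("mGrid must contain odd values only")
  location <- normalizeLocation(location)
  mGrid <- sort(mGrid); ratioGrid <- sort(ratioGrid)
  y <- Y[, location]
  X <- .standardize(X)$X
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  score <- matrix(NA_real_, length(mGrid), length(ratioGrid),
                  dimnames = list(mGrid, ratioGrid))
  for (mi in seq_along(mGrid)) for (ri in seq_along(ratioGrid)) {
    m <- mGrid[mi]; ratio <- ratioGrid[ri]
    ok <- 0L
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      pos <- tr[y[tr]]; neg <- sample(tr[!y[tr]])
      if (length(pos) < 2L || length(neg) < m) next
      chunks <- split(neg, sort(rep_len(seq_len(m), length(neg))))
      votes <- matrix(0L, length(te), m)
      for (i in seq_len(m)) {
        ni <- chunks[[i]]
        cap <- max(1L, round(ratio * length(pos)))
        if (length(ni) > cap) ni <- ni[seq_len(cap)]
        idx <- c(pos, ni)
        ytr <- factor(ifelse(y[idx], "pos", "neg"), levels = c("pos", "neg"))
        fit <- do.call(e1071::svm, c(list(
          x = X[idx, , drop = FALSE], y = ytr, kernel = "radial",
          scale = FALSE), svmParams))
        votes[, i] <- as.integer(.decisionValues(fit, X[te, , drop = FALSE]) > 0)
      }
      ok <- ok + sum((rowSums(votes) > m / 2) == y[te])
    }
    score[mi, ri] <- ok / n
  }
  best <- which(score == max(score, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(ratio = ratioGrid[best[2]], m = mGrid[best[1]], score = score)
}

#' Train the first layer of binary SVM sub-models
#'
#' Fits one soft-margin RBF SVM per sub-model spec (positives labeled
#' `pos`, the spec's negative chunk labeled `neg`), using the libsvm engine
#' via \pkg{e1071}. Training is deterministic given the data and
#' parameters.
#'
#' @param X numeric feature matrix (rownames = ids).
#' @param plan flat list of sub-model specs from [defaultPartitionPlan()] or
#'   [planPartitions()].
#' @param svmParams extra arguments passed to [e1071::svm] (e.g. `cost`,
#'   `gamma`); kernel defaults to RBF with `gamma = 1/ncol(X)`.
#' @return a [Layer1Ensemble-class].
#' @export
trainLayer1 <- function(X, plan, svmParams = list()) {
  stopifnot(length(plan) >= 1L)
  models <- vector("list", length(plan))
  specs <- data.frame(location = character(0), model_index = integer(0),
                      n_pos = integer(0), n_neg = integer(0),
                      ratio = numeric(0))
  for (i in seq_along(plan)) {
    sp <- plan[[i]]
    if (!length(sp$pos_ids))
      stop("empty positive set in sub-model ", sp$location, "/",
           sp$model_index)
    if (!length(sp$neg_ids))
      stop("single-class training set in sub-model ", sp$location, "/",
           sp$model_index)
    idx <- c(sp$pos_ids, sp$neg_ids)
    miss <- setdiff(idx, rownames(X))
    if (length(miss))
      stop("ids missing from feature matrix: ",
           paste(utils::head(miss, 3), collapse = ", "))
    ytr <- factor(rep(c("pos", "neg"),
                      c(length(sp$pos_ids), length(sp$neg_ids))),
                  levels = c("pos", "neg"))
    models[[i]] <- do.call(e1071::svm, c(list(
      x = X[idx, , drop = FALSE], y = ytr, kernel = "radial",
      scale = FALSE), svmParams))
    specs <- rbind(specs, data.frame(
      location = sp$location, model_index = sp$model_index,
      n_pos = length(sp$pos_ids), n_neg = length(sp$neg_ids),
      ratio = sp$ratio))
  }
  new("Layer1Ensemble", models = models, specs = specs,
      partition = plan, featureNames = colnames(X))
}

#' First-layer outputs for a set of proteins
#'
#' Runs every sub-model on the feature rows and returns both the signed
#' decision values (positive = membership side) and the hard votes
#' (`vote = 1` iff decision value > 0), in fixed (location, model index)
#' order — the same order at train and predict time.
#'
#' @param ensemble a [Layer1Ensemble-class].
#' @param X numeric feature matrix with the ensemble's column layout.
#' @return list with matrices `decision` and `vote` (proteins x sub-models)
#'   and the `specs` data.frame giving the column order.
#' @export
predictLayer1 <- function(ensemble, X) {
  stopifnot(is(ensemble, "Layer1Ensemble"))
  if (!identical(colnames(X), ensemble@featureNames))
    stop("feature columns do not match the ensemble's training layout (",
         ncol(X), " vs ", length(ensemble@featureNames), ")")
  dec <- vapply(ensemble@models, function(m) .decisionValues(m, X),
                numeric(nrow(X)))
  if (nrow(X) == 1L) dec <- matrix(dec, nrow = 1L)
  rownames(dec) <- rownames(X)
  colnames(dec) <- paste0(ensemble@specs$location, "_",
                          ensemble@specs$model_index)
  list(decision = dec, vote = (dec > 0) * 1L, specs = ensemble@specs)
}
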