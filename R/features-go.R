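#' Binary GO-term feature vector
#'
#' Entry j is 1 iff the j-th selected GO term annotates the protein.
#' Annotations come from the protein's direct terms; a protein with no
#' direct terms may borrow the terms of its most similar annotated
#' reference protein (supply `fallbackTerms`); otherwise an all-zero vector
#' with attribute `missing = TRUE` is returned.
#'
#' @param terms character vector of the protein's GO ids (possibly empty).
#' @param spec ordered character vector of selected GO ids (see
#'   [regularMRMR()]).
#' @param fallbackTerms optional GO ids of the most similar annotated
#'   protein, used when `terms` is empty.
#' @return named numeric 0/1 vector of length `length(spec)`.
#' @export
goFeatureVector <- function(terms, spec, fallbackTerms = NULL) {
  used <- terms
  missing <- FALSE
  if (!length(used)) {
    if (length(fallbackTerms)) used <- fallbackTerms
    else missing <- TRUE
  }
  out <- as.numeric(spec %in% used)
  names(out) <- paste0("go_", spec)
  if (missing) attr(out, "missing") <- TRUE
  out
}

# Mutual information of two binary vectors from empirical 2x2 counts,
# with 0 * log 0 = 0 and no pseudo-counts. Natural log.
.binaryMI <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) {
      pa <- sum(x == a) / n
      pb <- sum(y == b) / n
      mi <- mi + pab * log(pab / (pa * pb))
    }
  }
  mi
}

# relevance of each candidate column: mean MI against the 6 one-vs-rest
# location indicators
.goRelevance <- function(M, Y) {
  apply(M, 2L, function(col)
    mean(apply(Y, 2L, function(y) .binaryMI(col, y * 1))))
}

#' Greedy mutual-information mRMR selection of GO terms
#'
#' Forward selection of `k` GO terms for multi-label localization. The first
#' pick maximizes relevance, defined as the mean mutual information between
#' the term's presence indicator and the six one-vs-rest location
#' indicators; each subsequent pick maximizes relevance minus redundancy,
#' where redundancy is the mean mutual information with the already-selected
#' terms (the MID difference criterion). Mutual information is computed from
#' empirical 2x2 counts with `0 log 0 = 0`. Constant (all-0 or all-1)
#' columns are skipped with a message. Ties break on the lexicographically
#' smallest GO id, so selection is deterministic and invariant to protein
#' row order.
#'
#' @param M binary matrix, proteins x candidate GO terms (colnames = GO
#'   ids).
#' @param Y logical matrix, proteins x 6 locations.
#' @param k number of terms to select (default 35).
#' @return list with `ids` (ordered selected terms) and `scores` (the
#'   criterion value at each pick).
#' @export
regularMRMR <- function(M, Y, k = 35L) {
  stopifnot(is.matrix(M), nrow(M) == nrow(Y), ncol(Y) == 6L)
  if (is.null(colnames(M))) stop("candidate matrix needs GO ids as colnames")
  const <- apply(M, 2L, function(c) all(c == c[1]))
  if (any(const)) {
    message("skipping ", sum(const), " constant candidate column(s)")
    M <- M[, !const, drop = FALSE]
  }
  p <- ncol(M)
  if (k > p) stop("k (", k, ") exceeds usable candidate terms (", p, ")")
  rel <- .goRelevance(M, Y)
  ids <- colnames(M)
  selected <- character(0)
  scores <- numeric(0)
  # cache pairwise MI with selected columns as they accrue
  redSum <- stats::setNames(numeric(p), ids)
  for (step in seq_len(k)) {
    remaining <- setdiff(ids, selected)
    crit <- if (!length(selected)) rel[remaining] else
      rel[remaining] - redSum[remaining] / length(selected)
    best <- max(crit)
    pick <- sort(remaining[crit >= best - 1e-15])[1]
    selected <- c(selected, pick)
    scores <- c(scores, crit[[pick]])
    if (step < k) {
      remaining <- setdiff(ids, selected)
      addMI <- vapply(remaining, function(id)
        .binaryMI(M[, id], M[, pick]), numeric(1))
      redSum[remaining] <- redSum[remaining] + addMI
    }
  }
  list(ids = selected, scores = scores)
}

#' Choose the number of GO features by cross-validation
#'
#' Ranks candidates once with [regularMRMR()] at the deepest requested `k`,
#' then for each `k` in the grid estimates the absolute true success rate of
#' one-vs-rest SVMs trained on the top-`k` GO features alone, by `folds`-fold
#' cross-validation. Returns the `k` with the best ATSR; ties go to the
#' smallest `k`.
#'
#' @param M binary matrix, proteins x candidate GO terms.
#' @param Y logical matrix, proteins x 6 locations.
#' @param kGrid integer vector of candidate feature counts.
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return list with `k` (the winner), `atsr` (named vector over the grid)
#'   and `ranking` (the full mRMR ranking used).
#' @export
selectGOCount <- function(M, Y, kGrid, folds = 5L, seed = 1L) {
  stopifnot(length(kGrid) >= 1L)
  kGrid <- sort(unique(as.integer(kGrid)))
  if (length(kGrid) == 1L) {
    rk <- regularMRMR(M, Y, k = kGrid)
    return(list(k = kGrid, atsr = stats::setNames(NA_real_, kGrid),
                ranking = rk$ids))
  }
  rk <- regularMRMR(M, Y, k = max(kGrid))
  set.seed(seed)
  n <- nrow(M)
  fold <- sample(rep_len(seq_len(folds), n))
  res <- vapply(kGrid, function(k) {
    X <- M[, rk$ids[seq_len(k)], drop = FALSE]
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f; te <- !tr
      pred <- matrix(FALSE, sum(te), 6L)
      dec <- matrix(-Inf, sum(te), 6L)
      for (l in seq_len(6L)) {
        ytr <- factor(ifelse(Y[tr, l], "pos", "neg"),
                      levels = c("pos", "neg"))
        if (nlevels(droplevels(ytr)) < 2L) next
        fit <- e1071::svm(x = X[tr, , drop = FALSE], y = ytr,
                          kernel = "radial", scale = FALSE)
        dv <- .decisionValues(fit, X[te, , drop = FALSE])
        pred[, l] <- dv > 0
        dec[, l] <- dv
      }
      none <- rowSums(pred) == 0L
      if (any(none)) pred[cbind(which(none), apply(
        dec[none, , drop = FALSE], 1L, which.max))] <- TRUE
      hits <- hits + sum(apply(pred == Y[te, , drop = FALSE], 1L, all))
    }
    hits / n
  }, numeric(1))
  names(res) <- kGrid
  list(k = kGrid[which.max(res)], atsr = res, ranking = rk$ids)
}
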