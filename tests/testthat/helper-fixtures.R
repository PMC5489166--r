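# shared fixtures and independent oracles for the test suite

AB <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomSequence <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AB, len, replace = TRUE), collapse = "")
}

tinyProteinSet <- function(n = 6, len = 100, seed = 42, labeled = TRUE) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) randomSequence(len), "")
  names(seqs) <- sprintf("t%02d", seq_len(n))
  locs <- if (labeled)
    lapply(seq_len(n), function(i)
      sample(subcellLocations(), sample(1:2, 1, prob = c(.8, .2))))
  ProteinSet(seqs, locations = locs)
}

randomAAIndexTable <- function(seed = 1, n = 100) {
  set.seed(seed)
  m <- matrix(rnorm(n * 20, 0, 3), n, 20)
  colnames(m) <- AB
  rownames(m) <- sprintf("RND%04d", seq_len(n))
  m
}

# letter-count composition oracle
aacOracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  vapply(AB, function(a) sum(ch == a), numeric(1)) / nchar(s)
}

# brute-force mutual information of two binary vectors (natural log)
miOracle <- function(x, y) {
  n <- length(x); mi <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0)
      mi <- mi + pab * log(pab / (sum(x == a) / n * sum(y == b) / n))
  }
  mi
}

# exhaustive greedy mRMR oracle (recomputes every MI term naively)
mrmrOracle <- function(M, Y, k) {
  ids <- colnames(M)
  const <- apply(M, 2, function(c) all(c == c[1]))
  ids <- ids[!const]
  rel <- vapply(ids, function(j)
    mean(vapply(seq_len(ncol(Y)), function(l)
      miOracle(M[, j], Y[, l] * 1), numeric(1))), numeric(1))
  sel <- character(0)
  for (step in seq_len(k)) {
    rem <- setdiff(ids, sel)
    crit <- vapply(rem, function(j) {
      red <- if (length(sel))
        mean(vapply(sel, function(s) miOracle(M[, j], M[, s]), numeric(1)))
      else 0
      rel[[j]] - red
    }, numeric(1))
    sel <- c(sel, sort(rem[crit >= max(crit) - 1e-15])[1])
  }
  sel
}

# affine-gap Smith-Waterman oracle (independent dynamic program)
swOracle <- function(a, b, gapOpen = 11, gapExt = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - gapOpen, X[i - 1, j] - gapExt)
    Y[i, j] <- max(M[i, j - 1] - gapOpen, Y[i, j - 1] - gapExt)
    M[i, j] <- max(0, S[a[i - 1], b[j - 1]] +
                     max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
    best <- max(best, M[i, j])
  }
  best
}

randomTruthAndPred <- function(n, seed) {
  set.seed(seed)
  locs <- subcellLocations()
  ids <- sprintf("r%04d", seq_len(n))
  truth <- lapply(seq_len(n), function(i) sample(locs, sample(1:3, 1)))
  pred <- lapply(seq_len(n), function(i)
    if (runif(1) < 0.4) truth[[i]] else sample(locs, sample(1:3, 1)))
  list(truth = setNames(truth, ids), pred = setNames(pred, ids))
}
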