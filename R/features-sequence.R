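#' Extract the four analysis regions of a protein sequence
#'
#' Localization signal concentrates in particular parts of a protein
#' (N-terminal targeting peptides, C-terminal retention signals), so
#' encoders are applied to four regions: the full sequence, the first 30
#' N-terminal residues, the middle third, and the last 50 C-terminal
#' residues. For short sequences the N/C regions clamp to the full length
#' and regions may overlap. The middle third is the centered contiguous
#' slice of length `floor(len/3)` starting at `floor((len - floor(len/3))/2)`
#' (0-based), i.e. regions for a 90-mer are 1-90, 1-30, 31-60 and 41-90.
#'
#' @param sequence a single amino-acid sequence (character).
#' @return named list of character sequences: `full`, `n30`, `mid3`, `c50`.
#' @export
extractRegions <- function(sequence) {
  sequence <- as.character(sequence)
  len <- nchar(sequence)
  if (is.na(len) || len < 1L) stop("empty sequence")
  idx <- regionIndices(len)
  lapply(idx, function(r)
    if (length(r)) substr(sequence, r[1], r[length(r)]) else "")
}

#' @rdname extractRegions
#' @param len sequence length.
#' @return `regionIndices` returns the list of 1-based index vectors for the
#'   four regions.
#' @export
regionIndices <- function(len) {
  stopifnot(len >= 1L)
  m <- len %/% 3L
  midStart <- (len - m) %/% 2L + 1L
  list(
    full = seq_len(len),
    n30  = seq_len(min(30L, len)),
    mid3 = if (m >= 1L) seq.int(midStart, midStart + m - 1L) else integer(0),
    c50  = seq.int(max(1L, len - 49L), len)
  )
}

#' Amino acid composition of a region
#'
#' Fraction of each of the 20 standard amino acids in the region:
#' `AAC(a) = count(a) / N` with `N` the region length. For an empty region a
#' zero vector is returned with attribute `empty = TRUE` so downstream
#' prediction never aborts mid-batch.
#'
#' @param region a region sequence (character).
#' @return named numeric vector of length 20 (alphabetical one-letter
#'   order) summing to 1 for non-empty regions.
#' @examples
#' computeAAC("ACDEFGHIKLMNPQRSTVWY")  # uniformly 0.05
#' @export
computeAAC <- function(region) {
  region <- as.character(region)
  ab <- aminoAcidAlphabet()
  if (!nzchar(region)) {
    out <- stats::setNames(numeric(20L), ab)
    attr(out, "empty") <- TRUE
    return(out)
  }
  counts <- table(factor(strsplit(region, "")[[1]], levels = ab))
  out <- as.numeric(counts) / nchar(region)
  names(out) <- ab
  out
}

#' Weighted sign amino-acid-index encoding
#'
#' Projects a composition vector onto each of 100 physicochemical scales and
#' encodes, per scale, the sign and the log-magnitude of the projection:
#' `score_i = sum_j AAC(a_j) * h_ij`, `C_i = log10(max(|score_i|, epsilon))`,
#' `sign_i = 1` if `score_i < 0` else `0`. The zero floor `epsilon` keeps
#' the log finite when a projection vanishes; the log base only rescales
#' `C_i` uniformly.
#'
#' @param aac numeric composition vector of length 20 (see [computeAAC()]).
#' @param table scales x 20 matrix, see [defaultAAIndexTable()].
#' @param epsilon floor on `|score|` before the log (default 1e-6).
#' @return list with numeric vectors `score`, `sign` (0/1) and `C`, one
#'   entry per scale.
#' @export
computeWeightedSignAAIndex <- function(aac, table, epsilon = 1e-6) {
  if (!all(is.finite(table))) stop("AAindex table contains non-finite values")
  stopifnot(length(aac) == 20L, ncol(table) == 20L)
  score <- as.numeric(table %*% aac)
  list(score = score,
       sign  = as.integer(score < 0),
       C     = log10(pmax(abs(score), epsilon)))
}

#' Physicochemical properties for parallel-correlation PseAAC
#'
#' Hydrophobicity, hydrophilicity and side-chain mass of the 20 standard
#' amino acids, each standardized to zero mean and unit population standard
#' deviation over the 20 acids (the PseAAC convention).
#'
#' @return 3 x 20 numeric matrix (rows: hydrophobicity, hydrophilicity,
#'   side-chain mass; columns alphabetical one-letter order).
#' @export
pcPseAACProperties <- function() {
  ab <- aminoAcidAlphabet()
  hydrophobicity <- c(
    A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
    H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
    P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
    W = 0.81, Y = 0.26)
  hydrophilicity <- c(
    A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
    H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
    P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
    W = -3.4, Y = -2.3)
  sideChainMass <- c(
    A = 15, C = 47, D = 59, E = 73, F = 91, G = 1,
    H = 82, I = 57, K = 73, L = 57, M = 75, N = 58,
    P = 42, Q = 72, R = 101, S = 31, T = 45, V = 43,
    W = 130, Y = 107)
  std <- function(v) {
    v <- v[ab]
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  m <- rbind(hydrophobicity = std(hydrophobicity),
             hydrophilicity = std(hydrophilicity),
             sideChainMass  = std(sideChainMass))
  colnames(m) <- ab
  m
}

# mean squared property difference between residue pairs, 20 x 20
.pseaacThetaMatrix <- function(props = pcPseAACProperties()) {
  ab <- aminoAcidAlphabet()
  Th <- matrix(0, 20L, 20L, dimnames = list(ab, ab))
  for (k in seq_len(nrow(props))) {
    d <- outer(props[k, ], props[k, ], `-`)
    Th <- Th + d^2
  }
  Th / nrow(props)
}

#' Parallel-correlation pseudo amino acid composition
#'
#' The classic type-1 (parallel-correlation) PseAAC: 20 composition entries
#' augmented with `lambda` sequence-order correlation factors
#' `theta_j = mean_i Theta(R_i, R_{i+j})`, where `Theta` is the mean squared
#' difference of three standardized physicochemical properties
#' (hydrophobicity, hydrophilicity, side-chain mass). Entries are combined
#' with weight `omega` and normalized so the vector sums to 1; with
#' `lambda = 0` the vector reduces exactly to the composition.
#'
#' @param sequence amino-acid sequence (character), length must exceed
#'   `lambda`.
#' @param lambda number of correlation tiers (default 8).
#' @param omega weight factor for the correlation part (default 0.05).
#' @return named numeric vector of length `20 + lambda`, non-negative,
#'   summing to 1.
#' @export
computePseAAC <- function(sequence, lambda = 8L, omega = 0.05) {
  sequence <- as.character(sequence)
  len <- nchar(sequence)
  if (lambda < 0L) stop("lambda must be >= 0")
  if (len <= lambda)
    stop("sequence length (", len, ") must exceed lambda (", lambda,
         "): shorten lambda or supply a longer sequence")
  aac <- computeAAC(sequence)
  theta <- numeric(lambda)
  if (lambda > 0L) {
    Th <- .pseaacThetaMatrix()
    s <- match(strsplit(sequence, "")[[1]], aminoAcidAlphabet())
    for (j in seq_len(lambda)) {
      i <- seq_len(len - j)
      theta[j] <- mean(Th[cbind(s[i], s[i + j])])
    }
  }
  denom <- 1 + omega * sum(theta)
  out <- c(aac, omega * theta) / denom
  names(out) <- c(aminoAcidAlphabet(),
                  if (lambda > 0L) paste0("theta", seq_len(lambda)))
  out
}

#' Sequence-derived feature block for one protein
#'
#' Concatenates, in fixed documented order: amino acid composition of the
#' four regions (80 values), the weighted sign aa-index of the four regions
#' (sign and C interleaved per scale; 2 x 100 x 4 = 800 values), and the
#' PseAAC vector (20 + lambda values). The attached block map records every
#' span.
#'
#' @param sequence amino-acid sequence (character).
#' @param table AAindex matrix, see [defaultAAIndexTable()].
#' @param lambda,omega PseAAC parameters.
#' @param epsilon zero floor for the weighted-sign log.
#' @return named numeric vector with attribute `blockMap` (data.frame with
#'   `block`, `start`, `end`).
#' @export
sequenceFeatureBlock <- function(sequence, table = defaultAAIndexTable(),
                                 lambda = 8L, omega = 0.05,
                                 epsilon = 1e-6) {
  regions <- extractRegions(sequence)
  rn <- names(regions)
  parts <- list()
  for (r in rn) {
    v <- computeAAC(regions[[r]])
    names(v) <- paste0("aac_", r, "_", names(v))
    parts[[paste0("aac_", r)]] <- v
  }
  for (r in rn) {
    ws <- computeWeightedSignAAIndex(computeAAC(regions[[r]]), table, epsilon)
    inter <- as.numeric(rbind(ws$sign, ws$C))
    names(inter) <- as.vector(rbind(
      paste0("ws_", r, "_sign_", rownames(table)),
      paste0("ws_", r, "_C_", rownames(table))))
    parts[[paste0("wsaai_", r)]] <- inter
  }
  ps <- computePseAAC(sequence, lambda = lambda, omega = omega)
  names(ps) <- paste0("pseaac_", names(ps))
  parts[["pseaac"]] <- ps
  out <- unlist(parts, use.names = TRUE)
  names(out) <- sub("^[^.]+\\.", "", names(out))
  lens <- lengths(parts)
  ends <- cumsum(lens)
  attr(out, "blockMap") <- data.frame(
    block = names(parts), start = ends - lens + 1L, end = ends,
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# Vectorized sequence block for an AAStringSet: identical layout to
# sequenceFeatureBlock, one row per protein.
.sequenceBlockMatrix <- function(seqs, table, lambda = 8L, omega = 0.05,
                                 epsilon = 1e-6) {
  ab <- aminoAcidAlphabet()
  n <- length(seqs)
  chars <- as.character(seqs)
  w <- nchar(chars)
  regionSeqs <- list(
    full = chars,
    n30  = substr(chars, 1L, pmin(30L, w)),
    mid3 = {
      m <- w %/% 3L
      st <- (w - m) %/% 2L + 1L
      substr(chars, st, st + m - 1L)
    },
    c50  = substr(chars, pmax(1L, w - 49L), w))
  aacs <- lapply(regionSeqs, function(rs) {
    rw <- nchar(rs)
    fr <- Biostrings::letterFrequency(Biostrings::AAStringSet(rs), ab)
    fr / ifelse(rw == 0L, 1L, rw)
  })
  cols <- list()
  for (r in names(aacs)) {
    a <- aacs[[r]]
    colnames(a) <- paste0("aac_", r, "_", ab)
    cols[[paste0("aac_", r)]] <- a
  }
  for (r in names(aacs)) {
    score <- aacs[[r]] %*% t(table)               # n x 100
    sgn <- (score < 0) * 1
    C <- log10(pmax(abs(score), epsilon))
    inter <- matrix(0, n, 2L * ncol(score))
    inter[, seq(1L, ncol(inter), 2L)] <- sgn
    inter[, seq(2L, ncol(inter), 2L)] <- C
    colnames(inter) <- as.vector(rbind(
      paste0("ws_", r, "_sign_", rownames(table)),
      paste0("ws_", r, "_C_", rownames(table))))
    cols[[paste0("wsaai_", r)]] <- inter
  }
  Th <- .pseaacThetaMatrix()
  pse <- t(vapply(chars, function(sq) {
    len <- nchar(sq)
    aac <- Biostrings::letterFrequency(Biostrings::AAStringSet(sq), ab)[1, ] / len
    theta <- numeric(lambda)
    if (lambda > 0L && len > 1L) {
      s <- match(strsplit(sq, "")[[1]], ab)
      for (j in seq_len(min(lambda, len - 1L))) {
        i <- seq_len(len - j)
        theta[j] <- mean(Th[cbind(s[i], s[i + j])])
      }
    }
    c(aac, omega * theta) / (1 + omega * sum(theta))
  }, numeric(20L + lambda)))
  colnames(pse) <- paste0("pseaac_", c(ab, if (lambda > 0L)
    paste0("theta", seq_len(lambda))))
  rownames(pse) <- NULL
  cols[["pseaac"]] <- pse
  vals <- do.call(cbind, cols)
  rownames(vals) <- names(seqs)
  lens <- vapply(cols, ncol, integer(1))
  ends <- cumsum(lens)
  list(values = vals,
       blockMap = data.frame(block = names(cols),
                             start = ends - lens + 1L, end = ends,
                             stringsAsFactors = FALSE, row.names = NULL))
}
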