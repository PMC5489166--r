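#' Configuration of the genetic-algorithm-trained network
#'
#' Hyperparameters of the second-layer GANN. The defaults are the published
#' operating point: population 500, mutation rate 0.3, crossover rate 0.7,
#' weights bounded in [-25, 25], at most 1000 generations, and an error
#' (mean squared error) stopping target of 0.05. Operator details the
#' published setting leaves open are fixed here for reproducibility:
#' tournament selection of size 3, per-gene blend (BLX-0.5) crossover
#' applied to a parent pair with probability `crossoverRate`, mutation
#' applied to an offspring
#' with probability `mutationRate` (each gene then perturbed with
#' probability `geneMutationRate` by Gaussian noise of sd `mutationSigma`,
#' clipped to the bounds), and elitism of one.
#'
#' @param population GA population size.
#' @param mutationRate per-offspring mutation probability.
#' @param crossoverRate per-pair crossover probability.
#' @param maxW,minW weight bounds.
#' @param maxGen maximum generations.
#' @param errorTarget stop once best MSE is at or below this.
#' @param hiddenSize hidden-layer width (default 16).
#' @param seed RNG seed.
#' @param mutationSigma sd of the Gaussian gene perturbation.
#' @param geneMutationRate per-gene perturbation probability within a
#'   mutated offspring.
#' @return named list.
#' @export
gannConfig <- function(population = 500L, mutationRate = 0.3,
                       crossoverRate = 0.7, maxW = 25, minW = -25,
                       maxGen = 1000L, errorTarget = 0.05,
                       hiddenSize = 16L, seed = 1L,
                       mutationSigma = 2, geneMutationRate = 0.05) {
  stopifnot(minW < maxW, population >= 2L,
            mutationRate >= 0, mutationRate <= 1,
            crossoverRate >= 0, crossoverRate <= 1)
  list(population = as.integer(population), mutationRate = mutationRate,
       crossoverRate = crossoverRate, maxW = maxW, minW = minW,
       maxGen = as.integer(maxGen), errorTarget = errorTarget,
       hiddenSize = as.integer(hiddenSize), seed = as.integer(seed),
       mutationSigma = mutationSigma, geneMutationRate = geneMutationRate)
}

.gannForward <- function(w, Xb, d, h, K) {
  a <- (d + 1L) * h
  W1 <- matrix(w[seq_len(a)], d + 1L, h)
  W2 <- matrix(w[(a + 1L):length(w)], h + 1L, K)
  stats::plogis(cbind(1, stats::plogis(Xb %*% W1)) %*% W2)
}

#' Train the second-layer network by a genetic algorithm
#'
#' Evolves the flattened weight vector of a single-hidden-layer sigmoid
#' network mapping first-layer decision values to six location activations.
#' Initialization is uniform in `[minW, maxW]`; fitness is the negative
#' mean squared error between activations and the 0/1 label matrix; the
#' best individual is carried over unchanged each generation (elitism), so
#' the best MSE is non-increasing. Evolution stops at `maxGen` generations
#' or as soon as the best MSE reaches `errorTarget`. Runs are bit-exactly
#' reproducible for a fixed seed.
#'
#' @param X numeric matrix of first-layer decision values (proteins x
#'   sub-models).
#' @param Y 0/1 (or logical) label matrix, proteins x 6.
#' @param config a [gannConfig()] list.
#' @return a [GannModel-class].
#' @export
trainGANN <- function(X, Y, config = gannConfig()) {
  X <- as.matrix(X)
  Y <- matrix(as.numeric(Y), nrow(X))
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(unique(Y)) == 1L)
    warning("degenerate labels: all rows identical")
  d <- ncol(X); K <- ncol(Y); h <- config$hiddenSize
  Xb <- cbind(1, X)
  a <- (d + 1L) * h
  L <- a + (h + 1L) * K
  set.seed(config$seed)
  pop <- config$population
  P <- matrix(stats::runif(pop * L, config$minW, config$maxW), pop, L)
  mse <- function(w) mean((.gannForward(w, Xb, d, h, K) - Y)^2)
  f <- apply(P, 1L, mse)
  history <- numeric(0)
  gen <- 0L
  repeat {
    bi <- which.min(f)
    history <- c(history, f[bi])
    if (f[bi] <= config$errorTarget || gen >= config$maxGen) break
    gen <- gen + 1L
    newP <- matrix(0, pop, L)
    newf <- numeric(pop)
    newP[1L, ] <- P[bi, ]; newf[1L] <- f[bi]      # elitism of one
    i <- 2L
    tournament <- function() {
      cand <- sample.int(pop, 3L)
      cand[which.min(f[cand])]
    }
    while (i <= pop) {
      p1 <- P[tournament(), ]
      p2 <- P[tournament(), ]
      if (stats::runif(1) < config$crossoverRate) {
        # per-gene blend (BLX-0.5): children sample the segment spanned by
        # the parents, extended by half its length on both sides — unlike a
        # plain gene swap this lets the population refine weights
        # continuously instead of only recombining existing values
        al <- stats::runif(L, -0.5, 1.5)
        c1 <- al * p1 + (1 - al) * p2
        p2 <- (1 - al) * p1 + al * p2
        p1 <- c1
      }
      for (child in list(p1, p2)) {
        if (i > pop) break
        if (stats::runif(1) < config$mutationRate) {
          g <- stats::runif(L) < config$geneMutationRate
          child[g] <- child[g] +
            stats::rnorm(sum(g), 0, config$mutationSigma)
        }
        child <- pmin(pmax(child, config$minW), config$maxW)
        newP[i, ] <- child
        newf[i] <- mse(child)
        i <- i + 1L
      }
    }
    P <- newP; f <- newf
  }
  best <- P[which.min(f), ]
  new("GannModel",
      W1 = matrix(best[seq_len(a)], d + 1L, h),
      W2 = matrix(best[(a + 1L):L], h + 1L, K),
      config = config, history = history)
}

.threshToSets <- function(act, threshold = 0.5) {
  locs <- subcellLocations()
  lapply(seq_len(nrow(act)), function(i) {
    s <- locs[act[i, ] >= threshold]
    # every protein resides somewhere: fall back to the top activation,
    # ties to the lowest location code
    if (!length(s)) s <- locs[which.max(act[i, ])]
    s
  })
}

#' Predict location sets with the trained network
#'
#' A location is included when its output activation reaches 0.5; if no
#' activation does, the single highest-activation location is returned
#' (ties to the lowest location code), so the predicted set is never empty.
#'
#' @param model a [GannModel-class].
#' @param X matrix (or vector) of first-layer decision values.
#' @return a [LocPredictions-class].
#' @export
predictGANN <- function(model, X) {
  stopifnot(is(model, "GannModel"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  d <- nrow(model@W1) - 1L
  if (ncol(X) != d)
    stop("input length ", ncol(X), " does not match network inputs ", d)
  act <- .gannForward(c(model@W1, model@W2), cbind(1, X), d,
                      ncol(model@W1), ncol(model@W2))
  colnames(act) <- subcellLocations()
  rownames(act) <- rownames(X)
  ids <- if (is.null(rownames(X))) paste0("query_", seq_len(nrow(X))) else
    rownames(X)
  new("LocPredictions", ids = ids, sets = .threshToSets(act),
      scores = act, combiner = "gann")
}

#' Predict location sets by strict-majority voting
#'
#' For each location, the hard votes of its own sub-models are tallied: the
#' location is included iff positive votes exceed half the sub-model count
#' (strict majority; the odd sub-model count makes ties impossible). An
#' empty set falls back to the location with the highest positive-vote
#' fraction, ties to the lowest location code.
#'
#' @param votes 0/1 matrix, proteins x sub-models, in the fixed
#'   (location, model index) column order of [predictLayer1()].
#' @param specs the `specs` data.frame of [predictLayer1()] output (or a
#'   [Layer1Ensemble-class]).
#' @return a [LocPredictions-class].
#' @export
predictVote <- function(votes, specs) {
  if (is(specs, "Layer1Ensemble")) specs <- specs@specs
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  stopifnot(ncol(votes) == nrow(specs))
  locs <- subcellLocations()
  frac <- matrix(0, nrow(votes), 6L,
                 dimnames = list(rownames(votes), locs))
  for (l in locs) {
    cols <- which(specs$location == l)
    if (!length(cols)) next
    m <- length(cols)
    if (m %% 2L == 0L) stop("even sub-model count (", m, ") for ", l)
    frac[, l] <- rowSums(votes[, cols, drop = FALSE]) / m
  }
  sets <- lapply(seq_len(nrow(frac)), function(i) {
    s <- locs[frac[i, ] > 0.5]
    if (!length(s)) s <- locs[which.max(frac[i, ])]
    s
  })
  ids <- if (is.null(rownames(votes))) paste0("query_", seq_len(nrow(votes)))
  else rownames(votes)
  new("LocPredictions", ids = ids, sets = sets, scores = frac,
      combiner = "vote")
}

#' Combine the two second-layer predictors
#'
#' Operational rendering of the recommendation to use the network for
#' singleplex proteins and voting for multiplex proteins: since a query's
#' plexity is unknown a priori, the network's own set size is the proxy —
#' when the network predicts exactly one location its set is used,
#' otherwise the vote set is used.
#'
#' @param gann a [LocPredictions-class] from [predictGANN()].
#' @param vote a [LocPredictions-class] from [predictVote()].
#' @return a combined [LocPredictions-class] (scores from the source used
#'   per protein are averaged for reporting).
#' @export
combinePredictions <- function(gann, vote) {
  stopifnot(identical(gann@ids, vote@ids))
  sets <- lapply(seq_along(gann@ids), function(i)
    if (length(gann@sets[[i]]) == 1L) gann@sets[[i]] else vote@sets[[i]])
  new("LocPredictions", ids = gann@ids, sets = sets,
      scores = (gann@scores + vote@scores) / 2, combiner = "default")
}
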