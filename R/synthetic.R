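.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Six compartment-specific residue-usage profiles: a shared background with
# five signature residues per compartment boosted by `strength`.
.locationProfiles <- function(strength = 3) {
  ab <- aminoAcidAlphabet()
  signature <- list(
    CELL_MEMBRANE = c("F", "I", "L", "V", "W"),   # hydrophobic / TM-like
    CYTOPLASM     = c("A", "E", "K", "Q", "S"),
    ER_GOLGI      = c("C", "G", "N", "T", "Y"),
    MITOCHONDRION = c("L", "R", "S", "A", "M"),   # basic/amphipathic bias
    NUCLEUS       = c("K", "R", "P", "E", "D"),   # charged, NLS-like
    EXTRACELLULAR = c("C", "G", "P", "S", "T")
  )
  profs <- lapply(signature, function(sig) {
    p <- stats::setNames(rep(1, 20L), ab)
    p[sig] <- strength
    p / sum(p)
  })
  do.call(rbind, profs)
}

#' Generator configuration for synthetic proteomes
#'
#' Defaults emulate the statistical structure of the curated human training
#' data the predictor assumes: sequences of at least 80 residues,
#' compartment prevalences proportional to the curated per-location counts
#' (1453, 1542, 562, 462, 2064, 795), a multiplex fraction of 0.15
#' (training-like; the independent-test condition is 0.44), and synthetic
#' GO terms correlated with the compartment (three informative terms per
#' compartment firing with probability `goSignalStrength`, plus noise terms
#' firing at `goNoiseRate`).
#'
#' @param nProteins number of proteins.
#' @param lengthRange integer range of sequence lengths (default 80-600).
#' @param multiplexFraction probability a protein gets two compartments.
#' @param prevalence per-compartment sampling weights.
#' @param profileStrength boost of a compartment's signature residues.
#' @param concentration Dirichlet concentration of per-protein composition
#'   around its compartment profile (higher = less noisy).
#' @param nGoTerms total number of GO terms (18 informative + noise).
#' @param goSignalStrength probability an informative term fires given the
#'   compartment.
#' @param goNoiseRate firing probability of every term as noise.
#' @param seed RNG seed.
#' @return named list.
#' @export
generatorConfig <- function(nProteins = 600L, lengthRange = c(80L, 600L),
                            multiplexFraction = 0.15,
                            prevalence = c(1453, 1542, 562, 462, 2064, 795),
                            profileStrength = 3, concentration = 40,
                            nGoTerms = 40L, goSignalStrength = 0.9,
                            goNoiseRate = 0.05, seed = 1L) {
  stopifnot(multiplexFraction >= 0, multiplexFraction <= 1,
            length(prevalence) == 6L, all(prevalence > 0),
            lengthRange[1] >= 1L, lengthRange[2] >= lengthRange[1])
  list(nProteins = as.integer(nProteins),
       lengthRange = as.integer(lengthRange),
       multiplexFraction = multiplexFraction,
       prevalence = prevalence / sum(prevalence),
       profileStrength = profileStrength, concentration = concentration,
       nGoTerms = as.integer(nGoTerms),
       goSignalStrength = goSignalStrength, goNoiseRate = goNoiseRate,
       seed = as.integer(seed))
}

#' Generate a labeled synthetic proteome
#'
#' Each protein draws a location set (one compartment with probability
#' `1 - multiplexFraction`, else two distinct compartments, by prevalence),
#' a residue composition from a Dirichlet centered on the mixture of its
#' compartments' profiles, and i.i.d. residues of a length uniform in
#' `lengthRange`; informative GO terms of its compartments fire with
#' probability `goSignalStrength` and every term fires as noise at
#' `goNoiseRate`. Deterministic given the seed.
#'
#' @param config a [generatorConfig()] list.
#' @return list with `proteins` (a [ProteinSet-class]) and `truth`
#'   (bookkeeping: location sets, composition profiles used, planted GO
#'   terms, the informative-term map, and the config).
#' @export
simulateProteome <- function(config = generatorConfig()) {
  set.seed(config$seed)
  n <- config$nProteins
  locs <- subcellLocations()
  profs <- .locationProfiles(config$profileStrength)
  ab <- aminoAcidAlphabet()
  goIds <- sprintf("GO:%07d", seq_len(config$nGoTerms))
  informative <- stats::setNames(
    lapply(seq_len(6L), function(k) goIds[(3L * (k - 1L) + 1L):(3L * k)]),
    locs)
  ids <- sprintf("syn%04d", seq_len(n))
  seqs <- character(n)
  sets <- vector("list", n)
  goTerms <- vector("list", n)
  usedProfiles <- matrix(0, n, 20L, dimnames = list(ids, ab))
  for (i in seq_len(n)) {
    k <- if (stats::runif(1) < config$multiplexFraction) 2L else 1L
    ls <- sample(locs, k, prob = config$prevalence)
    ls <- locs[sort(match(ls, locs))]   # canonical compartment-code order
    sets[[i]] <- ls
    mix <- colMeans(profs[ls, , drop = FALSE])
    comp <- .rdirichlet(config$concentration * mix)
    usedProfiles[i, ] <- comp
    len <- sample(seq.int(config$lengthRange[1], config$lengthRange[2]), 1L)
    seqs[i] <- paste(sample(ab, len, replace = TRUE, prob = comp),
                     collapse = "")
    fire <- stats::runif(config$nGoTerms) < config$goNoiseRate
    for (l in ls)
      fire[match(informative[[l]], goIds)] <-
        fire[match(informative[[l]], goIds)] |
        (stats::runif(3L) < config$goSignalStrength)
    goTerms[[i]] <- goIds[fire]
  }
  proteins <- ProteinSet(stats::setNames(seqs, ids), locations = sets,
                         goTerms = goTerms)
  list(proteins = proteins,
       truth = list(locationSets = stats::setNames(sets, ids),
                    profiles = usedProfiles,
                    goPlanted = stats::setNames(goTerms, ids),
                    informativeTerms = informative,
                    config = config))
}

# Kyte-Doolittle hydropathy, for linking simulated burial to hydrophobicity
.kdHydropathy <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
    H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
    P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
    W = -0.9, Y = -1.3)
}

# Tien et al. theoretical maximum ASA per residue (square Angstrom)
.maxASA <- function() {
  c(A = 129, C = 167, D = 193, E = 223, F = 240, G = 104,
    H = 224, I = 197, K = 236, L = 201, M = 224, N = 195,
    P = 159, Q = 225, R = 274, S = 155, T = 172, V = 174,
    W = 285, Y = 263)
}

#' Simulate per-residue surface-accessibility profiles
#'
#' Relative surface accessibility is drawn per residue from a Beta
#' distribution whose mean decreases with Kyte-Doolittle hydropathy
#' (hydrophobic residues tend to be buried); absolute accessibility is RSA
#' times the residue's theoretical maximum; the exposure class is `E` iff
#' RSA >= 0.25.
#'
#' @param x a [ProteinSet-class].
#' @param seed RNG seed.
#' @param betaConcentration Beta concentration (higher = tighter around the
#'   hydropathy-linked mean).
#' @return named list of per-protein data frames with columns
#'   `residue_index`, `aa`, `class`, `RSA`, `ASA`.
#' @export
simulateSAProfiles <- function(x, seed = 1L, betaConcentration = 10) {
  set.seed(seed)
  kd <- .kdHydropathy()
  mx <- .maxASA()
  seqs <- as.character(proteinSequences(x))
  out <- lapply(seqs, function(sq) {
    aa <- strsplit(sq, "")[[1]]
    mu <- 0.5 - 0.08 * kd[aa]              # in about [0.14, 0.86]
    mu <- pmin(pmax(mu, 0.05), 0.95)
    rsa <- stats::rbeta(length(aa), mu * betaConcentration,
                        (1 - mu) * betaConcentration)
    data.frame(residue_index = seq_along(aa), aa = aa,
               class = ifelse(rsa >= 0.25, "E", "B"),
               RSA = rsa, ASA = rsa * mx[aa],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  stats::setNames(out, names(x))
}

#' Separable first-layer output fixture
#'
#' Builds a synthetic matrix shaped like first-layer decision values: each
#' compartment's sub-model columns are shifted by `+mu` for member proteins
#' and `-mu` for non-members, plus Gaussian noise — a controlled test bed
#' for the second-layer combiners.
#'
#' @param n number of proteins (>= 50).
#' @param seed RNG seed.
#' @param mu class shift.
#' @param noise Gaussian noise sd.
#' @param mPerLocation per-compartment sub-model counts (default sums to
#'   32).
#' @param multiplexFraction probability of a second compartment.
#' @return list with `decision` (n x sum(m)), `vote` (0/1), `Y` (logical
#'   n x 6), `specs` (column order data.frame), `truth` (location sets).
#' @export
separableLayer1Fixture <- function(n = 300L, seed = 1L, mu = 2, noise = 0.5,
                                   mPerLocation = c(5L, 5L, 5L, 5L, 7L, 5L),
                                   multiplexFraction = 0.15) {
  stopifnot(n >= 50L)
  set.seed(seed)
  locs <- subcellLocations()
  ids <- sprintf("fix%04d", seq_len(n))
  Y <- matrix(FALSE, n, 6L, dimnames = list(ids, locs))
  for (i in seq_len(n)) {
    k <- if (stats::runif(1) < multiplexFraction) 2L else 1L
    Y[i, sample(6L, k)] <- TRUE
  }
  total <- sum(mPerLocation)
  dec <- matrix(stats::rnorm(n * total, 0, noise), n, total)
  specs <- data.frame(
    location = rep(locs, mPerLocation),
    model_index = unlist(lapply(mPerLocation, seq_len)))
  for (l in seq_len(6L)) {
    cols <- which(specs$location == locs[l])
    dec[, cols] <- dec[, cols] + ifelse(Y[, l], mu, -mu)
  }
  rownames(dec) <- ids
  colnames(dec) <- paste0(specs$location, "_", specs$model_index)
  list(decision = dec, vote = (dec > 0) * 1L, Y = Y, specs = specs,
       truth = stats::setNames(
         lapply(seq_len(n), function(i) locs[Y[i, ]]), ids))
}
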