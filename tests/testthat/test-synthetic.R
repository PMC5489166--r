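test_that("generator defaults match the study conditions", {
  cfg <- generatorConfig()
  expect_identical(cfg$nProteins, 600L)
  expect_identical(cfg$lengthRange, c(80L, 600L))
  expect_equal(cfg$multiplexFraction, 0.15)
  expect_equal(cfg$prevalence,
               c(1453, 1542, 562, 462, 2064, 795) / 6878, tolerance = 1e-12)
  expect_error(generatorConfig(multiplexFraction = 1.5))
})

test_that("simulated proteome honors lengths, labels and reproducibility", {
  cfg <- generatorConfig(nProteins = 120L, seed = 91)
  sim <- simulateProteome(cfg)
  ps <- sim$proteins
  expect_length(ps, 120L)
  w <- Biostrings::width(proteinSequences(ps))
  expect_true(all(w >= 80L & w <= 600L))
  sets <- locationSets(ps)
  expect_true(all(lengths(sets) %in% 1:2))
  expect_identical(sim$truth$locationSets, sets)
  # realized multiplex fraction near the nominal 15%
  expect_lt(abs(mean(lengths(sets) == 2L) - 0.15), 0.08)
  again <- simulateProteome(cfg)
  expect_identical(as.character(proteinSequences(again$proteins)),
                   as.character(proteinSequences(ps)))
  expect_identical(goAnnotations(again$proteins), goAnnotations(ps))
  other <- simulateProteome(generatorConfig(nProteins = 120L, seed = 92))
  expect_false(identical(as.character(proteinSequences(other$proteins)),
                         as.character(proteinSequences(ps))))
})

test_that("compartment prevalence follows the configured weights", {
  sim <- simulateProteome(generatorConfig(nProteins = 1500L, seed = 97))
  Y <- locationMatrix(sim$proteins)
  got <- colSums(Y) / sum(colSums(Y))
  want <- generatorConfig()$prevalence
  expect_lt(max(abs(got - want)), 0.05)
  # NUCLEUS is the most prevalent compartment by design
  expect_identical(names(which.max(colSums(Y))), "NUCLEUS")
})

test_that("signature residues are enriched in their compartment's sequences", {
  sim <- simulateProteome(generatorConfig(nProteins = 300L,
                                          profileStrength = 6, seed = 101))
  ps <- sim$proteins
  Y <- locationMatrix(ps)
  aac <- t(vapply(as.character(proteinSequences(ps)), aacOracle,
                  numeric(20)))
  # NUCLEUS signature includes K and R; membrane signature includes I and L
  nuc <- Y[, "NUCLEUS"] & rowSums(Y) == 1L
  mem <- Y[, "CELL_MEMBRANE"] & rowSums(Y) == 1L
  expect_gt(mean(aac[nuc, "K"]), mean(aac[mem, "K"]))
  expect_gt(mean(aac[mem, "I"]), mean(aac[nuc, "I"]))
})

test_that("planted GO terms are informative for their compartment", {
  sim <- simulateProteome(generatorConfig(nProteins = 400L, seed = 103))
  ps <- sim$proteins
  Y <- locationMatrix(ps)
  info <- sim$truth$informativeTerms
  go <- goAnnotations(ps)
  for (l in c("NUCLEUS", "CYTOPLASM")) {
    tm <- info[[l]][1]
    fires <- vapply(go, function(tt) tm %in% tt, logical(1))
    expect_gt(mean(fires[Y[, l]]), 0.7)
    expect_lt(mean(fires[!Y[, l]]), 0.25)
  }
})

test_that("simulated SA profiles are one-row-per-residue with coherent columns", {
  sim <- simulateProteome(generatorConfig(nProteins = 8L,
                                          lengthRange = c(80L, 120L),
                                          seed = 107))
  profs <- simulateSAProfiles(sim$proteins, seed = 5)
  w <- Biostrings::width(proteinSequences(sim$proteins))
  for (i in seq_along(profs)) {
    p <- profs[[i]]
    expect_identical(nrow(p), w[i])
    expect_true(all(p$RSA >= 0 & p$RSA <= 1))
    expect_identical(p$class, ifelse(p$RSA >= 0.25, "E", "B"))
    expect_equal(p$ASA, p$RSA * ProtSubLoc:::.maxASA()[p$aa],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # hydrophobic residues are buried more often on average
  all <- do.call(rbind, profs)
  expect_gt(mean(all$RSA[all$aa == "K"]), mean(all$RSA[all$aa == "I"]))
})

test_that("separable fixture has the advertised shift structure", {
  fix <- separableLayer1Fixture(n = 100, seed = 7, mu = 2, noise = 0.5)
  expect_identical(dim(fix$decision), c(100L, 32L))
  expect_identical(fix$vote, (fix$decision > 0) * 1L)
  for (l in subcellLocations()) {
    cols <- fix$specs$location == l
    inM <- mean(fix$decision[fix$Y[, l], cols])
    outM <- mean(fix$decision[!fix$Y[, l], cols])
    expect_gt(inM, 1)
    expect_lt(outM, -1)
  }
  expect_identical(fix$truth,
                   setNames(lapply(seq_len(100), function(i)
                     subcellLocations()[fix$Y[i, ]]), rownames(fix$Y)))
})
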