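test_that("exact-set accuracy matches hand-counted examples", {
  truth <- list(a = "NUCLEUS", b = c("NUCLEUS", "CYTOPLASM"),
                c = "EXTRACELLULAR")
  pred <- list(a = "NUCLEUS",
               b = c("CYTOPLASM", "NUCLEUS"),  # order must not matter
               c = c("EXTRACELLULAR", "NUCLEUS"))  # superset is a failure
  a <- atsr(pred, truth)
  expect_equal(as.numeric(a), 2 / 3, tolerance = 1e-12)
  expect_identical(attr(a, "correct"), 2L)
  expect_identical(attr(a, "total"), 3L)
  # under-prediction of a multiplex set also fails
  expect_equal(as.numeric(atsr(list(b = "NUCLEUS"), truth)), 0)
  expect_error(atsr(list(zz = "NUCLEUS"), truth), "no truth")
})

test_that("exact-set accuracy matches a counting oracle on random pairs", {
  rp <- randomTruthAndPred(400, seed = 71)
  a <- atsr(rp$pred, rp$truth)
  want <- mean(mapply(function(p, t)
    length(union(p, t)) == length(intersect(p, t)), rp$pred, rp$truth))
  expect_equal(as.numeric(a), want, tolerance = 1e-12)
  expect_identical(attr(a, "total"), 400L)
})

test_that("per-location rates restrict to true members", {
  truth <- list(a = "NUCLEUS", b = c("NUCLEUS", "CYTOPLASM"), c = "NUCLEUS")
  pred <- list(a = "NUCLEUS", b = "NUCLEUS", c = "CYTOPLASM")
  pl <- perLocationATSR(pred, truth)
  nuc <- pl[pl$location == "NUCLEUS", ]
  expect_identical(nuc$total, 3L)
  expect_identical(nuc$correct, 1L)
  cyt <- pl[pl$location == "CYTOPLASM", ]
  expect_identical(cyt$total, 1L)   # only b truly has CYTOPLASM
  expect_identical(cyt$correct, 0L)
  expect_false("ER_GOLGI" %in% pl$location)
})

test_that("plexity breakdown partitions the correct count", {
  rp <- randomTruthAndPred(300, seed = 73)
  pb <- plexBreakdown(rp$pred, rp$truth)
  expect_identical(pb$group, c("singleplex", "multiplex", "overall"))
  expect_identical(sum(pb$correct[1:2]), pb$correct[3])
  expect_identical(sum(pb$total[1:2]), pb$total[3])
  expect_identical(pb$total[1], sum(lengths(rp$truth) == 1L))
  allSingle <- plexBreakdown(list(a = "NUCLEUS"), list(a = "NUCLEUS"))
  expect_true(is.na(allSingle$rate[2]))
})

test_that("evaluation accepts prediction objects and membership matrices", {
  rp <- randomTruthAndPred(50, seed = 79)
  Y <- ProtSubLoc:::.locationMatrixFromSets(rp$truth, names(rp$truth))
  pred <- new("LocPredictions", ids = names(rp$pred),
              sets = unname(rp$pred),
              scores = matrix(0, 50, 6,
                              dimnames = list(names(rp$pred),
                                              subcellLocations())),
              combiner = "vote")
  expect_equal(as.numeric(atsr(pred, Y)),
               as.numeric(atsr(rp$pred, rp$truth)), tolerance = 1e-12)
  rep <- evalReport(pred, rp$truth)
  expect_equal(rep$overall$rate, as.numeric(atsr(rp$pred, rp$truth)))
  expect_s3_class(rep$perLocation, "data.frame")
})

test_that("stratified folds balance compartment membership", {
  set.seed(83)
  n <- 240
  Y <- matrix(FALSE, n, 6, dimnames = list(sprintf("s%03d", 1:n),
                                           subcellLocations()))
  Y[cbind(1:n, sample(6, n, TRUE, prob = c(5, 5, 1, 1, 6, 2)))] <- TRUE
  Y[sample(n, 30), sample(6, 1)] <- TRUE
  fold <- ProtSubLoc:::.stratifiedFolds(Y, 5L, seed = 3)
  expect_identical(sort(unique(fold)), 1:5)
  expect_lte(diff(range(table(fold))), 6)
  for (l in 1:6) {
    per <- vapply(1:5, function(f) sum(Y[fold == f, l]), integer(1))
    expect_lte(diff(range(per)), max(3L, ceiling(0.35 * mean(per))))
  }
  expect_identical(ProtSubLoc:::.stratifiedFolds(Y, 5L, seed = 3), fold)
})

test_that("nested cross-validation on a small proteome reports coherently and audits leakage", {
  sim <- simulateProteome(generatorConfig(nProteins = 90L,
                                          profileStrength = 6,
                                          concentration = 100,
                                          lengthRange = c(80L, 160L),
                                          seed = 17))
  res <- nestedCV(sim$proteins,
                  featureConfig(useSA = FALSE, useGO = TRUE, useSSP = FALSE),
                  folds = 3L, seed = 5,
                  mPerLocation = rep(3L, 6),
                  gann = gannConfig(population = 60L, maxGen = 15L,
                                    hiddenSize = 6L, seed = 2))
  expect_true(res$leakageAudit)
  expect_identical(res$vote$overall$total, 90L)
  expect_identical(nrow(res$foldRates), 3L)
  # pooled predictions cover every protein exactly once
  expect_setequal(res$predictions$vote@ids, names(sim$proteins))
  # pooled rate equals the weighted mean of fold rates
  sizes <- table(ProtSubLoc:::.stratifiedFolds(
    locationMatrix(sim$proteins), 3L, 5))
  expect_equal(res$vote$overall$rate,
               sum(res$foldRates$vote * as.integer(sizes)) / 90,
               tolerance = 1e-12)
  expect_gt(res$vote$overall$rate, 0.4)
})
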