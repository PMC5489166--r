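test_that("network forward pass is a bounded sigmoid map", {
  set.seed(61)
  fix <- separableLayer1Fixture(n = 60, seed = 3)
  cfg <- gannConfig(population = 20L, maxGen = 3L, hiddenSize = 4L, seed = 2)
  m <- trainGANN(fix$decision, fix$Y, cfg)
  act <- predictGANN(m, fix$decision)@scores
  expect_true(all(act > 0 & act < 1))
  expect_identical(colnames(act), subcellLocations())
  # hand-computed forward pass for one row
  x <- fix$decision[1, ]
  h <- plogis(c(1, x) %*% m@W1)
  want <- plogis(c(1, h) %*% m@W2)
  expect_equal(unname(act[1, ]), as.numeric(want), tolerance = 1e-12)
})

test_that("GA keeps weights in bounds and best error non-increasing", {
  fix <- separableLayer1Fixture(n = 80, seed = 5)
  cfg <- gannConfig(population = 30L, maxGen = 15L, hiddenSize = 4L,
                    seed = 7, errorTarget = 0)
  m <- trainGANN(fix$decision, fix$Y, cfg)
  expect_true(all(m@W1 >= -25 & m@W1 <= 25))
  expect_true(all(m@W2 >= -25 & m@W2 <= 25))
  expect_true(all(diff(m@history) <= 1e-12))
  expect_length(m@history, 16L)  # generation 0 plus 15 generations
})

test_that("GA training is seed-reproducible and seed-sensitive", {
  fix <- separableLayer1Fixture(n = 60, seed = 9)
  cfg <- gannConfig(population = 20L, maxGen = 5L, hiddenSize = 4L, seed = 4)
  a <- trainGANN(fix$decision, fix$Y, cfg)
  b <- trainGANN(fix$decision, fix$Y, cfg)
  expect_identical(a@W1, b@W1)
  expect_identical(a@history, b@history)
  cfg$seed <- 5L
  expect_false(identical(trainGANN(fix$decision, fix$Y, cfg)@W1, a@W1))
})

test_that("maxGen 0 returns the best of the initial population and degenerate labels warn", {
  fix <- separableLayer1Fixture(n = 50, seed = 2)
  cfg <- gannConfig(population = 15L, maxGen = 0L, hiddenSize = 3L, seed = 1)
  m <- trainGANN(fix$decision, fix$Y, cfg)
  expect_length(m@history, 1L)
  Yflat <- matrix(1, 50, 6)
  expect_warning(trainGANN(fix$decision, Yflat,
                           gannConfig(population = 10L, maxGen = 0L,
                                      hiddenSize = 2L)), "degenerate")
})

test_that("network thresholding never yields an empty set and falls back to the top activation", {
  act <- rbind(c(.9, .6, .1, .1, .1, .1),
               c(.2, .3, .1, .4, .2, .1),
               c(.3, .3, .3, .3, .3, .3))
  colnames(act) <- subcellLocations()
  sets <- ProtSubLoc:::.threshToSets(act)
  expect_setequal(sets[[1]], subcellLocations()[1:2])
  expect_identical(sets[[2]], "MITOCHONDRION")
  expect_identical(sets[[3]], "CELL_MEMBRANE")  # tie -> lowest code
})

test_that("strict-majority voting matches a per-location counting oracle", {
  set.seed(67)
  fix <- separableLayer1Fixture(n = 200, seed = 13, mu = 0.4, noise = 1)
  pred <- predictVote(fix$vote, fix$specs)
  sets <- predictedSets(pred)
  locs <- subcellLocations()
  for (i in sample(200, 40)) {
    want <- locs[vapply(locs, function(l) {
      cols <- fix$specs$location == l
      sum(fix$vote[i, cols]) > sum(cols) / 2
    }, logical(1))]
    if (!length(want)) {
      fr <- vapply(locs, function(l)
        mean(fix$vote[i, fix$specs$location == l]), numeric(1))
      want <- locs[which.max(fr)]
    }
    expect_setequal(sets[[i]], want)
  }
  expect_true(all(lengths(sets) >= 1L))
  badSpecs <- data.frame(location = rep(locs, c(4, 6, 6, 6, 6, 4)),
                         model_index = 1)
  expect_error(predictVote(fix$vote, badSpecs), "even")
})

test_that("combined rule trusts the network only on singleton sets", {
  ids <- c("a", "b")
  sc <- matrix(0.5, 2, 6, dimnames = list(ids, subcellLocations()))
  g <- new("LocPredictions", ids = ids,
           sets = list("NUCLEUS", c("NUCLEUS", "CYTOPLASM")),
           scores = sc, combiner = "gann")
  v <- new("LocPredictions", ids = ids,
           sets = list(c("ER_GOLGI", "EXTRACELLULAR"), "MITOCHONDRION"),
           scores = sc, combiner = "vote")
  comb <- combinePredictions(g, v)
  expect_identical(predictedSets(comb)[["a"]], "NUCLEUS")
  expect_identical(predictedSets(comb)[["b"]], "MITOCHONDRION")
  expect_identical(comb@combiner, "default")
})

test_that("both combiners recover labels on a cleanly separable fixture", {
  fix <- separableLayer1Fixture(n = 150, seed = 21, mu = 3, noise = 0.3)
  vote <- predictVote(fix$vote, fix$specs)
  expect_gt(as.numeric(atsr(predictedSets(vote), fix$truth)), 0.95)
  cfg <- gannConfig(population = 250L, maxGen = 150L, hiddenSize = 8L,
                    seed = 3)
  g <- trainGANN(fix$decision, fix$Y, cfg)
  ga <- predictGANN(g, fix$decision)
  expect_gt(as.numeric(atsr(predictedSets(ga), fix$truth)), 0.6)
})
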