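# small labeled feature set with a linear-ish membership signal
.layer1Toy <- function(n = 90, p = 8, seed = 11) {
  set.seed(seed)
  ids <- sprintf("p%03d", seq_len(n))
  Y <- matrix(FALSE, n, 6, dimnames = list(ids, subcellLocations()))
  Y[cbind(seq_len(n), sample(6, n, TRUE))] <- TRUE
  Y[sample(n, round(0.15 * n)), sample(6, 1)] <- TRUE
  X <- matrix(rnorm(n * p), n, p, dimnames = list(ids, paste0("f", 1:p)))
  for (l in 1:6) X[Y[, l], min(l, p)] <- X[Y[, l], min(l, p)] + 3
  list(X = X, Y = Y)
}

test_that("negative partitions are disjoint, exhaustive and near-equal", {
  toy <- .layer1Toy()
  for (loc in subcellLocations()) {
    plan <- planPartitions(toy$Y, loc, m = 5, seed = 3)
    expect_length(plan, 5L)
    negAll <- unlist(lapply(plan, `[[`, "neg_ids"))
    expect_false(anyDuplicated(negAll) > 0)
    expect_setequal(negAll, rownames(toy$Y)[!toy$Y[, loc]])
    sizes <- lengths(lapply(plan, `[[`, "neg_ids"))
    expect_lte(max(sizes) - min(sizes), 1L)
    # all sub-models share the full positive set
    for (sp in plan)
      expect_setequal(sp$pos_ids, rownames(toy$Y)[toy$Y[, loc]])
    expect_equal(plan[[1]]$ratio,
                 length(plan[[1]]$neg_ids) / length(plan[[1]]$pos_ids))
  }
  expect_error(planPartitions(toy$Y, "NUCLEUS", 4), "odd")
  expect_error(planPartitions(toy$Y, "NUCLEUS", 11), "3..9")
  empty <- toy$Y; empty[, "ER_GOLGI"] <- FALSE
  expect_error(planPartitions(empty, "ER_GOLGI", 3), "no positives")
})

test_that("partition shuffling is seed-reproducible and seed-sensitive", {
  toy <- .layer1Toy()
  a <- planPartitions(toy$Y, "NUCLEUS", 5, seed = 7)
  b <- planPartitions(toy$Y, "NUCLEUS", 5, seed = 7)
  c <- planPartitions(toy$Y, "NUCLEUS", 5, seed = 8)
  expect_identical(a, b)
  expect_false(identical(lapply(a, `[[`, "neg_ids"),
                         lapply(c, `[[`, "neg_ids")))
})

test_that("default plan yields 32 sub-models covering every negative", {
  toy <- .layer1Toy()
  plan <- defaultPartitionPlan(toy$Y, seed = 5)
  expect_length(plan, 32L)
  counts <- table(vapply(plan, `[[`, "", "location"))
  expect_identical(as.integer(counts[subcellLocations()]),
                   c(5L, 5L, 5L, 5L, 7L, 5L))
  for (loc in subcellLocations()) {
    negAll <- unlist(lapply(Filter(function(s) s$location == loc, plan),
                            `[[`, "neg_ids"))
    expect_setequal(negAll, rownames(toy$Y)[!toy$Y[, loc]])
  }
})

test_that("trained ensemble recovers a separable membership signal", {
  toy <- .layer1Toy(n = 120, seed = 13)
  std <- ProtSubLoc:::.standardize(toy$X)
  plan <- defaultPartitionPlan(toy$Y, seed = 2)
  ens <- trainLayer1(std$X, plan)
  expect_s4_class(ens, "Layer1Ensemble")
  expect_length(ens@models, 32L)
  out <- predictLayer1(ens, std$X)
  expect_identical(dim(out$decision), c(120L, 32L))
  expect_identical(out$vote, (out$decision > 0) * 1L)
  # resubstitution majority votes should track true membership closely
  acc <- vapply(subcellLocations(), function(l) {
    cols <- which(out$specs$location == l)
    maj <- rowSums(out$vote[, cols, drop = FALSE]) > length(cols) / 2
    mean(maj == toy$Y[, l])
  }, numeric(1))
  expect_gt(mean(acc), 0.9)
})

test_that("training and prediction guard against malformed input", {
  toy <- .layer1Toy(n = 60)
  plan <- planPartitions(toy$Y, "NUCLEUS", 3, seed = 1)
  bad <- plan; bad[[1]]$neg_ids <- character(0)
  expect_error(trainLayer1(toy$X, bad), "single-class")
  bad <- plan; bad[[2]]$pos_ids <- character(0)
  expect_error(trainLayer1(toy$X, bad), "empty positive")
  bad <- plan; bad[[1]]$neg_ids[1] <- "ghost"
  expect_error(trainLayer1(toy$X, bad), "missing from feature matrix")
  ens <- trainLayer1(toy$X, plan)
  wrong <- toy$X[, 1:5]
  expect_error(predictLayer1(ens, wrong), "column")
  one <- predictLayer1(ens, toy$X[1, , drop = FALSE])
  expect_identical(dim(one$decision), c(1L, 3L))
})

test_that("decision-value orientation is positive on the membership side", {
  toy <- .layer1Toy(n = 80, seed = 17)
  std <- ProtSubLoc:::.standardize(toy$X)
  # order the training rows negatives-first to provoke label-order flips
  plan <- planPartitions(toy$Y, "CYTOPLASM", 3, seed = 9)
  ens <- trainLayer1(std$X[rev(rownames(std$X)), ], plan)
  dec <- predictLayer1(ens, std$X)$decision
  pos <- toy$Y[, "CYTOPLASM"]
  expect_gt(mean(rowMeans(dec[pos, , drop = FALSE])),
            mean(rowMeans(dec[!pos, , drop = FALSE])))
})

test_that("ratio/m sweep returns grid members and breaks ties downward", {
  toy <- .layer1Toy(n = 70, p = 4, seed = 19)
  got <- chooseRatioAndM(toy$X, toy$Y, "NUCLEUS", ratioGrid = c(1, 3),
                         mGrid = c(3L, 5L), folds = 2L, seed = 3)
  expect_true(got$m %in% c(3L, 5L))
  expect_true(got$ratio %in% c(1, 3))
  expect_identical(dim(got$score), c(2L, 2L))
  expect_equal(got$score[as.character(got$m), as.character(got$ratio)],
               max(got$score, na.rm = TRUE))
  expect_error(chooseRatioAndM(toy$X, toy$Y, "NUCLEUS", 1, mGrid = 4L),
               "odd")
})

test_that("standardization round-trips and leaves constants finite", {
  X <- cbind(a = rnorm(30, 5, 2), b = rep(3, 30), c = runif(30))
  std <- ProtSubLoc:::.standardize(X)
  expect_equal(colMeans(std$X), c(a = 0, b = 0, c = 0), tolerance = 1e-12)
  expect_equal(sd(std$X[, "a"]), 1, tolerance = 1e-12)
  expect_true(all(is.finite(std$X)))
  again <- ProtSubLoc:::.applyStandardize(X, std$center, std$scale)
  expect_equal(again, std$X, tolerance = 1e-12)
})
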