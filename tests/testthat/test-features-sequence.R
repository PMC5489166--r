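test_that("region extraction matches documented index arithmetic", {
  r <- extractRegions(randomSequence(90, seed = 1))
  expect_identical(nchar(r$full), 90L)
  expect_identical(nchar(r$n30), 30L)
  expect_identical(nchar(r$mid3), 30L)
  expect_identical(nchar(r$c50), 50L)
  expect_identical(regionIndices(90)$mid3, 31:60)
  # short sequences clamp; regions may overlap
  r <- regionIndices(40)
  expect_identical(r$n30, 1:30)
  expect_identical(r$c50, 1:40)
  expect_identical(r$mid3, 14:26)
  # mid3 length and centering hold across lengths
  for (len in c(80L, 81L, 89L, 91L, 100L, 601L)) {
    m <- len %/% 3L
    idx <- regionIndices(len)$mid3
    expect_length(idx, m)
    expect_identical(idx[1], (len - m) %/% 2L + 1L)
  }
})

test_that("amino acid composition matches a letter-count oracle", {
  expect_equal(unname(computeAAC("ACDEFGHIKLMNPQRSTVWY")), rep(0.05, 20))
  set.seed(3)
  for (i in 1:20) {
    s <- randomSequence(sample(5:200, 1))
    expect_equal(computeAAC(s), aacOracle(s), tolerance = 1e-12)
  }
  z <- computeAAC("")
  expect_equal(unname(z), numeric(20), ignore_attr = TRUE)
  expect_true(isTRUE(attr(z, "empty")))
})

test_that("weighted sign aa index follows its defining algebra", {
  tbl <- randomAAIndexTable(5)
  aac <- aacOracle(randomSequence(80, seed = 2))
  ws <- computeWeightedSignAAIndex(aac, tbl)
  # score is the plain inner product per scale
  expect_equal(ws$score, as.numeric(tbl %*% aac), tolerance = 1e-12)
  expect_identical(ws$sign, as.integer(ws$score < 0))
  expect_equal(ws$C, log10(pmax(abs(ws$score), 1e-6)), tolerance = 1e-12)
  # homogeneity: scaling every table entry by c shifts C by log10(c)
  big <- computeWeightedSignAAIndex(aac, tbl * 10)
  expect_equal(big$C, ws$C + 1, tolerance = 1e-9)
  expect_identical(big$sign, ws$sign)
  # zero projection hits the epsilon floor instead of -Inf
  z <- computeWeightedSignAAIndex(numeric(20), tbl)
  expect_true(all(is.finite(z$C)))
  expect_equal(z$C, rep(log10(1e-6), nrow(tbl)))
  bad <- tbl; bad[1, 1] <- NA
  expect_error(computeWeightedSignAAIndex(aac, bad), "non-finite")
})

test_that("PseAAC properties are standardized and theta is a squared metric", {
  p <- pcPseAACProperties()
  expect_identical(dim(p), c(3L, 20L))
  expect_equal(rowMeans(p), c(hydrophobicity = 0, hydrophilicity = 0,
                              sideChainMass = 0), tolerance = 1e-12)
  expect_equal(apply(p, 1, function(v) mean(v^2)), rep(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  Th <- ProtSubLoc:::.pseaacThetaMatrix()
  expect_equal(Th, t(Th))
  expect_true(all(diag(Th) == 0))
  expect_true(all(Th >= 0))
})

test_that("PseAAC reduces to composition at lambda 0 and matches a brute-force oracle", {
  s <- randomSequence(60, seed = 7)
  expect_equal(unname(computePseAAC(s, lambda = 0)),
               unname(computeAAC(s)), tolerance = 1e-12)
  # direct recomputation of the defining formula at lambda = 2
  Th <- ProtSubLoc:::.pseaacThetaMatrix()
  ch <- strsplit(s, "")[[1]]
  th <- vapply(1:2, function(j)
    mean(vapply(seq_len(length(ch) - j), function(i)
      Th[ch[i], ch[i + j]], numeric(1))), numeric(1))
  want <- c(aacOracle(s), 0.05 * th) / (1 + 0.05 * sum(th))
  expect_equal(unname(computePseAAC(s, lambda = 2)), unname(want),
               tolerance = 1e-12)
  v <- computePseAAC(s)
  expect_length(v, 28L)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_true(all(v >= 0))
  expect_error(computePseAAC(randomSequence(8), lambda = 8), "must exceed")
})

test_that("sequence feature block has the documented layout and block map", {
  tbl <- randomAAIndexTable(11)
  s <- randomSequence(120, seed = 5)
  fb <- sequenceFeatureBlock(s, tbl)
  expect_length(fb, 908L)
  bm <- attr(fb, "blockMap")
  expect_identical(bm$block,
                   c(paste0("aac_", c("full", "n30", "mid3", "c50")),
                     paste0("wsaai_", c("full", "n30", "mid3", "c50")),
                     "pseaac"))
  expect_identical(bm$start[1], 1L)
  expect_identical(bm$end[9], 908L)
  expect_true(all(bm$start[-1] == bm$end[-9] + 1L))
  # spot-check content against the scalar encoders
  expect_equal(unname(fb[1:20]), unname(computeAAC(s)), tolerance = 1e-12)
  ws <- computeWeightedSignAAIndex(computeAAC(extractRegions(s)$c50), tbl)
  span <- bm$start[8]:bm$end[8]
  expect_equal(unname(fb[span]), as.numeric(rbind(ws$sign, ws$C)),
               tolerance = 1e-12)
  expect_equal(unname(fb[881:908]), unname(computePseAAC(s)),
               tolerance = 1e-12)
})

test_that("vectorized block matrix agrees with the scalar encoder", {
  tbl <- randomAAIndexTable(13)
  set.seed(21)
  seqs <- setNames(vapply(c(9L, 30L, 80L, 90L, 143L), randomSequence, ""),
                   paste0("v", 1:5))
  M <- ProtSubLoc:::.sequenceBlockMatrix(Biostrings::AAStringSet(seqs), tbl)
  for (i in seq_along(seqs)) {
    lam <- min(8L, nchar(seqs[i]) - 1L)
    if (lam == 8L) {
      expect_equal(unname(M$values[i, ]),
                   unname(sequenceFeatureBlock(seqs[[i]], tbl)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    } else {
      # short sequences: truncated-lag tiers present, trailing tiers zero
      expect_true(all(M$values[i, paste0("pseaac_theta",
                                         seq.int(lam + 1L, 8L))] == 0))
    }
  }
  expect_identical(attr(sequenceFeatureBlock(seqs[[3]], tbl), "blockMap"),
                   M$blockMap)
})
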