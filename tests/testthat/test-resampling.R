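smallConfig <- networkConfig(nLambda = 40L)

test_that("bootstrap replicates are reproducible and percentile CIs behave", {
  spec <- syntheticSpec(n = 120,
                        communitySizes = c(somatic = 4L,
                                           anxiety_depression = 3L),
                        withinDensity = 0.5, bridgeDensity = 0.3,
                        weightRange = c(0.25, 0.4), seed = 15)
  rm <- sampleOrdinal(buildGroundTruth(spec), spec)

  b1 <- bootstrapEdges(rm, smallConfig, B = 5, seed = 9)
  b2 <- bootstrapEdges(rm, smallConfig, B = 5, seed = 9)
  expect_identical(b1@edgeBoot, b2@edgeBoot)
  expect_identical(b1@eiBoot, b2@eiBoot)
  expect_true(all(b1@edges$ciLower <= b1@edges$ciUpper))

  # B = 1: degenerate interval equal to the single replicate
  b3 <- bootstrapEdges(rm, smallConfig, B = 1, seed = 2)
  expect_equal(b3@edges$ciLower, unname(b3@edgeBoot[1, ]))
  expect_equal(b3@edges$ciUpper, unname(b3@edgeBoot[1, ]))
})

test_that("edges absent from every replicate get a [0, 0] interval", {
  spec <- syntheticSpec(n = 250,
                        communitySizes = c(somatic = 2L,
                                           anxiety_depression = 2L),
                        withinDensity = 0, bridgeDensity = 0, seed = 44)
  rm <- sampleOrdinal(buildGroundTruth(spec), spec)
  b <- bootstrapEdges(rm, smallConfig, B = 8, seed = 5)
  allZero <- colSums(b@edgeBoot != 0) == 0
  expect_true(any(allZero))
  expect_true(all(b@edges$ciLower[allZero] == 0 &
                  b@edges$ciUpper[allZero] == 0))
})

test_that("confidence intervals tighten with sample size", {
  spec <- function(n) syntheticSpec(n = n,
      communitySizes = c(somatic = 3L, anxiety_depression = 3L),
      withinDensity = 0.6, bridgeDensity = 0.4,
      weightRange = c(0.25, 0.4), seed = 3)
  gt <- buildGroundTruth(spec(200))
  rmS <- sampleOrdinal(gt, spec(200))
  rmL <- sampleOrdinal(gt, spec(2000))
  bS <- bootstrapEdges(rmS, smallConfig, B = 30, seed = 1)
  bL <- bootstrapEdges(rmL, smallConfig, B = 30, seed = 1)
  expect_lt(mean(bL@edges$ciUpper - bL@edges$ciLower),
            mean(bS@edges$ciUpper - bS@edges$ciLower))
})

test_that("case-dropping stability hits the ceiling on duplicated data", {
  # 16 distinct strongly-patterned rows repeated 40x: any subsample keeps
  # essentially the same correlation structure, so centralities persist
  set.seed(33)
  base <- matrix(sample(0:3, 16 * 6, TRUE), 16, 6)
  base[, 2] <- base[, 1]; base[, 4] <- pmin(base[, 3] + 1L, 3L)
  v <- base[rep(seq_len(16), times = 40), ]
  rm <- rmFromValues(v, c("S1", "S2", "S3", "P1", "P2", "G1"))
  st <- caseDroppingBootstrap(rm, smallConfig, BPerLevel = 25, seed = 8)
  expect_equal(unname(csCoefficient(st)[["EI"]]), 0.75)

  # CS is non-increasing in the correlation threshold
  cs5 <- csCoefficient(st, corThreshold = 0.5)
  cs7 <- csCoefficient(st, corThreshold = 0.7)
  cs9 <- csCoefficient(st, corThreshold = 0.9)
  expect_true(all(cs5 >= cs7 & cs7 >= cs9))
})

test_that("the drop grid is truncated when subsamples get too small", {
  rm <- randomResponses(40, c("S1", "S2", "S3", "P1", "P2"), seed = 2)
  expect_warning(
    st <- caseDroppingBootstrap(rm, smallConfig,
                                dropGrid = c(0.1, 0.5, 0.9),
                                BPerLevel = 3, seed = 1),
    "truncat")
  expect_true(max(st@dropProportions) <= 0.5)
})

test_that("difference tests read paired percentile intervals correctly", {
  x <- c(0.1, 0.2, 0.15, 0.12, 0.18)
  expect_false(pairDifferenceSignificant(x, x))
  expect_true(pairDifferenceSignificant(x, x + 1))
  expect_error(pairDifferenceSignificant(x, x[-1]), "equal length")

  spec <- syntheticSpec(n = 150,
                        communitySizes = c(somatic = 3L,
                                           anxiety_depression = 3L),
                        withinDensity = 0.6, bridgeDensity = 0.4,
                        weightRange = c(0.25, 0.4), seed = 12)
  rm <- sampleOrdinal(buildGroundTruth(spec), spec)
  b <- bootstrapEdges(rm, smallConfig, B = 20, seed = 3)
  for (what in c("edge", "EI", "BEI")) {
    D <- differenceTest(b, what, alpha = 0.05)
    expect_true(isSymmetric(D))
    expect_false(any(diag(D)))
    # agrees with the pairwise primitive
    mat <- switch(what, edge = b@edgeBoot, EI = b@eiBoot, BEI = b@beiBoot)
    i <- 1L; j <- min(3L, ncol(mat))
    expect_identical(D[i, j],
                     pairDifferenceSignificant(mat[, i], mat[, j]))
  }
})
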