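test_that("empty-density spec yields the empty network", {
  spec <- syntheticSpec(withinDensity = 0, bridgeDensity = 0, seed = 3)
  gt <- buildGroundTruth(spec)
  expect_identical(edgeCount(gt), 0L)
  expect_identical(nrow(bridgeEdges(gt)), 0L)
  expect_equal(edgeWeights(gt), edgeWeights(gt) * 0)
})

test_that("ground truth is positive definite with intact support", {
  for (s in 1:10) {
    spec <- syntheticSpec(withinDensity = 0.3, bridgeDensity = 0.2,
                          seed = 500 + s)
    gt <- buildGroundTruth(spec)
    K <- precisionMatrix(gt)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
    W <- edgeWeights(gt)
    expect_true(isSymmetric(W))
    expect_equal(max(abs(diag(W))), 0)
    # bridges positive and correctly labelled
    be <- bridgeEdges(gt)
    comm <- nodeCommunities(gt)
    if (nrow(be)) {
      expect_true(all(W[be] > 0))
      expect_true(all(comm[be[, 1]] != comm[be[, 2]]))
    }
    # every nonzero cross-community entry is listed as a bridge
    ij <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    cross <- comm[ij[, 1]] != comm[ij[, 2]]
    expect_identical(sum(cross), nrow(be))
  }
})

test_that("a single weak edge round-trips exactly through the precision matrix", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  gt <- groundTruthFromWeights(W, c("somatic", "somatic", "anxiety_depression"))
  # min eigenvalue of I - W is 0.7, so no inflation: weight survives exactly
  expect_equal(edgeWeights(gt)[1, 2], 0.3, tolerance = 1e-12)
  expect_identical(nrow(bridgeEdges(gt)), 0L)
  # closed-form 3x3: inverting K and re-deriving the partial correlation
  K <- precisionMatrix(gt)
  Sig <- solve(K)
  P <- -stats::cov2cor(solve(stats::cov2cor(Sig)))
  expect_equal(P[1, 2], 0.3, tolerance = 1e-10)
})

test_that("infeasibly dense heavy structures are rejected", {
  p <- 40
  W <- matrix(0.3, p, p); diag(W) <- 0
  expect_error(groundTruthFromWeights(W, rep(c("somatic", "anxiety_depression"),
                                             each = p / 2)),
               "positive definite")
})

test_that("ordinal sampling is deterministic and honours thresholds", {
  spec <- syntheticSpec(n = 50, seed = 9)
  gt <- buildGroundTruth(spec)
  expect_identical(responseValues(sampleOrdinal(gt, spec)),
                   responseValues(sampleOrdinal(gt, spec)))

  # identity precision + quartile thresholds: ~uniform categories
  th <- matrix(rep(qnorm(c(0.25, 0.5, 0.75)), each = 2), 2, 3)
  spec2 <- syntheticSpec(n = 10000,
                         communitySizes = c(somatic = 1L,
                                            anxiety_depression = 1L),
                         withinDensity = 0, bridgeDensity = 0,
                         thresholds = th, seed = 21)
  gt2 <- buildGroundTruth(spec2)
  rm2 <- sampleOrdinal(gt2, spec2)
  props <- tabulate(responseValues(rm2)[, 1] + 1L, 4L) / 10000
  expect_equal(props, rep(0.25, 4), tolerance = 0.02)

  # all mass below the first cut point: constant-zero column
  th3 <- th; th3[1, ] <- c(8, 9, 10)
  spec3 <- syntheticSpec(n = 200,
                         communitySizes = c(somatic = 1L,
                                            anxiety_depression = 1L),
                         withinDensity = 0, bridgeDensity = 0,
                         thresholds = th3, seed = 5)
  rm3 <- sampleOrdinal(buildGroundTruth(spec3), spec3)
  expect_true(all(responseValues(rm3)[, 1] == 0L))
})

test_that("zero latent correlation gives near-zero sample Spearman", {
  spec <- syntheticSpec(n = 2000,
                        communitySizes = c(somatic = 2L,
                                           anxiety_depression = 2L),
                        withinDensity = 0, bridgeDensity = 0, seed = 31)
  rm <- sampleOrdinal(buildGroundTruth(spec), spec)
  S <- corValues(spearmanMatrix(rm))
  expect_lt(max(abs(S[upper.tri(S)])), 0.06)
})

test_that("threshold calibration hits target ordinal moments", {
  # symmetric target: cuts symmetric about 0
  th <- calibrateThresholds(1.5, 0.9)
  expect_equal(unname(th[1, 1]), unname(-th[1, 3]), tolerance = 1e-3)
  expect_equal(unname(th[1, 2]), 0, tolerance = 1e-3)

  # published fatigue moments reproduce within stated tolerance
  th2 <- calibrateThresholds(1.45, 1.06)
  mom <- impliedOrdinalMoments(th2)
  expect_lt(abs(mom$mean - 1.45), 0.05)
  expect_lt(abs(mom$sd - 1.06), 0.1)

  # every default calibration target is attainable
  ref <- referenceItemMoments()
  thAll <- calibrateThresholds(ref$mean, ref$sd, ref$item_id)
  momAll <- impliedOrdinalMoments(thAll)
  expect_true(all(abs(momAll$mean - ref$mean) <= 0.05))
  expect_true(all(abs(momAll$sd - ref$sd) <= 0.1))

  # degenerate zero mean: all cuts far in the upper tail
  th0 <- calibrateThresholds(0, 0.5)
  expect_true(all(th0 > 4))

  # infeasible pair named in the error
  expect_error(calibrateThresholds(1.5, 1.6, itemNames = "S9"), "S9")
})

test_that("synthetic data sets round-trip through disk", {
  spec <- syntheticSpec(n = 30, seed = 2)
  dir <- withr::local_tempdir()
  paths <- writeSyntheticData(dir, spec)
  expect_true(all(file.exists(paths)))
  edges <- read.csv(paths["edges"])
  gt <- buildGroundTruth(spec)
  expect_identical(nrow(edges), edgeCount(gt))
  expect_identical(sum(edges$is_bridge), nrow(bridgeEdges(gt)))
})
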