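test_that("expected influence equals brute-force row sums", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- -0.1
  W[2, 3] <- W[3, 2] <- 0.2
  net <- makeNet(W, c("somatic", "somatic", "anxiety_depression"))
  expect_equal(unname(expectedInfluence(net)), c(0.2, 0.5, 0.1))

  for (s in 1:10) {
    p <- sample(3:30, 1)
    W <- randomWeights(p, seed = s)
    net <- makeNet(W, sample(c("somatic", "anxiety_depression"), p, TRUE))
    brute <- vapply(seq_len(p), function(i)
      sum(vapply(seq_len(p), function(j) W[i, j], numeric(1))), numeric(1))
    expect_equal(unname(expectedInfluence(net)), brute, tolerance = 1e-12)
  }

  # adding a positive edge strictly increases the node's EI
  W2 <- W; W2[1, 2] <- W2[2, 1] <- W2[1, 2] + 0.1
  net2 <- makeNet(W2, nodeCommunities(net))
  expect_gt(expectedInfluence(net2)[1], expectedInfluence(net)[1])

  # all-positive network: EI equals the weighted degree
  Wp <- abs(randomWeights(8, seed = 3))
  netp <- makeNet(Wp, rep("somatic", 8))
  expect_equal(unname(expectedInfluence(netp)), rowSums(abs(Wp)))
})

test_that("bridge expected influence sums only cross-community edges", {
  W <- matrix(0, 3, 3)
  W[1, 3] <- W[3, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- 0.2
  W[1, 2] <- W[2, 1] <- 0.5
  comm <- c("somatic", "somatic", "anxiety_depression")
  net <- makeNet(W, comm)
  expect_equal(unname(bridgeExpectedInfluence(net)), c(0.1, 0.2, 0.3))

  for (s in 1:10) {
    p <- sample(4:30, 1)
    W <- randomWeights(p, seed = 40 + s)
    comm <- sample(c("somatic", "anxiety_depression"), p, TRUE)
    net <- makeNet(W, comm)
    bei <- bridgeExpectedInfluence(net)
    brute <- vapply(seq_len(p), function(i)
      sum(W[i, comm != comm[i]]), numeric(1))
    expect_equal(unname(bei), brute, tolerance = 1e-12)
    # double-counting identity
    cross <- outer(comm, comm, "!=") & upper.tri(W)
    expect_equal(sum(bei), 2 * sum(W[cross]), tolerance = 1e-12)
    # swapping the two labels leaves BEI unchanged
    swapped <- ifelse(comm == "somatic", "anxiety_depression", "somatic")
    expect_equal(bridgeExpectedInfluence(makeNet(W, swapped)), bei)
  }

  # no inter-community edges
  W0 <- matrix(0, 3, 3); W0[1, 2] <- W0[2, 1] <- 0.4
  expect_equal(unname(bridgeExpectedInfluence(
    makeNet(W0, c("somatic", "somatic", "anxiety_depression")))), c(0, 0, 0))
})

test_that("z-standardization uses the population-SD convention", {
  expect_equal(zStandardize(c(0, 1)), c(-1, 1))
  expect_warning(z0 <- zStandardize(c(2, 2, 2)), "constant")
  expect_equal(z0, c(0, 0, 0))
  set.seed(6)
  x <- rnorm(25)
  z <- zStandardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)
})

test_that("predictability is neighborhood R-squared, clipped to [0, 1]", {
  set.seed(14)
  ids <- paste0("S", 1:5)
  v <- matrix(sample(0:3, 200 * 5, TRUE), 200, 5)
  rm <- rmFromValues(v, ids)

  # isolated node
  W <- matrix(0, 5, 5)
  W[2, 3] <- W[3, 2] <- 0.2
  net <- makeNet(W, rep("somatic", 5), nodeNames = ids)
  pre <- nodePredictability(rm, net)
  expect_equal(unname(pre[1]), 0)

  # a node whose sole neighbor is its own duplicate predicts perfectly
  v2 <- v; v2[, 2] <- v2[, 3]
  rm2 <- rmFromValues(v2, ids)
  expect_equal(unname(nodePredictability(rm2, net)[2]), 1)

  # oracle: R^2 from lm on the neighbor columns
  W3 <- randomWeights(5, density = 0.5, seed = 2)
  net3 <- makeNet(W3, rep("somatic", 5), nodeNames = ids)
  pre3 <- nodePredictability(rm, net3)
  for (j in 1:5) {
    nb <- which(W3[j, ] != 0)
    if (!length(nb)) next
    fit <- lm(v[, j] ~ v[, nb])
    expect_equal(unname(pre3[j]), summary(fit)$r.squared, tolerance = 1e-10)
  }
  expect_true(all(pre3 >= 0 & pre3 <= 1))

  # collinear neighbors trigger the ridge fallback
  v4 <- v; v4[, 4] <- v4[, 5]
  rm4 <- rmFromValues(v4, ids)
  W4 <- matrix(0, 5, 5)
  W4[1, 4] <- W4[4, 1] <- W4[1, 5] <- W4[5, 1] <- 0.2
  net4 <- makeNet(W4, rep("somatic", 5), nodeNames = ids)
  expect_message(pre4 <- nodePredictability(rm4, net4), "ridge")
  expect_true(pre4[1] >= 0 && pre4[1] <= 1)
})

test_that("layout is deterministic, bounded and edge-responsive", {
  W <- matrix(0, 2, 2)
  W[1, 2] <- W[2, 1] <- 0.5
  net <- makeNet(W, c("somatic", "anxiety_depression"))
  xy1 <- frLayout(net, seed = 4)
  xy2 <- frLayout(net, seed = 4)
  expect_identical(xy1, xy2)
  expect_true(all(xy1 >= 0 & xy1 <= 1))

  # one node sits in the center
  one <- makeNet(matrix(0, 1, 1), "somatic")
  expect_equal(unname(frLayout(one, 1)), matrix(0.5, 1, 2))

  # within a larger layout, a connected pair sits closer than a detached one
  W5 <- matrix(0, 6, 6)
  W5[1, 2] <- W5[2, 1] <- 0.9
  for (k in 3:5) { W5[k, k + 1] <- W5[k + 1, k] <- 0.2 }
  netC <- makeNet(W5, rep("somatic", 6))
  W5b <- W5; W5b[1, 2] <- W5b[2, 1] <- 0
  netD <- makeNet(W5b, rep("somatic", 6))
  dC <- dist(frLayout(netC, seed = 10)[1:2, ])
  dD <- dist(frLayout(netD, seed = 10)[1:2, ])
  expect_lt(as.numeric(dC), as.numeric(dD))
})

test_that("centrality table assembles all node-level indices", {
  spec <- syntheticSpec(n = 150, seed = 61)
  rm <- sampleOrdinal(buildGroundTruth(spec), spec)
  net <- estimateNetwork(rm)
  tb <- centralityTable(net, rm)
  expect_identical(tb$node, nodeNames(net))
  expect_equal(tb$EI_raw, unname(expectedInfluence(net)))
  expect_equal(mean(tb$EI_z), 0, tolerance = 1e-10)
  expect_true(all(tb$PRE >= 0 & tb$PRE <= 1))
})
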