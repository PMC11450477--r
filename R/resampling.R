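#' Network estimation settings shared across resampling
#'
#' Bundles the estimation settings every bootstrap replicate re-uses:
#' EBIC hyperparameter, penalty grid and convergence controls.
#'
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param nLambda penalty grid size (default 100).
#' @param lambdaMinRatio smallest/largest penalty ratio (default 0.01).
#' @param tol,maxit glasso convergence controls.
#' @return a list of class `networkConfig`.
#' @export
networkConfig <- function(gamma = 0.5, nLambda = 100L, lambdaMinRatio = 0.01,
                          tol = 1e-5, maxit = 500L) {
  structure(list(gamma = gamma, nLambda = as.integer(nLambda),
                 lambdaMinRatio = lambdaMinRatio, tol = tol,
                 maxit = as.integer(maxit)),
            class = "networkConfig")
}

# full estimation chain on a response matrix subset:
# Spearman -> nearest-PD -> EBIC glasso
.estimateNetwork <- function(rm, config, communities = NULL) {
  if (is.null(communities)) communities <- itemInfo(rm)$community
  S <- nearestPositiveDefinite(spearmanMatrix(rm))
  ebicGlasso(S, gamma = config$gamma, nLambda = config$nLambda,
             lambdaMinRatio = config$lambdaMinRatio,
             communities = communities, tol = config$tol,
             maxit = config$maxit)
}

#' Estimate the symptom network from responses
#'
#' Convenience wrapper running the full estimation chain -- Spearman
#' correlations, positive-definite repair, EBIC-selected graphical lasso
#' -- on a response matrix, carrying the item communities onto the
#' network.
#'
#' @param rm a [ResponseMatrix-class].
#' @param config a [networkConfig()].
#' @return a [SymptomNetwork-class].
#' @export
estimateNetwork <- function(rm, config = networkConfig()) {
  .estimateNetwork(rm, config)
}

#' Nonparametric bootstrap of edge weights and centralities
#'
#' Resamples respondents with replacement `B` times, re-runs the full
#' estimation chain per replicate, and collects every edge weight plus
#' the expected-influence and bridge-expected-influence vectors.  Edge
#' 95\% confidence intervals are percentile intervals (2.5/97.5).
#' Replicates whose fit fails are skipped and counted; more than 10\%
#' failures is an error.  Reproducible given the seed (replicate index
#' sets are drawn up front, so skipping never shifts the mapping).
#'
#' @param rm a [ResponseMatrix-class].
#' @param config a [networkConfig()].
#' @param B number of bootstrap samples (default 1000).
#' @param seed integer seed.
#' @return a [BootstrapSummary-class].
#' @export
bootstrapEdges <- function(rm, config = networkConfig(), B = 1000L,
                           seed = 1L) {
  B <- as.integer(B)
  stopifnot(B >= 1L)
  net <- .estimateNetwork(rm, config)
  p <- length(nodeNames(net))
  ij <- .pairIndices(p)
  pairNames <- paste(nodeNames(net)[ij[, 1]], nodeNames(net)[ij[, 2]],
                     sep = "--")
  n <- nRespondents(rm)
  set.seed(seed)
  idxMat <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)

  edgeBoot <- matrix(NA_real_, B, nrow(ij), dimnames = list(NULL, pairNames))
  eiBoot <- beiBoot <- matrix(NA_real_, B, p,
                              dimnames = list(NULL, nodeNames(net)))
  failures <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      nb <- .estimateNetwork(rm[idxMat[b, ], ], config)
      list(w = edgeWeights(nb)[ij], ei = expectedInfluence(nb),
           bei = bridgeExpectedInfluence(nb))
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    edgeBoot[b, ] <- res$w
    eiBoot[b, ] <- res$ei
    beiBoot[b, ] <- res$bei
  }
  if (failures > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates failed", failures, B))
  if (failures > 0L)
    message(sprintf("%d bootstrap replicate(s) failed and were skipped",
                    failures))
  ok <- stats::complete.cases(edgeBoot)
  ci <- apply(edgeBoot[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  edges <- data.frame(node_a = nodeNames(net)[ij[, 1]],
                      node_b = nodeNames(net)[ij[, 2]],
                      estimate = edgeWeights(net)[ij],
                      bootMean = colMeans(edgeBoot[ok, , drop = FALSE]),
                      ciLower = ci[1L, ], ciUpper = ci[2L, ],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("BootstrapSummary", B = B, edges = edges,
      edgeBoot = edgeBoot[ok, , drop = FALSE],
      eiBoot = eiBoot[ok, , drop = FALSE],
      beiBoot = beiBoot[ok, , drop = FALSE],
      failures = failures, network = net)
}

#' Case-dropping bootstrap stability of centralities
#'
#' For each case-drop proportion in the grid, draws subsamples without
#' replacement, re-estimates the network, and records the Pearson
#' correlation between subsample and full-sample centralities.  The
#' correlation-stability (CS) coefficient is the largest drop proportion
#' (reached contiguously from the smallest) at which at least
#' `probLevel` of the correlations are >= `corThreshold`; values above
#' 0.5 are conventionally read as good stability, above 0.25 as
#' acceptable.
#'
#' @param rm a [ResponseMatrix-class].
#' @param config a [networkConfig()].
#' @param dropGrid case-drop proportions (default 0.10 to 0.75 by 0.05).
#' @param BPerLevel subsamples per grid level (default 250; raise to
#'   1000 for publication-grade runs).
#' @param seed integer seed.
#' @param statistics which centralities to track (default EI and BEI).
#' @param corThreshold,probLevel CS definition parameters (0.7 / 0.95).
#' @return a [StabilityResult-class].
#' @export
caseDroppingBootstrap <- function(rm, config = networkConfig(),
                                  dropGrid = seq(0.10, 0.75, by = 0.05),
                                  BPerLevel = 250L, seed = 1L,
                                  statistics = c("EI", "BEI"),
                                  corThreshold = 0.7, probLevel = 0.95) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  n <- nRespondents(rm)
  p <- nItems(rm)
  keepN <- as.integer(round((1 - dropGrid) * n))
  ok <- keepN >= p + 5L
  if (!all(ok)) {
    warning("truncating drop grid: subsamples below p + 5 respondents")
    dropGrid <- dropGrid[ok]
    keepN <- keepN[ok]
  }
  if (!length(dropGrid)) stop("drop grid empty after truncation")

  full <- .estimateNetwork(rm, config)
  ref <- list(EI = expectedInfluence(full), BEI = bridgeExpectedInfluence(full))
  cors <- lapply(statistics, function(s)
    matrix(NA_real_, BPerLevel, length(dropGrid),
           dimnames = list(NULL, paste0("drop", dropGrid))))
  names(cors) <- statistics

  for (li in seq_along(dropGrid)) {
    set.seed(.subSeed(seed, li))
    for (b in seq_len(BPerLevel)) {
      idx <- sample.int(n, keepN[li])
      sub <- tryCatch(.estimateNetwork(rm[idx, ], config),
                      error = function(e) NULL)
      if (is.null(sub)) next
      for (s in statistics) {
        val <- if (s == "EI") expectedInfluence(sub)
               else bridgeExpectedInfluence(sub)
        cors[[s]][b, li] <-
          if (stats::sd(val) == 0 || stats::sd(ref[[s]]) == 0) 0
          else stats::cor(ref[[s]], val)
      }
    }
  }
  res <- new("StabilityResult", dropProportions = dropGrid,
             correlations = cors,
             csCoefficient = stats::setNames(rep(0, length(statistics)),
                                             statistics),
             corThreshold = corThreshold, probLevel = probLevel)
  res@csCoefficient <- csCoefficient(res)
  validObject(res)
  res
}

#' Paired bootstrap difference tests
#'
#' For every unordered pair of edges (or of nodes, for EI/BEI), checks
#' whether the (alpha/2, 1-alpha/2) percentile interval of the paired
#' replicate differences excludes zero.  Pairs from the same replicate
#' stream, as produced by [bootstrapEdges()]; no multiplicity
#' correction is applied (matching common practice for these tests).
#'
#' @param boot a [BootstrapSummary-class].
#' @param what `"edge"`, `"EI"` or `"BEI"`.
#' @param alpha significance level (default 0.05).
#' @return symmetric logical matrix (diagonal `FALSE`) with attribute
#'   `"alpha"`; `TRUE` marks a significant difference.
#' @export
differenceTest <- function(boot, what = c("edge", "EI", "BEI"),
                           alpha = 0.05) {
  what <- match.arg(what)
  mat <- switch(what, edge = boot@edgeBoot, EI = boot@eiBoot,
                BEI = boot@beiBoot)
  m <- ncol(mat)
  sig <- matrix(FALSE, m, m, dimnames = list(colnames(mat), colnames(mat)))
  probs <- c(alpha / 2, 1 - alpha / 2)
  for (i in seq_len(m - 1L)) {
    d <- mat[, (i + 1L):m, drop = FALSE] - mat[, i]
    qs <- apply(d, 2L, stats::quantile, probs = probs, names = FALSE)
    hit <- qs[1L, ] > 0 | qs[2L, ] < 0
    sig[i, (i + 1L):m] <- hit
    sig[(i + 1L):m, i] <- hit
  }
  attr(sig, "alpha") <- alpha
  sig
}

#' @describeIn differenceTest test one pair of paired bootstrap
#'   distributions directly; errors if the vectors have unequal length
#'   (they must come from the same replicate stream).
#' @param x,y paired replicate vectors of the two quantities.
#' @export
pairDifferenceSignificant <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y))
    stop("paired distributions must have equal length")
  qs <- stats::quantile(y - x, probs = c(alpha / 2, 1 - alpha / 2),
                        names = FALSE)
  qs[1L] > 0 || qs[2L] < 0
}
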