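#' Specify a synthetic psychosomatic data set
#'
#' Builds the specification of the latent-Gaussian ordinal generator.
#' The defaults emulate the study conditions the package models: 665
#' respondents, a 20-node network of 11 somatic and 9 anxiety/depression
#' items, a sparse positive two-community partial-correlation structure
#' with positively weighted bridge edges, and item marginals calibrated
#' to published item means and SDs.
#'
#' @param n sample size.
#' @param communitySizes named integer vector with elements `somatic` and
#'   `anxiety_depression`.
#' @param withinDensity proportion of within-community pairs carrying an
#'   edge (default 0.20, giving a mean degree of about 3 -- the sparsity
#'   typical of published symptom networks).
#' @param bridgeDensity proportion of between-community pairs carrying an
#'   edge (default 0.10).
#' @param weightRange magnitude interval for nonzero partial correlations.
#' @param bridgePositive,withinPositive edge-sign conventions; both TRUE
#'   by default (symptom networks are overwhelmingly positive, and the
#'   somatic--psychological bridges the model emulates are all positive).
#' @param thresholds optional p x 3 matrix of latent cut points; by
#'   default calibrated via [calibrateThresholds()] to
#'   [referenceItemMoments()] when the node set matches, otherwise to a
#'   generic mild-symptom marginal (mean 0.7, SD 0.8).
#' @param seed integer seed governing every draw.
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(n = 665,
                          communitySizes = c(somatic = 11L,
                                             anxiety_depression = 9L),
                          withinDensity = 0.20, bridgeDensity = 0.10,
                          weightRange = c(0.15, 0.35),
                          bridgePositive = TRUE, withinPositive = TRUE,
                          thresholds = NULL, seed = 1L) {
  if (is.null(thresholds)) thresholds <- matrix(numeric(), 0L, 0L)
  new("SyntheticSpec", n = as.integer(n),
      communitySizes = stats::setNames(as.integer(communitySizes),
                                       names(communitySizes)),
      withinDensity = withinDensity, bridgeDensity = bridgeDensity,
      weightRange = as.numeric(weightRange),
      bridgePositive = isTRUE(bridgePositive),
      withinPositive = isTRUE(withinPositive),
      thresholds = thresholds, seed = as.integer(seed))
}

.syntheticNodeNames <- function(communitySizes) {
  ns <- communitySizes[["somatic"]]
  na <- communitySizes[["anxiety_depression"]]
  som <- if (ns > 0) paste0("S", seq_len(ns)) else character()
  anx <- if (na >= 3) c("P1", "P2", paste0("G", seq_len(na - 2L)))
         else if (na == 2) c("P1", "P2")
         else if (na == 1) "G1" else character()
  c(som, anx)
}

.syntheticCommunities <- function(communitySizes) {
  rep(c("somatic", "anxiety_depression"),
      times = c(communitySizes[["somatic"]],
                communitySizes[["anxiety_depression"]]))
}

#' Mean and SD of a discretized standard normal
#'
#' For each row of cut points, the mean and standard deviation of the
#' 0--3 ordinal variable obtained by thresholding a standard normal.
#'
#' @param thresholds numeric vector of 3 increasing cut points, or a
#'   p x 3 matrix of them.
#' @return data.frame with columns `mean` and `sd`, one row per item.
#' @export
impliedOrdinalMoments <- function(thresholds) {
  if (is.null(dim(thresholds))) thresholds <- matrix(thresholds, 1L)
  mom <- t(apply(thresholds, 1L, function(th) {
    pr <- diff(c(0, stats::pnorm(th), 1))
    mu <- sum(0:3 * pr)
    c(mean = mu, sd = sqrt(max(sum((0:3)^2 * pr) - mu^2, 0)))
  }))
  as.data.frame(mom)
}

#' Calibrate latent thresholds to target ordinal moments
#'
#' Finds, for each item, three increasing cut points on the latent
#' standard-normal scale such that the discretized 0--3 marginal matches
#' a target mean within 0.05 and a target SD within 0.1 (numerical
#' search; Nelder-Mead on an unconstrained reparametrization).
#'
#' @param targetMeans,targetSds per-item target moments on the 0--3
#'   scale.
#' @param itemNames optional names used in error messages.
#' @return p x 3 matrix of cut points.
#' @export
calibrateThresholds <- function(targetMeans, targetSds, itemNames = NULL) {
  stopifnot(length(targetMeans) == length(targetSds))
  if (is.null(itemNames)) itemNames <- paste0("item", seq_along(targetMeans))
  out <- matrix(NA_real_, length(targetMeans), 3L,
                dimnames = list(itemNames, NULL))
  for (i in seq_along(targetMeans)) {
    M <- targetMeans[i]; SD <- targetSds[i]
    if (M < 1e-8) { out[i, ] <- c(8, 9, 10); next }   # column is all zeros
    if (M < 0 || M > 3)
      stop("infeasible target mean for item ", itemNames[i])
    f <- M - floor(M)
    if (SD^2 > M * (3 - M) || SD^2 < f * (1 - f) * 0.999)
      stop("infeasible (mean, sd) pair for item ", itemNames[i])
    # stage 1: discretized-normal family th_k = (k + 0.5 - mu)/sig -- two
    # parameters for two targets, so the solution is well determined and a
    # symmetric target yields symmetric cut points
    obj2 <- function(par) {
      mom <- impliedOrdinalMoments((c(0.5, 1.5, 2.5) - par[1]) / exp(par[2]))
      (mom$mean - M)^2 + (mom$sd - SD)^2
    }
    fit2 <- stats::optim(c(M, log(max(SD, 0.05))), obj2,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    th <- (c(0.5, 1.5, 2.5) - fit2$par[1]) / exp(fit2$par[2])
    mom <- impliedOrdinalMoments(th)
    if (abs(mom$mean - M) > 0.05 || abs(mom$sd - SD) > 0.1) {
      # stage 2: free-threshold refinement for targets the two-parameter
      # family cannot reach
      obj3 <- function(u) {
        mom <- impliedOrdinalMoments(cumsum(c(u[1], exp(u[2]), exp(u[3]))))
        (mom$mean - M)^2 + (mom$sd - SD)^2
      }
      d0 <- pmax(diff(th), 1e-3)
      fit3 <- stats::optim(c(th[1], log(d0)), obj3, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
      th <- cumsum(c(fit3$par[1], exp(fit3$par[2]), exp(fit3$par[3])))
      mom <- impliedOrdinalMoments(th)
    }
    if (abs(mom$mean - M) > 0.05 || abs(mom$sd - SD) > 0.1)
      stop("threshold calibration failed for item ", itemNames[i],
           sprintf(" (reached mean %.3f, sd %.3f)", mom$mean, mom$sd))
    out[i, ] <- th
  }
  out
}

.defaultThresholds <- function(spec) {
  nm <- .syntheticNodeNames(spec@communitySizes)
  ref <- referenceItemMoments()
  if (all(nm %in% ref$item_id)) {
    ref <- ref[match(nm, ref$item_id), ]
    calibrateThresholds(ref$mean, ref$sd, nm)
  } else {
    p <- length(nm)
    calibrateThresholds(rep(0.7, p), rep(0.8, p), nm)
  }
}

.pdInflate <- function(K0, minEigen = 0.05, cap = 2) {
  ev <- eigen(K0, symmetric = TRUE, only.values = TRUE)$values
  delta <- max(0, minEigen - min(ev))
  if (delta > cap)
    stop(sprintf(paste0("requested structure needs a diagonal inflation of ",
                        "%.2f (> cap %.2f) to become positive definite; ",
                        "reduce densities or weights"), delta, cap))
  K <- K0 + diag(delta, nrow(K0))
  # re-standardize to unit diagonal; touches only the overall scale of
  # each row/column, so the support is preserved exactly
  D <- diag(1 / sqrt(diag(K)))
  K <- D %*% K %*% D
  (K + t(K)) / 2
}

.gtFromK <- function(K, communities, nodeNames) {
  dimnames(K) <- list(nodeNames, nodeNames)
  pc <- -K / sqrt(outer(diag(K), diag(K)))
  diag(pc) <- 0
  ij <- .pairIndices(nrow(K))
  nz <- ij[pc[ij] != 0, , drop = FALSE]
  cross <- communities[nz[, 1]] != communities[nz[, 2]]
  new("GroundTruthNetwork", precision = K, partialCorr = pc,
      communities = communities,
      bridgeEdges = nz[cross, , drop = FALSE])
}

#' Draw a ground-truth sparse two-community network
#'
#' Draws a sparse symmetric edge support at the requested within- and
#' between-community densities, assigns partial-correlation weights from
#' `weightRange`, converts to a precision matrix (unit diagonal,
#' \eqn{\kappa_{ij} = -w_{ij}}), and enforces positive definiteness by
#' adding the exact diagonal shift that lifts the smallest eigenvalue to
#' 0.05, followed by re-standardization.  The shift touches only the
#' diagonal, so the edge support is preserved exactly (weights shrink by
#' the common factor 1/(1+delta)).
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [GroundTruthNetwork-class].
#' @export
buildGroundTruth <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  comm <- .syntheticCommunities(spec@communitySizes)
  nm <- .syntheticNodeNames(spec@communitySizes)
  p <- length(comm)
  W <- matrix(0, p, p)
  ij <- .pairIndices(p)
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    bridge <- comm[i] != comm[j]
    dens <- if (bridge) spec@bridgeDensity else spec@withinDensity
    if (stats::runif(1) < dens) {
      w <- stats::runif(1, spec@weightRange[1], spec@weightRange[2])
      pos <- if (bridge) spec@bridgePositive else spec@withinPositive
      if (!pos && stats::runif(1) < 0.5) w <- -w
      W[i, j] <- W[j, i] <- w
    }
  }
  K0 <- diag(p) - W
  .gtFromK(.pdInflate(K0), comm, nm)
}

#' Ground-truth network from an explicit weight matrix
#'
#' Deterministic counterpart of [buildGroundTruth()]: takes a symmetric
#' partial-correlation matrix (zero diagonal) and community labels and
#' applies the same precision-matrix construction and positive-definite
#' inflation.
#'
#' @param W symmetric p x p partial-correlation matrix, zero diagonal.
#' @param communities per-node community labels.
#' @param nodeNames optional node names.
#' @return a [GroundTruthNetwork-class].
#' @export
groundTruthFromWeights <- function(W, communities,
                                   nodeNames = colnames(W)) {
  stopifnot(isSymmetric(unname(W)), all(diag(W) == 0))
  if (is.null(nodeNames)) nodeNames <- paste0("V", seq_len(ncol(W)))
  .gtFromK(.pdInflate(diag(ncol(W)) - W), communities, nodeNames)
}

#' Sample ordinal questionnaire data from a ground-truth network
#'
#' Samples latent vectors from the zero-mean Gaussian whose correlation
#' matrix is the standardized inverse of the ground-truth precision
#' matrix, then discretizes every coordinate into \{0,1,2,3\} by its
#' per-item thresholds (a Gaussian copula with ordinal margins).
#'
#' @param gt a [GroundTruthNetwork-class].
#' @param spec the [SyntheticSpec-class] that produced it (supplies n,
#'   thresholds and the item layout).
#' @param seed seed for the draw (default: the spec's seed).
#' @return a [ResponseMatrix-class] with item ids matching the
#'   ground-truth node names.
#' @export
sampleOrdinal <- function(gt, spec, seed = spec@seed) {
  validObject(spec)
  K <- precisionMatrix(gt)
  p <- ncol(K)
  Sigma <- stats::cov2cor(solve(K))
  th <- if (nrow(spec@thresholds) > 0L) spec@thresholds
        else .defaultThresholds(spec)
  if (nrow(th) != p) stop("thresholds must have one row per item")
  set.seed(seed)
  Z <- matrix(stats::rnorm(spec@n * p), spec@n, p) %*% chol(Sigma)
  vals <- vapply(seq_len(p),
                 function(j) findInterval(Z[, j], th[j, ]),
                 integer(spec@n))
  if (spec@n == 1L) vals <- matrix(vals, 1L, p)
  nm <- colnames(K)
  scale <- ifelse(startsWith(nm, "P"), "PHQ2",
                  ifelse(startsWith(nm, "G"), "GAD7", "somatic"))
  items <- data.frame(item_id = nm, label = nm, scale = scale,
                      community = nodeCommunities(gt),
                      stringsAsFactors = FALSE)
  colnames(vals) <- nm
  responseMatrix(vals, items = items)
}

#' Write a synthetic data set to disk
#'
#' Writes the sampled responses (CSV), the ground-truth edge list (CSV
#' with columns `node_a`, `node_b`, `weight`, `is_bridge`) and the
#' generator specification (YAML) into a directory.
#'
#' @param dir output directory (created if needed).
#' @param spec a [SyntheticSpec-class].
#' @param gt optional pre-built ground truth; built from `spec` if
#'   missing.
#' @param rm optional pre-sampled responses; sampled if missing.
#' @return invisibly, the named vector of file paths written.
#' @export
writeSyntheticData <- function(dir, spec, gt = NULL, rm = NULL) {
  if (is.null(gt)) gt <- buildGroundTruth(spec)
  if (is.null(rm)) rm <- sampleOrdinal(gt, spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(responses = file.path(dir, "responses.csv"),
             edges = file.path(dir, "ground_truth_edges.csv"),
             spec = file.path(dir, "synthetic_spec.yaml"))
  utils::write.csv(as.data.frame(responseValues(rm)), paths["responses"],
                   row.names = FALSE)
  W <- edgeWeights(gt)
  ij <- .pairIndices(ncol(W))
  nz <- ij[W[ij] != 0, , drop = FALSE]
  comm <- nodeCommunities(gt)
  edges <- data.frame(node_a = colnames(W)[nz[, 1]],
                      node_b = colnames(W)[nz[, 2]],
                      weight = W[nz],
                      is_bridge = comm[nz[, 1]] != comm[nz[, 2]])
  utils::write.csv(edges, paths["edges"], row.names = FALSE)
  yaml::write_yaml(list(
    n = spec@n, communitySizes = as.list(spec@communitySizes),
    withinDensity = spec@withinDensity, bridgeDensity = spec@bridgeDensity,
    weightRange = spec@weightRange, bridgePositive = spec@bridgePositive,
    withinPositive = spec@withinPositive, seed = spec@seed),
    paths["spec"])
  invisible(paths)
}
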