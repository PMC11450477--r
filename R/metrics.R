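#' @rdname expectedInfluence
#' @export
setMethod("expectedInfluence", "SymptomNetwork", function(object) {
  w <- edgeWeights(object)
  stats::setNames(rowSums(w), nodeNames(object))
})

#' @rdname expectedInfluence
#' @export
setMethod("expectedInfluence", "GroundTruthNetwork", function(object) {
  w <- edgeWeights(object)
  stats::setNames(rowSums(w), colnames(w))
})

.bei <- function(w, comm, nm) {
  other <- outer(comm, comm, "!=")
  stats::setNames(rowSums(w * other), nm)
}

#' @rdname bridgeExpectedInfluence
#' @export
setMethod("bridgeExpectedInfluence", "SymptomNetwork", function(object) {
  comm <- nodeCommunities(object)
  if (any(is.na(comm) | comm == ""))
    stop("missing community label for node(s): ",
         paste(nodeNames(object)[is.na(comm) | comm == ""], collapse = ", "))
  .bei(edgeWeights(object), comm, nodeNames(object))
})

#' @rdname bridgeExpectedInfluence
#' @export
setMethod("bridgeExpectedInfluence", "GroundTruthNetwork", function(object) {
  w <- edgeWeights(object)
  .bei(w, nodeCommunities(object), colnames(w))
})

#' z-standardize a centrality vector
#'
#' Centers and scales by the population standard deviation (divide by
#' n, the usual convention for reporting standardized centralities).
#' A constant input yields all zeros with a warning.
#'
#' @param x numeric vector with at least 2 entries.
#' @return standardized vector (mean 0, population SD 1).
#' @export
zStandardize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to standardize")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    warning("constant input; returning zeros")
    return(x * 0)
  }
  (x - mean(x)) / s
}

#' Nodewise predictability
#'
#' The proportion of a node's variance explainable from its estimated
#' network neighbors: the coefficient of determination R^2 of the
#' least-squares regression of the node's observed scores on the scores
#' of all nodes it shares a nonzero edge with, clipped to [0, 1].  An
#' isolated node has predictability 0.  A collinear neighbor design
#' falls back to a ridge solve with penalty 1e-6 (reported via a
#' message).
#'
#' @param rm the [ResponseMatrix-class] the network was estimated from
#'   (columns must cover the network's nodes).
#' @param net a [SymptomNetwork-class].
#' @return named numeric vector of per-node predictability in [0, 1].
#' @export
nodePredictability <- function(rm, net) {
  nm <- nodeNames(net)
  idx <- match(nm, itemInfo(rm)$item_id)
  if (anyNA(idx))
    stop("response matrix lacks item(s): ", paste(nm[is.na(idx)], collapse = ", "))
  v <- responseValues(rm)[, idx, drop = FALSE]
  w <- edgeWeights(net)
  pre <- stats::setNames(numeric(length(nm)), nm)
  for (j in seq_along(nm)) {
    nb <- which(w[j, ] != 0)
    if (!length(nb)) next
    y <- v[, j]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) next
    X <- cbind(1, v[, nb, drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      message("collinear neighbors for node ", nm[j], "; ridge fallback")
      XtX <- crossprod(X) + diag(1e-6, ncol(X))
      beta <- solve(XtX, crossprod(X, y))
      res <- y - X %*% beta
    } else {
      res <- stats::residuals(stats::lm.fit(X, y))
    }
    pre[j] <- min(max(1 - sum(res^2) / tss, 0), 1)
  }
  pre
}

#' Fruchterman-Reingold layout of the network
#'
#' Force-directed coordinates with absolute edge weights as attraction
#' strengths, rescaled to the unit square.  Deterministic given the
#' seed.
#'
#' @param net a [SymptomNetwork-class].
#' @param seed integer seed.
#' @return p x 2 matrix of coordinates in the unit square, row names =
#'   node names.
#' @export
frLayout <- function(net, seed = 1L) {
  w <- abs(edgeWeights(net))
  p <- ncol(w)
  if (p == 1L)
    return(matrix(0.5, 1L, 2L, dimnames = list(nodeNames(net), c("x", "y"))))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, weights = if (igraph::ecount(g) > 0)
    igraph::E(g)$weight else NULL)
  rng <- apply(xy, 2L, function(z) diff(range(z)))
  xy <- sweep(xy, 2L, apply(xy, 2L, min))
  xy <- sweep(xy, 2L, ifelse(rng > 0, rng, 1), "/")
  dimnames(xy) <- list(nodeNames(net), c("x", "y"))
  xy
}

#' Node-level centrality table
#'
#' Expected influence, bridge expected influence (raw and
#' z-standardized; population-SD convention) and, when responses are
#' supplied, nodewise predictability -- one row per network node.
#'
#' @param net a [SymptomNetwork-class].
#' @param rm optional [ResponseMatrix-class] for predictability.
#' @return data.frame with columns `node`, `community`, `EI_raw`,
#'   `EI_z`, `BEI_raw`, `BEI_z` and (if `rm` given) `PRE`.
#' @export
centralityTable <- function(net, rm = NULL) {
  ei <- expectedInfluence(net)
  bei <- bridgeExpectedInfluence(net)
  out <- data.frame(node = nodeNames(net),
                    community = nodeCommunities(net),
                    EI_raw = unname(ei),
                    EI_z = unname(suppressWarnings(zStandardize(ei))),
                    BEI_raw = unname(bei),
                    BEI_z = unname(suppressWarnings(zStandardize(bei))),
                    stringsAsFactors = FALSE)
  if (!is.null(rm)) out$PRE <- unname(nodePredictability(rm, net))
  out
}
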