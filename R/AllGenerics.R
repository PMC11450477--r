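#' @name symnet-accessors
#' @title Accessors for symnet classes
#'
#' @description Accessor generics for the package's S4 containers:
#' response values, item catalogs, edge weights, precision matrices,
#' community labels and edge summaries.  Slots should be reached through
#' these rather than `@`.
#'
#' @param object a symnet S4 object.
#' @return The requested component; see the individual methods.
NULL

#' @rdname symnet-accessors
#' @export
setGeneric("responseValues", function(object) standardGeneric("responseValues"))

#' @rdname symnet-accessors
#' @export
setGeneric("itemInfo", function(object) standardGeneric("itemInfo"))

#' @rdname symnet-accessors
#' @export
setGeneric("respondentIds", function(object) standardGeneric("respondentIds"))

#' @rdname symnet-accessors
#' @export
setGeneric("demographics", function(object) standardGeneric("demographics"))

#' @rdname symnet-accessors
#' @export
setGeneric("nRespondents", function(object) standardGeneric("nRespondents"))

#' @rdname symnet-accessors
#' @export
setGeneric("nItems", function(object) standardGeneric("nItems"))

#' @rdname symnet-accessors
#' @export
setGeneric("corValues", function(object) standardGeneric("corValues"))

#' @rdname symnet-accessors
#' @export
setGeneric("sampleSize", function(object) standardGeneric("sampleSize"))

#' @rdname symnet-accessors
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))

#' @rdname symnet-accessors
#' @export
setGeneric("precisionMatrix", function(object) standardGeneric("precisionMatrix"))

#' @rdname symnet-accessors
#' @export
setGeneric("nodeCommunities", function(object) standardGeneric("nodeCommunities"))

#' @rdname symnet-accessors
#' @export
setGeneric("nodeNames", function(object) standardGeneric("nodeNames"))

#' @rdname symnet-accessors
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname symnet-accessors
#' @export
setGeneric("meanEdgeWeight", function(object) standardGeneric("meanEdgeWeight"))

#' @rdname symnet-accessors
#' @export
setGeneric("bridgeEdges", function(object) standardGeneric("bridgeEdges"))

#' @rdname symnet-accessors
#' @export
setGeneric("regularizationPath", function(object) standardGeneric("regularizationPath"))

#' @rdname symnet-accessors
#' @export
setGeneric("prevalencePct", function(object) standardGeneric("prevalencePct"))

#' @rdname symnet-accessors
#' @export
setGeneric("totalScores", function(object) standardGeneric("totalScores"))

#' Expected influence of every node
#'
#' One-step expected influence: the signed sum of all edge weights
#' incident to a node.  Unlike strength centrality it does not take
#' absolute values, so it is the appropriate centrality for networks that
#' may contain negative edges.
#'
#' @param object a [SymptomNetwork-class] (or a [GroundTruthNetwork-class],
#'   for which the true partial correlations are summed).
#' @return named numeric vector of per-node expected influence.
#' @export
setGeneric("expectedInfluence", function(object) standardGeneric("expectedInfluence"))

#' Bridge expected influence of every node
#'
#' The signed sum of a node's edge weights to nodes in the *other*
#' community; high values identify symptoms transmitting activation
#' between the somatic and anxiety--depression clusters.
#'
#' @param object a [SymptomNetwork-class] or [GroundTruthNetwork-class]
#'   with community labels on every node.
#' @return named numeric vector of per-node bridge expected influence.
#' @export
setGeneric("bridgeExpectedInfluence",
           function(object) standardGeneric("bridgeExpectedInfluence"))

#' Correlation-stability coefficient
#'
#' @param object a [StabilityResult-class].
#' @param corThreshold correlation threshold (default: the one stored).
#' @param probLevel required probability (default: the one stored).
#' @return named numeric vector, the CS coefficient per statistic.
#' @export
setGeneric("csCoefficient",
  function(object, corThreshold = NULL, probLevel = NULL)
    standardGeneric("csCoefficient"))
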