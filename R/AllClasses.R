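#' @importFrom methods new validObject is slot setValidity show
NULL

.SCALES <- c("GAD7", "PHQ2", "somatic")
.COMMUNITIES <- c("somatic", "anxiety_depression")

.checkItemCatalog <- function(items) {
  msgs <- character()
  need <- c("item_id", "label", "scale", "community")
  miss <- setdiff(need, names(items))
  if (length(miss))
    return(sprintf("item catalog lacks column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(items$item_id))
    msgs <- c(msgs, "item_id values must be unique")
  if (!all(items$scale %in% .SCALES))
    msgs <- c(msgs, sprintf("scale must be one of %s", paste(.SCALES, collapse = "/")))
  if (!all(items$community %in% .COMMUNITIES))
    msgs <- c(msgs, sprintf("community must be one of %s", paste(.COMMUNITIES, collapse = "/")))
  bad <- items$scale %in% c("GAD7", "PHQ2") & items$community != "anxiety_depression"
  if (any(bad))
    msgs <- c(msgs, "GAD-7 and PHQ-2 items must belong to the anxiety_depression community")
  bad <- items$scale == "somatic" & items$community != "somatic"
  if (any(bad))
    msgs <- c(msgs, "somatic-scale items must belong to the somatic community")
  msgs
}

#' Ordinal questionnaire responses with item metadata
#'
#' An n x p table of integer Likert responses (each item scored 0--3:
#' none / occasional / sometimes / frequent) together with a per-item
#' catalog giving the item label, its source scale (GAD-7, PHQ-2 or the
#' somatic-symptom inventory) and its network community (somatic vs
#' anxiety--depression).  This is the single raw input of every stage of
#' the analysis.
#'
#' @slot values integer matrix, respondents in rows, items in columns,
#'   entries in \{0, 1, 2, 3\}.
#' @slot items data.frame with columns `item_id`, `label`, `scale`,
#'   `community`, one row per column of `values`, in column order.
#' @slot respondentIds character vector of row identifiers.
#' @slot demographics data.frame of optional pass-through respondent
#'   covariates (possibly zero columns); never used in estimation.
#'
#' @seealso [responseMatrix()], [loadResponses()]
#' @export
setClass("ResponseMatrix",
  representation(values = "matrix", items = "data.frame",
                 respondentIds = "character", demographics = "data.frame"))

setValidity("ResponseMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) < 1L) msgs <- c(msgs, "need at least one respondent")
  if (ncol(v) < 2L) msgs <- c(msgs, "need at least two items")
  if (!all(v %in% 0:3)) msgs <- c(msgs, "all responses must be integers in 0..3")
  if (ncol(v) != nrow(object@items))
    msgs <- c(msgs, "item catalog must have one row per response column")
  if (length(object@respondentIds) != nrow(v))
    msgs <- c(msgs, "respondentIds length must equal the number of rows")
  if (nrow(object@demographics) > 0L && nrow(object@demographics) != nrow(v))
    msgs <- c(msgs, "demographics must have one row per respondent")
  msgs <- c(msgs, .checkItemCatalog(object@items))
  if (!is.null(colnames(v)) && !identical(colnames(v), object@items$item_id))
    msgs <- c(msgs, "column names must match catalog item_id order")
  if (length(msgs)) msgs else TRUE
})

#' Screening outcome for a psychological scale
#'
#' Per-respondent totals of a screener together with the count and
#' percentage of respondents at or above the scale's clinical cut-off
#' (GAD-7 >= 5 for anxiety, PHQ-2 >= 2 for depression).
#'
#' @slot scale scale name ("GAD7" or "PHQ2").
#' @slot threshold integer screening cut-off.
#' @slot totalScores per-respondent integer totals.
#' @slot positives number of respondents at or above the cut-off.
#' @slot prevalencePct positives as a percentage of n, rounded half-up
#'   to two decimals.
#' @slot n number of respondents.
#' @export
setClass("ScreeningResult",
  representation(scale = "character", threshold = "integer",
                 totalScores = "integer", positives = "integer",
                 prevalencePct = "numeric", n = "integer"))

setValidity("ScreeningResult", function(object) {
  msgs <- character()
  if (object@positives < 0L || object@positives > object@n)
    msgs <- c(msgs, "positives must lie in [0, n]")
  if (length(msgs)) msgs else TRUE
})

#' Spearman correlation matrix of questionnaire items
#'
#' @slot S symmetric p x p matrix of Spearman rank correlations with unit
#'   diagonal.
#' @slot nUsed number of complete cases the correlations were computed on.
#' @export
setClass("CorrelationMatrix",
  representation(S = "matrix", nUsed = "integer"))

setValidity("CorrelationMatrix", function(object) {
  S <- object@S
  msgs <- character()
  if (nrow(S) != ncol(S)) msgs <- c(msgs, "S must be square")
  if (max(abs(S - t(S))) > 1e-8) msgs <- c(msgs, "S must be symmetric")
  if (any(abs(S) > 1 + 1e-8)) msgs <- c(msgs, "entries must lie in [-1, 1]")
  if (max(abs(diag(S) - 1)) > 1e-8) msgs <- c(msgs, "diagonal must be 1")
  if (length(msgs)) msgs else TRUE
})

#' Specification of the synthetic ordinal data generator
#'
#' Describes the study conditions a synthetic data set should emulate:
#' sample size, the two symptom communities and their sizes, the sparsity
#' and magnitude of the true partial-correlation structure, and the
#' per-item latent thresholds that shape the ordinal marginals.
#'
#' @slot n sample size (default 665, the size of the survey the package
#'   models).
#' @slot communitySizes named integer vector, sizes of the `somatic` and
#'   `anxiety_depression` communities (defaults 11 and 9).
#' @slot withinDensity proportion of within-community node pairs carrying
#'   a nonzero true partial correlation.
#' @slot bridgeDensity proportion of between-community pairs carrying an
#'   edge.
#' @slot weightRange interval the nonzero partial-correlation magnitudes
#'   are drawn from.
#' @slot bridgePositive logical; if TRUE (default) all bridge edges are
#'   positive, mirroring the all-positive bridging structure typical of
#'   psychosomatic comorbidity networks.
#' @slot withinPositive logical; if TRUE (default) within-community edges
#'   are positive too (symptom networks are overwhelmingly positive).
#' @slot thresholds p x 3 matrix of strictly increasing latent cut points,
#'   one row per item, or a 0 x 0 matrix to request the default
#'   calibration to published item means/SDs.
#' @slot seed integer seed governing all draws.
#' @export
setClass("SyntheticSpec",
  representation(n = "integer", communitySizes = "integer",
                 withinDensity = "numeric", bridgeDensity = "numeric",
                 weightRange = "numeric", bridgePositive = "logical",
                 withinPositive = "logical", thresholds = "matrix",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@n < 1L) msgs <- c(msgs, "n must be >= 1")
  if (!identical(sort(names(object@communitySizes)), sort(.COMMUNITIES)))
    msgs <- c(msgs, "communitySizes must be named 'somatic' and 'anxiety_depression'")
  if (object@withinDensity < 0 || object@withinDensity > 1 ||
      object@bridgeDensity < 0 || object@bridgeDensity > 1)
    msgs <- c(msgs, "densities must lie in [0, 1]")
  if (length(object@weightRange) != 2L || any(object@weightRange <= 0) ||
      any(object@weightRange >= 1) || diff(object@weightRange) < 0)
    msgs <- c(msgs, "weightRange must be an increasing interval inside (0, 1)")
  th <- object@thresholds
  if (nrow(th) > 0L) {
    if (ncol(th) != 3L) msgs <- c(msgs, "thresholds must have 3 columns")
    if (any(th[, 2] <= th[, 1]) || any(th[, 3] <= th[, 2]))
      msgs <- c(msgs, "thresholds must be strictly increasing per item")
  }
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth sparse partial-correlation network
#'
#' The generating model of a synthetic data set: a positive-definite
#' precision matrix, the implied partial correlations
#' \eqn{w_{ij} = -\kappa_{ij}/\sqrt{\kappa_{ii}\kappa_{jj}}}, the
#' community membership of each node and the list of bridge edges
#' (edges crossing the two communities).
#'
#' @slot precision p x p symmetric positive-definite precision matrix.
#' @slot partialCorr p x p partial-correlation matrix, zero diagonal.
#' @slot communities character vector of node community labels.
#' @slot bridgeEdges integer matrix with two columns, one row per
#'   inter-community edge.
#' @export
setClass("GroundTruthNetwork",
  representation(precision = "matrix", partialCorr = "matrix",
                 communities = "character", bridgeEdges = "matrix"))

setValidity("GroundTruthNetwork", function(object) {
  K <- object@precision; W <- object@partialCorr
  msgs <- character()
  if (max(abs(K - t(K))) > 1e-8) msgs <- c(msgs, "precision must be symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) msgs <- c(msgs, "precision must be positive definite")
  if (max(abs(diag(W))) > 0) msgs <- c(msgs, "partialCorr diagonal must be zero")
  if (any(abs(W) >= 1)) msgs <- c(msgs, "partial correlations must lie in (-1, 1)")
  if (length(object@communities) != nrow(K))
    msgs <- c(msgs, "one community label per node is required")
  if (nrow(object@bridgeEdges) > 0L) {
    cc <- object@communities
    cross <- cc[object@bridgeEdges[, 1]] != cc[object@bridgeEdges[, 2]]
    if (!all(cross)) msgs <- c(msgs, "bridgeEdges must cross communities")
  }
  if (length(msgs)) msgs else TRUE
})

#' Estimated regularized partial-correlation network
#'
#' The result of graphical-lasso estimation with extended-BIC model
#' selection: the edge-weight matrix of regularized partial correlations,
#' the selected precision matrix, the penalty that produced it, and the
#' full regularization path used for selection.
#'
#' @slot weights p x p symmetric weight matrix with zero diagonal;
#'   \eqn{w_{ij} = -\hat\kappa_{ij}/\sqrt{\hat\kappa_{ii}\hat\kappa_{jj}}}.
#' @slot precision selected precision estimate \eqn{\hat K}.
#' @slot lambda selected penalty.
#' @slot gamma EBIC hyperparameter used for selection.
#' @slot path data.frame over the lambda grid: `lambda`, `edges`,
#'   `loglik`, `ebic`.
#' @slot communities node community labels.
#' @slot n sample size behind the correlation input.
#' @slot nodeNames node identifiers.
#' @export
setClass("SymptomNetwork",
  representation(weights = "matrix", precision = "matrix", lambda = "numeric",
                 gamma = "numeric", path = "data.frame",
                 communities = "character", n = "integer",
                 nodeNames = "character"))

setValidity("SymptomNetwork", function(object) {
  W <- object@weights
  msgs <- character()
  if (nrow(W) != ncol(W)) msgs <- c(msgs, "weights must be square")
  if (max(abs(W - t(W))) > 0) msgs <- c(msgs, "weights must be exactly symmetric")
  if (max(abs(diag(W))) > 0) msgs <- c(msgs, "weight diagonal must be zero")
  if (any(abs(W) >= 1)) msgs <- c(msgs, "|weights| must be < 1")
  if (length(object@communities) != nrow(W))
    msgs <- c(msgs, "one community label per node is required")
  if (length(object@nodeNames) != nrow(W))
    msgs <- c(msgs, "one name per node is required")
  if (length(msgs)) msgs else TRUE
})

#' Nonparametric bootstrap summary of an estimated network
#'
#' Replicate-level edge weights and centralities from resampling
#' respondents with replacement and re-estimating the network, plus
#' percentile confidence intervals per edge.
#'
#' @slot B number of bootstrap replicates requested.
#' @slot edges data.frame per unordered node pair: `node_a`, `node_b`,
#'   `estimate`, `bootMean`, `ciLower`, `ciUpper` (95\% percentile CI).
#' @slot edgeBoot replicates x pairs matrix of bootstrap edge weights.
#' @slot eiBoot replicates x nodes matrix of bootstrap expected influence.
#' @slot beiBoot replicates x nodes matrix of bootstrap bridge expected
#'   influence.
#' @slot failures number of replicates whose fit failed and were skipped.
#' @slot network the point-estimate [SymptomNetwork-class].
#' @export
setClass("BootstrapSummary",
  representation(B = "integer", edges = "data.frame", edgeBoot = "matrix",
                 eiBoot = "matrix", beiBoot = "matrix", failures = "integer",
                 network = "SymptomNetwork"))

setValidity("BootstrapSummary", function(object) {
  msgs <- character()
  if (object@B < 1L) msgs <- c(msgs, "B must be >= 1")
  if (any(object@edges$ciLower > object@edges$ciUpper))
    msgs <- c(msgs, "CI lower bounds must not exceed upper bounds")
  if (length(msgs)) msgs else TRUE
})

#' Case-dropping bootstrap stability of centrality indices
#'
#' For a grid of case-drop proportions, the distribution of correlations
#' between full-sample and subsample centralities, and the resulting
#' correlation-stability (CS) coefficient: the largest drop proportion at
#' which at least `probLevel` of the correlations stay at or above
#' `corThreshold`.
#'
#' @slot dropProportions the case-drop grid actually used.
#' @slot correlations named list (one element per statistic, e.g. "EI")
#'   of replicate x level correlation matrices.
#' @slot csCoefficient named numeric, CS coefficient per statistic.
#' @slot corThreshold correlation threshold (default 0.7).
#' @slot probLevel required probability (default 0.95).
#' @export
setClass("StabilityResult",
  representation(dropProportions = "numeric", correlations = "list",
                 csCoefficient = "numeric", corThreshold = "numeric",
                 probLevel = "numeric"))

setValidity("StabilityResult", function(object) {
  msgs <- character()
  bad <- !(object@csCoefficient %in% c(0, object@dropProportions))
  if (any(bad)) msgs <- c(msgs, "csCoefficient must lie in the grid or be 0")
  if (length(msgs)) msgs else TRUE
})
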