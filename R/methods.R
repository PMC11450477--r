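#' @rdname symnet-accessors
#' @export
setMethod("responseValues", "ResponseMatrix", function(object) object@values)

#' @rdname symnet-accessors
#' @export
setMethod("itemInfo", "ResponseMatrix", function(object) object@items)

#' @rdname symnet-accessors
#' @export
setMethod("respondentIds", "ResponseMatrix", function(object) object@respondentIds)

#' @rdname symnet-accessors
#' @export
setMethod("demographics", "ResponseMatrix", function(object) object@demographics)

#' @rdname symnet-accessors
#' @export
setMethod("nRespondents", "ResponseMatrix", function(object) nrow(object@values))

#' @rdname symnet-accessors
#' @export
setMethod("nItems", "ResponseMatrix", function(object) ncol(object@values))

#' @describeIn ResponseMatrix dimensions (respondents, items).
#' @param x a `ResponseMatrix`.
#' @export
setMethod("dim", "ResponseMatrix", function(x) dim(x@values))

#' @describeIn ResponseMatrix subset respondents (i) and/or items (j);
#'   items may be selected by `item_id`.
#' @param i,j row (respondent) and column (item) indices.
#' @param drop ignored; a `ResponseMatrix` is always returned.
#' @param ... unused.
#' @export
setMethod("[", "ResponseMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(j)) {
    jj <- match(j, x@items$item_id)
    if (anyNA(jj))
      stop("unknown item_id(s): ", paste(j[is.na(jj)], collapse = ", "))
    j <- jj
  }
  dg <- x@demographics
  if (nrow(dg) > 0L) dg <- dg[i, , drop = FALSE]
  new("ResponseMatrix",
      values = x@values[i, j, drop = FALSE],
      items = x@items[j, , drop = FALSE],
      respondentIds = x@respondentIds[i],
      demographics = dg)
})

setMethod("show", "ResponseMatrix", function(object) {
  sc <- table(object@items$scale)
  cat(sprintf("ResponseMatrix: %d respondents x %d items (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%s: %d", names(sc), sc), collapse = ", ")))
  if (ncol(object@demographics) > 0L)
    cat("  demographics:", paste(names(object@demographics), collapse = ", "), "\n")
})

#' @rdname symnet-accessors
#' @export
setMethod("prevalencePct", "ScreeningResult", function(object) object@prevalencePct)

#' @rdname symnet-accessors
#' @export
setMethod("totalScores", "ScreeningResult", function(object) object@totalScores)

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("%s screening (cut-off >= %d): %d / %d positive (%.2f%%)\n",
              object@scale, object@threshold, object@positives, object@n,
              object@prevalencePct))
})

#' @rdname symnet-accessors
#' @export
setMethod("corValues", "CorrelationMatrix", function(object) object@S)

#' @rdname symnet-accessors
#' @export
setMethod("sampleSize", "CorrelationMatrix", function(object) object@nUsed)

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix (Spearman): %d x %d, n = %d\n",
              nrow(object@S), ncol(object@S), object@nUsed))
})

#' @rdname symnet-accessors
#' @export
setMethod("edgeWeights", "SymptomNetwork", function(object) object@weights)

#' @rdname symnet-accessors
#' @export
setMethod("edgeWeights", "GroundTruthNetwork", function(object) object@partialCorr)

#' @rdname symnet-accessors
#' @export
setMethod("precisionMatrix", "SymptomNetwork", function(object) object@precision)

#' @rdname symnet-accessors
#' @export
setMethod("precisionMatrix", "GroundTruthNetwork", function(object) object@precision)

#' @rdname symnet-accessors
#' @export
setMethod("nodeCommunities", "SymptomNetwork", function(object) object@communities)

#' @rdname symnet-accessors
#' @export
setMethod("nodeCommunities", "GroundTruthNetwork", function(object) object@communities)

#' @rdname symnet-accessors
#' @export
setMethod("nodeNames", "SymptomNetwork", function(object) object@nodeNames)

#' @rdname symnet-accessors
#' @export
setMethod("bridgeEdges", "GroundTruthNetwork", function(object) object@bridgeEdges)

#' @rdname symnet-accessors
#' @export
setMethod("edgeCount", "SymptomNetwork",
          function(object) sum(object@weights[upper.tri(object@weights)] != 0))

#' @rdname symnet-accessors
#' @export
setMethod("edgeCount", "GroundTruthNetwork",
          function(object) sum(object@partialCorr[upper.tri(object@partialCorr)] != 0))

#' @rdname symnet-accessors
#' @export
setMethod("meanEdgeWeight", "SymptomNetwork", function(object) {
  w <- object@weights[upper.tri(object@weights)]
  w <- w[w != 0]
  if (!length(w)) return(0)
  mean(w)
})

#' @rdname symnet-accessors
#' @export
setMethod("regularizationPath", "SymptomNetwork", function(object) object@path)

setMethod("show", "SymptomNetwork", function(object) {
  e <- edgeCount(object)
  cat(sprintf("SymptomNetwork: %d nodes, %d nonzero edges\n",
              nrow(object@weights), e))
  cat(sprintf("  lambda = %.4g (EBIC gamma = %.2f), n = %d\n",
              object@lambda, object@gamma, object@n))
  if (e > 0)
    cat(sprintf("  mean nonzero edge weight = %.3f\n", meanEdgeWeight(object)))
})

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf("GroundTruthNetwork: %d nodes, %d edges (%d bridges)\n",
              nrow(object@precision), edgeCount(object), nrow(object@bridgeEdges)))
})

setMethod("show", "BootstrapSummary", function(object) {
  cat(sprintf("BootstrapSummary: B = %d (%d failed), %d edges\n",
              object@B, object@failures, nrow(object@edges)))
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult (case-dropping bootstrap)\n")
  cs <- object@csCoefficient
  for (s in names(cs))
    cat(sprintf("  CS(%s) = %.2f  (cor >= %.2f in >= %.0f%% of subsamples)\n",
                s, cs[[s]], object@corThreshold, 100 * object@probLevel))
})

#' @rdname csCoefficient
#' @export
setMethod("csCoefficient", "StabilityResult",
  function(object, corThreshold = NULL, probLevel = NULL) {
    if (is.null(corThreshold)) corThreshold <- object@corThreshold
    if (is.null(probLevel)) probLevel <- object@probLevel
    vapply(object@correlations, function(m) {
      ok <- apply(m, 2L, function(col) {
        col <- col[!is.na(col)]
        if (!length(col)) return(FALSE)
        mean(col >= corThreshold) >= probLevel
      })
      # contiguous run from the smallest drop proportion upward
      run <- cumprod(ok) == 1
      if (!any(run)) 0 else max(object@dropProportions[run])
    }, numeric(1))
  })
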