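#' Spearman correlation matrix of all items
#'
#' Pairwise Spearman rank correlations (average ranks for ties) over all
#' item columns.  Ordinal 0--3 Likert items are heavily tied, which
#' average ranking handles; a constant column has no defined rank
#' correlation and is an error naming the item.
#'
#' @param rm a [ResponseMatrix-class].
#' @return a [CorrelationMatrix-class].
#' @export
spearmanMatrix <- function(rm) {
  v <- responseValues(rm)
  nd <- apply(v, 2L, function(x) length(unique(x)))
  if (any(nd < 2L))
    stop("constant column(s), Spearman correlation undefined: ",
         paste(itemInfo(rm)$item_id[nd < 2L], collapse = ", "))
  S <- stats::cor(v, method = "spearman")
  S <- (S + t(S)) / 2
  diag(S) <- 1
  new("CorrelationMatrix", S = S, nUsed = nrow(v))
}

# two-sided p-value for a Spearman coefficient via the t approximation
.spearmanP <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Correlations of somatic items with the depression and anxiety totals
#'
#' Spearman correlations of every somatic item (plus the somatic total
#' score) with the PHQ-2 total (depression) and the GAD-7 total
#' (anxiety), with two-sided p-values from the t approximation.  No
#' multiplicity correction is applied.
#'
#' @param rm a [ResponseMatrix-class] containing the somatic, GAD-7 and
#'   PHQ-2 items.
#' @return data.frame with one row per somatic item plus a leading
#'   `total` row; columns `item_id`, `label`, `r_depression`,
#'   `p_depression`, `r_anxiety`, `p_anxiety`.
#' @export
scaleCorrelations <- function(rm) {
  dep <- scaleTotal(rm, "PHQ2")
  anx <- scaleTotal(rm, "GAD7")
  items <- itemInfo(rm)
  som <- items$item_id[items$scale == "somatic"]
  v <- responseValues(rm)
  n <- nrow(v)
  cols <- cbind(`total` = rowSums(v[, som, drop = FALSE]),
                v[, som, drop = FALSE])
  rd <- apply(cols, 2L, function(x) stats::cor(x, dep, method = "spearman"))
  ra <- apply(cols, 2L, function(x) stats::cor(x, anx, method = "spearman"))
  data.frame(
    item_id = c("total", som),
    label = c("somatic total score", items$label[match(som, items$item_id)]),
    r_depression = unname(rd), p_depression = unname(.spearmanP(rd, n)),
    r_anxiety = unname(ra), p_anxiety = unname(.spearmanP(ra, n)),
    stringsAsFactors = FALSE)
}

#' Published reference scale-correlation table
#'
#' The Spearman correlations of 30 somatic symptoms (and the somatic
#' total) with the depression and anxiety screener totals reported for
#' the survey of 665 students the package models; the input the standard
#' item-selection rule reproduces its 11-item network node set from.
#'
#' @return data.frame with columns `item_id`, `label`, `r_depression`,
#'   `r_anxiety`.
#' @export
referenceScaleCorrelations <- function() {
  path <- system.file("extdata", "reference_scale_correlations.csv",
                      package = "symnet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Select somatic items for the network
#'
#' Retains the somatic items whose correlation with either screener
#' total reaches the cutoff: `max(r_depression, r_anxiety) >= cutoff`
#' (inclusive, so a coefficient printed exactly at the cutoff is kept).
#' The network node set is the retained somatic items plus all GAD-7 and
#' PHQ-2 items.
#'
#' @param tbl a scale-correlation table as returned by
#'   [scaleCorrelations()] or [referenceScaleCorrelations()]; rows with
#'   `item_id == "total"` are ignored.
#' @param cutoff inclusion threshold in (0, 1), default 0.5.
#' @return character vector of retained somatic `item_id`s, in table
#'   order.
#' @export
selectNetworkItems <- function(tbl, cutoff = 0.5) {
  .assertScalarNumber(cutoff, "cutoff", 0, 1)
  tbl <- tbl[tbl$item_id != "total", , drop = FALSE]
  keep <- pmax(tbl$r_depression, tbl$r_anxiety) >= cutoff
  if (!any(keep))
    warning("no somatic item reaches the cutoff; ",
            "the network will contain psychological items only")
  tbl$item_id[keep]
}

#' Nearest positive-definite correlation matrix
#'
#' Spearman matrices of discrete data can be indefinite, while the
#' graphical lasso requires a positive-definite input.  If the smallest
#' eigenvalue is below 1e-6, eigenvalues are clipped at 1e-6, the matrix
#' reconstructed and re-standardized to unit diagonal; otherwise the
#' input is returned unchanged.
#'
#' @param S a [CorrelationMatrix-class] or a plain symmetric matrix.
#' @return object of the same type as the input, positive definite.
#' @export
nearestPositiveDefinite <- function(S) {
  isCM <- is(S, "CorrelationMatrix")
  M <- if (isCM) corValues(S) else S
  stopifnot(isSymmetric(unname(M), tol = 1e-8))
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) >= 1e-6) return(S)
  M2 <- M
  # re-standardization can push the smallest eigenvalue back under the
  # floor, so clip with headroom and iterate until it holds
  for (it in 1:100) {
    e <- eigen((M2 + t(M2)) / 2, symmetric = TRUE)
    if (min(e$values) >= 1e-6) break
    ev <- pmax(e$values, 2e-6)
    M2 <- e$vectors %*% (ev * t(e$vectors))
    M2 <- stats::cov2cor((M2 + t(M2)) / 2)
  }
  dimnames(M2) <- dimnames(M)
  if (isCM) new("CorrelationMatrix", S = M2, nUsed = sampleSize(S)) else M2
}
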