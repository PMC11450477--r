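#' Default item catalog of the psychosomatic survey
#'
#' The 39-item catalog the package is built around: 30 somatic symptoms
#' (S1--S30) from a health-status inventory, the 7 GAD-7 anxiety items
#' (G1--G7) and the 2 PHQ-2 depression items (P1, P2).  Every item is
#' scored 0--3 (none / occasional / sometimes / frequent).  Somatic items
#' belong to the `somatic` community, GAD-7 and PHQ-2 items to the
#' `anxiety_depression` community.
#'
#' @return data.frame with columns `item_id`, `label`, `scale`,
#'   `community`.
#' @examples
#' head(defaultItemCatalog())
#' @export
defaultItemCatalog <- function() {
  path <- system.file("extdata", "item_catalog.csv", package = "symnet",
                      mustWork = TRUE)
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(length(.checkItemCatalog(items)) == 0L)
  items
}

#' Published reference moments of the 20 network items
#'
#' Item means and standard deviations (on the 0--3 scale) reported for
#' the 11 selected somatic symptoms and the 9 anxiety/depression items in
#' the survey of 665 students the package models.  Used as the default
#' calibration target of the synthetic-data generator.
#'
#' @return data.frame with columns `item_id`, `label`, `community`,
#'   `mean`, `sd`.
#' @export
referenceItemMoments <- function() {
  path <- system.file("extdata", "reference_item_moments.csv",
                      package = "symnet", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Construct a ResponseMatrix
#'
#' @param values numeric/integer matrix or data.frame of item responses,
#'   respondents in rows, entries in 0..3.
#' @param items item catalog (data.frame with `item_id`, `label`,
#'   `scale`, `community`); defaults to the columns of `values` looked up
#'   in [defaultItemCatalog()].
#' @param respondentIds optional respondent identifiers.
#' @param demographics optional data.frame of pass-through covariates.
#' @return a validated [ResponseMatrix-class].
#' @export
responseMatrix <- function(values, items = NULL, respondentIds = NULL,
                           demographics = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(items)) {
    cat <- defaultItemCatalog()
    idx <- match(colnames(values), cat$item_id)
    if (anyNA(idx))
      stop("columns not in the default catalog: ",
           paste(colnames(values)[is.na(idx)], collapse = ", "))
    items <- cat[idx, , drop = FALSE]
  }
  rownames(items) <- NULL
  colnames(values) <- items$item_id
  if (is.null(respondentIds)) respondentIds <- as.character(seq_len(nrow(values)))
  if (is.null(demographics)) demographics <- data.frame()
  new("ResponseMatrix", values = values, items = items,
      respondentIds = as.character(respondentIds), demographics = demographics)
}

#' Read and validate questionnaire responses from CSV
#'
#' Expects a tidy CSV, one row per respondent, one integer-coded column
#' per item in the catalog.  Columns named in `demographicCols` are kept
#' aside as pass-through covariates; any other column not in the catalog
#' is an error.  Rows with a missing or out-of-range entry in any item
#' column are dropped listwise and the number of dropped rows is
#' reported.
#'
#' @param path CSV file path.
#' @param items item catalog; default [defaultItemCatalog()].
#' @param demographicCols column names tolerated (and retained) besides
#'   the items, e.g. `c("sex", "age", "degree")`.
#' @param idCol optional name of a respondent-id column.
#' @return a validated [ResponseMatrix-class].
#' @export
loadResponses <- function(path, items = defaultItemCatalog(),
                          demographicCols = c("sex", "age", "degree"),
                          idCol = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  known <- c(items$item_id, demographicCols, idCol)
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    stop("unknown column(s) not in the item catalog: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(items$item_id, names(df))
  if (length(missing))
    stop("required item column(s) missing: ", paste(missing, collapse = ", "))

  vals <- as.matrix(df[, items$item_id, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "integer")
  ok <- rowSums(is.na(vals) | vals < 0L | vals > 3L) == 0L
  dropped <- sum(!ok)
  if (dropped > 0L)
    message(sprintf("dropped %d row(s) with missing or out-of-range responses",
                    dropped))
  if (!any(ok)) stop("no rows survive validation")

  ids <- if (!is.null(idCol)) as.character(df[[idCol]][ok]) else
    as.character(which(ok))
  demo <- df[ok, intersect(demographicCols, names(df)), drop = FALSE]
  rownames(demo) <- NULL
  responseMatrix(vals[ok, , drop = FALSE], items = items,
                 respondentIds = ids, demographics = demo)
}

.scaleItems <- function(rm, scale) {
  scale <- match.arg(scale, .SCALES)
  ids <- itemInfo(rm)$item_id[itemInfo(rm)$scale == scale]
  if (!length(ids)) stop("no items of scale '", scale, "' present")
  ids
}

#' Per-respondent total score of a scale
#'
#' Sums the item scores of one scale for every respondent (range 0--21
#' for GAD-7, 0--6 for PHQ-2).
#'
#' @param rm a [ResponseMatrix-class].
#' @param scale one of `"GAD7"`, `"PHQ2"`, `"somatic"`.
#' @return integer vector of per-respondent totals.
#' @export
scaleTotal <- function(rm, scale) {
  ids <- .scaleItems(rm, scale)
  n_expected <- c(GAD7 = 7L, PHQ2 = 2L)
  if (scale %in% names(n_expected) && length(ids) != n_expected[[scale]])
    stop(sprintf("scale %s requires %d items, found %d", scale,
                 n_expected[[scale]], length(ids)))
  as.integer(rowSums(responseValues(rm)[, ids, drop = FALSE]))
}

#' Screening prevalence of anxiety or depression
#'
#' Counts respondents at or above the scale's screening cut-off
#' (GAD-7 total >= 5 indicates an anxiety state; PHQ-2 total >= 2
#' suggests depression) and reports the percentage, rounded half-up to
#' two decimals.
#'
#' @param rm a [ResponseMatrix-class].
#' @param scale `"GAD7"` or `"PHQ2"`.
#' @param threshold screening cut-off; defaults to the scale's standard
#'   value (5 for GAD-7, 2 for PHQ-2).
#' @return a [ScreeningResult-class].
#' @export
screeningPrevalence <- function(rm, scale, threshold = NULL) {
  scale <- match.arg(scale, c("GAD7", "PHQ2"))
  if (is.null(threshold)) threshold <- c(GAD7 = 5L, PHQ2 = 2L)[[scale]]
  tot <- scaleTotal(rm, scale)
  pos <- sum(tot >= threshold)
  n <- length(tot)
  new("ScreeningResult", scale = scale, threshold = as.integer(threshold),
      totalScores = tot, positives = as.integer(pos),
      prevalencePct = roundHalfUp(100 * pos / n, 2), n = as.integer(n))
}

#' Endorsement frequency and descriptives per item
#'
#' For each item, the percentage of respondents endorsing it -- scoring
#' at or above `endorseAt` (default 1, i.e. "occasional" or more, the
#' only non-endorsement level being "none" = 0) -- together with the item
#' mean and sample standard deviation.
#'
#' @param rm a [ResponseMatrix-class].
#' @param scale restrict to one scale (default `"somatic"`); `NULL` for
#'   all items.
#' @param endorseAt minimal score counting as endorsement.
#' @return data.frame with columns `item_id`, `label`, `frequency_pct`,
#'   `mean`, `sd`, sorted by decreasing frequency.
#' @export
symptomFrequency <- function(rm, scale = "somatic", endorseAt = 1L) {
  items <- itemInfo(rm)
  keep <- if (is.null(scale)) rep(TRUE, nrow(items)) else items$scale == scale
  v <- responseValues(rm)[, keep, drop = FALSE]
  n <- nrow(v)
  out <- data.frame(
    item_id = items$item_id[keep],
    label = items$label[keep],
    frequency_pct = roundHalfUp(100 * colMeans(v >= endorseAt), 2),
    mean = colMeans(v),
    sd = apply(v, 2L, stats::sd),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$frequency_pct, out$item_id), ]
}

#' Cronbach's alpha internal consistency
#'
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i \sigma^2_i}
#'   {\sigma^2_{total}}\right)}
#' with sample variances (n - 1 denominator).
#'
#' @param rm a [ResponseMatrix-class].
#' @param itemIds items forming the scale (>= 2); defaults to all items.
#' @return alpha as a single numeric value.
#' @export
cronbachAlpha <- function(rm, itemIds = itemInfo(rm)$item_id) {
  v <- responseValues(rm)[, itemIds, drop = FALSE]
  k <- ncol(v)
  if (k < 2L) stop("Cronbach's alpha requires at least 2 items")
  if (nrow(v) < 2L) stop("Cronbach's alpha requires at least 2 respondents")
  vt <- stats::var(rowSums(v))
  if (vt == 0) stop("total-score variance is zero; alpha undefined")
  k / (k - 1) * (1 - sum(apply(v, 2L, stats::var)) / vt)
}

#' Summarize pass-through demographic covariates
#'
#' Categorical columns are tabulated as counts with component ratios
#' (percentages rounded half-up to two decimals); numeric columns are
#' summarized as mean and sample SD.  Demographics are descriptive only
#' and never enter network estimation.
#'
#' @param demo data.frame of covariates (e.g. `demographics(rm)`).
#' @return list with elements `categorical` (data.frame: `variable`,
#'   `level`, `count`, `pct`) and `numeric` (data.frame: `variable`,
#'   `mean`, `sd`).
#' @export
summarizeDemographics <- function(demo) {
  cats <- data.frame(variable = character(), level = character(),
                     count = integer(), pct = numeric(),
                     stringsAsFactors = FALSE)
  nums <- data.frame(variable = character(), mean = numeric(), sd = numeric(),
                     stringsAsFactors = FALSE)
  n <- nrow(demo)
  for (nm in names(demo)) {
    x <- demo[[nm]]
    if (is.numeric(x)) {
      nums <- rbind(nums, data.frame(variable = nm, mean = mean(x),
                                     sd = stats::sd(x)))
    } else {
      tb <- table(x)
      cats <- rbind(cats, data.frame(
        variable = nm, level = names(tb), count = as.integer(tb),
        pct = roundHalfUp(100 * as.integer(tb) / n, 2)))
    }
  }
  rownames(cats) <- rownames(nums) <- NULL
  list(categorical = cats, numeric = nums)
}
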