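#' Full-analysis configuration
#'
#' One object holding every setting of the end-to-end analysis.  Exactly
#' one of `input` (a responses CSV) or `synthetic` (a
#' [SyntheticSpec-class]) must be given.  Defaults follow the standard
#' settings of the methodology the package implements: item-selection
#' cutoff 0.5, EBIC gamma 0.5, alpha 0.05, B = 1000 bootstrap samples.
#'
#' @param input path to a responses CSV (see [loadResponses()]), or NULL.
#' @param synthetic a [SyntheticSpec-class], or NULL.
#' @param items item catalog for CSV input.
#' @param cutoff somatic item-selection cutoff.
#' @param gamma,nLambda,lambdaMinRatio network-estimation settings.
#' @param B nonparametric bootstrap samples (0 disables the bootstrap
#'   stages).
#' @param BPerLevel case-dropping subsamples per level (0 disables the
#'   stability stage).
#' @param alpha significance level of the difference tests.
#' @param seed master seed for every stochastic stage.
#' @param outputDir optional directory; when set, [runPipeline()] writes
#'   all report tables there.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(input = NULL, synthetic = NULL,
                           items = defaultItemCatalog(), cutoff = 0.5,
                           gamma = 0.5, nLambda = 100L,
                           lambdaMinRatio = 0.01, B = 1000L,
                           BPerLevel = 250L, alpha = 0.05, seed = 1L,
                           outputDir = NULL) {
  if (is.null(input) == is.null(synthetic))
    stop("exactly one of 'input' or 'synthetic' must be supplied")
  structure(list(input = input, synthetic = synthetic, items = items,
                 cutoff = cutoff,
                 network = networkConfig(gamma = gamma, nLambda = nLambda,
                                         lambdaMinRatio = lambdaMinRatio),
                 B = as.integer(B), BPerLevel = as.integer(BPerLevel),
                 alpha = alpha, seed = as.integer(seed),
                 outputDir = outputDir),
            class = "pipelineConfig")
}

#' Summary block of an estimated network
#'
#' Counts nonzero unordered edges, their mean/min/max weight, the number
#' and percentage of bridging edges (edges crossing the two
#' communities), and the three largest-magnitude bridging edges.  An
#' empty network reports a bridging percentage of 0 with a note.
#'
#' @param net a [SymptomNetwork-class].
#' @return list with elements `edgeCount`, `meanWeight`, `minWeight`,
#'   `maxWeight`, `bridgingCount`, `bridgingPct`, `topBridges`
#'   (data.frame), `note`.
#' @export
summarizeNetwork <- function(net) {
  w <- edgeWeights(net)
  comm <- nodeCommunities(net)
  ij <- .pairIndices(ncol(w))
  wv <- w[ij]
  nz <- wv != 0
  bridge <- nz & (comm[ij[, 1]] != comm[ij[, 2]])
  note <- NULL
  if (!any(nz)) {
    note <- "network has no edges; bridging percentage reported as 0"
    pct <- 0
  } else {
    pct <- roundHalfUp(100 * sum(bridge) / sum(nz), 2)
  }
  bi <- which(bridge)
  bi <- bi[order(-abs(wv[bi]))][seq_len(min(3L, length(bi)))]
  topBridges <- data.frame(node_a = nodeNames(net)[ij[bi, 1]],
                           node_b = nodeNames(net)[ij[bi, 2]],
                           weight = wv[bi], stringsAsFactors = FALSE)
  list(edgeCount = sum(nz),
       meanWeight = if (any(nz)) mean(wv[nz]) else 0,
       minWeight = if (any(nz)) min(wv[nz]) else 0,
       maxWeight = if (any(nz)) max(wv[nz]) else 0,
       bridgingCount = sum(bridge), bridgingPct = pct,
       topBridges = topBridges, note = note)
}

.stageLog <- function(log, stage, t0, ...) {
  info <- list(...)
  msg <- sprintf("[%s] %.2fs%s", stage, as.numeric(Sys.time()) - t0,
                 if (length(info))
                   paste0(" (", paste(names(info), unlist(info), sep = "=",
                                      collapse = ", "), ")") else "")
  message(msg)
  rbind(log, data.frame(stage = stage,
                        seconds = as.numeric(Sys.time()) - t0,
                        stringsAsFactors = FALSE))
}

#' Run the complete psychosomatic network analysis
#'
#' Executes, in order: data loading (or synthetic generation), screening
#' prevalence, symptom frequencies, scale correlations, somatic item
#' selection, network estimation (Spearman, positive-definite repair,
#' EBIC-selected graphical lasso), centralities and predictability,
#' layout, network summary, and -- when enabled -- the nonparametric
#' bootstrap with difference tests and the case-dropping stability
#' bootstrap.  Every stage logs its timing to the console.
#'
#' @param cfg a [pipelineConfig()].
#' @return list of class `analysisReport` with elements `demographics`,
#'   `screening`, `frequency`, `scaleCorrelations`, `selectedItems`,
#'   `network`, `summary`, `centrality`, `layout`, `bootstrap`,
#'   `differences`, `stability`, `groundTruth` (synthetic runs only),
#'   `config`, `timings`.  Written to `outputDir` via [writeReport()]
#'   when configured.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  log <- data.frame(stage = character(), seconds = numeric())
  t0 <- as.numeric(Sys.time())
  gt <- NULL
  if (!is.null(cfg$synthetic)) {
    gt <- buildGroundTruth(cfg$synthetic)
    rm <- sampleOrdinal(gt, cfg$synthetic, seed = .subSeed(cfg$seed, 1L))
  } else {
    rm <- loadResponses(cfg$input, items = cfg$items)
  }
  log <- .stageLog(log, "load", t0, n = nRespondents(rm), p = nItems(rm))

  t0 <- as.numeric(Sys.time())
  demo <- summarizeDemographics(demographics(rm))
  screening <- list(GAD7 = screeningPrevalence(rm, "GAD7"),
                    PHQ2 = screeningPrevalence(rm, "PHQ2"))
  freq <- symptomFrequency(rm)
  log <- .stageLog(log, "descriptives", t0)

  t0 <- as.numeric(Sys.time())
  sc <- scaleCorrelations(rm)
  selected <- selectNetworkItems(sc, cutoff = cfg$cutoff)
  items <- itemInfo(rm)
  nodeSet <- c(selected,
               items$item_id[items$scale %in% c("GAD7", "PHQ2")])
  rmNet <- rm[, nodeSet]
  log <- .stageLog(log, "item-selection", t0, retained = length(selected))

  t0 <- as.numeric(Sys.time())
  net <- estimateNetwork(rmNet, cfg$network)
  summ <- summarizeNetwork(net)
  log <- .stageLog(log, "network", t0, edges = summ$edgeCount)

  t0 <- as.numeric(Sys.time())
  cent <- centralityTable(net, rmNet)
  layout <- frLayout(net, seed = .subSeed(cfg$seed, 2L))
  log <- .stageLog(log, "centrality", t0)

  boot <- diffs <- stab <- NULL
  if (cfg$B > 0L) {
    t0 <- as.numeric(Sys.time())
    boot <- bootstrapEdges(rmNet, cfg$network, B = cfg$B,
                           seed = .subSeed(cfg$seed, 3L))
    diffs <- list(edge = differenceTest(boot, "edge", cfg$alpha),
                  EI = differenceTest(boot, "EI", cfg$alpha),
                  BEI = differenceTest(boot, "BEI", cfg$alpha))
    log <- .stageLog(log, "bootstrap", t0, B = cfg$B)
  }
  if (cfg$BPerLevel > 0L) {
    t0 <- as.numeric(Sys.time())
    stab <- caseDroppingBootstrap(rmNet, cfg$network,
                                  BPerLevel = cfg$BPerLevel,
                                  seed = .subSeed(cfg$seed, 4L))
    log <- .stageLog(log, "stability", t0,
                     csEI = csCoefficient(stab)[["EI"]])
  }

  report <- structure(list(
    demographics = demo, screening = screening, frequency = freq,
    scaleCorrelations = sc, selectedItems = selected, network = net,
    summary = summ, centrality = cent, layout = layout, bootstrap = boot,
    differences = diffs, stability = stab, groundTruth = gt,
    responses = rm, config = cfg, timings = log),
    class = "analysisReport")
  if (!is.null(cfg$outputDir)) writeReport(report, cfg$outputDir)
  report
}

#' @export
print.analysisReport <- function(x, ...) {
  cat("Psychosomatic symptom network analysis\n")
  cat(sprintf("  n = %d respondents\n", nRespondents(x$responses)))
  for (s in names(x$screening))
    cat(sprintf("  %s positive: %d (%.2f%%)\n", s, x$screening[[s]]@positives,
                prevalencePct(x$screening[[s]])))
  cat(sprintf("  network: %d nodes, %d edges (mean weight %.3f)\n",
              length(nodeNames(x$network)), x$summary$edgeCount,
              x$summary$meanWeight))
  cat(sprintf("  bridging edges: %d (%.2f%%)\n", x$summary$bridgingCount,
              x$summary$bridgingPct))
  if (!is.null(x$stability)) {
    cs <- csCoefficient(x$stability)
    cat(sprintf("  CS coefficients: %s\n",
                paste(sprintf("%s=%.2f", names(cs), cs), collapse = ", ")))
  }
  invisible(x)
}

#' Write all report tables of a pipeline run
#'
#' Writes the screening, frequency, correlation, centrality, network
#' (weight matrix and edge list), bootstrap, stability and difference
#' tables as labeled CSV files, plus a YAML manifest of the
#' configuration and seed sufficient to reproduce the run.
#'
#' @param report an `analysisReport` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    name
  }
  files <- character()
  scr <- do.call(rbind, lapply(report$screening, function(s)
    data.frame(scale = s@scale, threshold = s@threshold,
               positives = s@positives, n = s@n,
               prevalence_pct = prevalencePct(s))))
  files <- c(files, wcsv(scr, "screening.csv"))
  files <- c(files, wcsv(report$frequency, "symptom_frequency.csv"))
  files <- c(files, wcsv(report$scaleCorrelations, "scale_correlations.csv"))
  files <- c(files, wcsv(report$centrality, "centrality.csv"))

  w <- edgeWeights(report$network)
  files <- c(files, wcsv(cbind(node = rownames(w), as.data.frame(w)),
                         "weight_matrix.csv"))
  ij <- .pairIndices(ncol(w))
  comm <- nodeCommunities(report$network)
  nz <- ij[w[ij] != 0, , drop = FALSE]
  el <- data.frame(node_a = rownames(w)[nz[, 1]],
                   node_b = rownames(w)[nz[, 2]], weight = w[nz],
                   is_bridge = comm[nz[, 1]] != comm[nz[, 2]])
  files <- c(files, wcsv(el, "edge_list.csv"))
  files <- c(files, wcsv(regularizationPath(report$network), "lambda_path.csv"))
  files <- c(files, wcsv(cbind(node = rownames(report$layout),
                               as.data.frame(report$layout)), "layout.csv"))
  if (!is.null(report$bootstrap))
    files <- c(files, wcsv(report$bootstrap@edges, "edge_bootstrap.csv"))
  if (!is.null(report$stability)) {
    st <- report$stability
    curves <- do.call(rbind, lapply(names(st@correlations), function(s) {
      m <- st@correlations[[s]]
      data.frame(statistic = s, drop = st@dropProportions,
                 meanCor = colMeans(m, na.rm = TRUE),
                 q05 = apply(m, 2L, stats::quantile, probs = 0.05,
                             na.rm = TRUE, names = FALSE))
    }))
    files <- c(files, wcsv(curves, "stability_curves.csv"))
  }
  if (!is.null(report$differences))
    for (s in names(report$differences))
      files <- c(files, wcsv(
        cbind(id = rownames(report$differences[[s]]),
              as.data.frame(report$differences[[s]])),
        sprintf("difference_%s.csv", s)))
  cfg <- report$config
  yaml::write_yaml(list(
    seed = cfg$seed, cutoff = cfg$cutoff, gamma = cfg$network$gamma,
    nLambda = cfg$network$nLambda, lambdaMinRatio = cfg$network$lambdaMinRatio,
    B = cfg$B, BPerLevel = cfg$BPerLevel, alpha = cfg$alpha,
    input = if (is.null(cfg$input)) "synthetic" else cfg$input),
    file.path(dir, "manifest.yaml"))
  invisible(c(files, "manifest.yaml"))
}
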