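# catalog rows inferred from item-id prefixes (S* somatic, G* GAD-7, P* PHQ-2)
toyCatalog <- function(ids) {
  scale <- ifelse(startsWith(ids, "G"), "GAD7",
                  ifelse(startsWith(ids, "P"), "PHQ2", "somatic"))
  data.frame(item_id = ids, label = ids, scale = scale,
             community = ifelse(scale == "somatic", "somatic",
                                "anxiety_depression"),
             stringsAsFactors = FALSE)
}

rmFromValues <- function(values, ids = colnames(values)) {
  colnames(values) <- ids
  responseMatrix(values, items = toyCatalog(ids))
}

randomResponses <- function(n, ids, seed = 1) {
  set.seed(seed)
  rmFromValues(matrix(sample(0:3, n * length(ids), replace = TRUE), n),
               ids = ids)
}

# a SymptomNetwork straight from a weight matrix (no estimation)
makeNet <- function(W, communities, n = 100L, nodeNames = NULL) {
  p <- ncol(W)
  if (is.null(nodeNames)) nodeNames <- colnames(W)
  if (is.null(nodeNames)) nodeNames <- paste0("V", seq_len(p))
  dimnames(W) <- list(nodeNames, nodeNames)
  new("SymptomNetwork", weights = W, precision = diag(p), lambda = 0.1,
      gamma = 0.5, path = data.frame(), communities = communities,
      n = as.integer(n), nodeNames = nodeNames)
}

randomWeights <- function(p, density = 0.3, seed = 1, wmax = 0.4) {
  set.seed(seed)
  W <- matrix(0, p, p)
  ij <- which(upper.tri(W), arr.ind = TRUE)
  on <- runif(nrow(ij)) < density
  w <- runif(nrow(ij), -wmax, wmax) * on
  W[ij] <- w
  W + t(W)
}

# support-recovery rates of an estimated network against ground truth
recoveryRates <- function(net, gt) {
  ut <- upper.tri(edgeWeights(gt))
  true <- edgeWeights(gt)[ut] != 0
  est <- edgeWeights(net)[ut] != 0
  c(sensitivity = sum(est & true) / max(sum(true), 1L),
    specificity = sum(!est & !true) / max(sum(!true), 1L))
}
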