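#' Graphical lasso fit at a single penalty
#'
#' L1-penalized Gaussian maximum-likelihood estimation of a sparse
#' precision matrix by blockwise coordinate descent.  The diagonal is
#' not penalized (the convention of the regularized partial-correlation
#' network literature), so the fitted covariance keeps the input
#' diagonal.  At `lambda = 0` the unpenalized MLE, i.e. the inverse of
#' `S`, is returned directly.
#'
#' @param S positive-definite correlation (or covariance) matrix, e.g.
#'   after [nearestPositiveDefinite()].
#' @param lambda nonnegative penalty on off-diagonal precision entries.
#' @param tol parameter-change convergence tolerance (relative to the
#'   mean absolute off-diagonal of `S`), default 1e-5.
#' @param maxit maximum number of outer sweeps per fit, default 500.
#' @return the precision estimate \eqn{\hat K} (exact zeros where the
#'   lasso deactivates an entry), with the fitted covariance in
#'   attribute `"W"` and the sweep count in attribute `"iterations"`.
#' @export
glassoFit <- function(S, lambda, tol = 1e-5, maxit = 500L) {
  if (is(S, "CorrelationMatrix")) S <- corValues(S)
  .assertScalarNumber(lambda, "lambda", 0)
  if (lambda < 1e-12) {
    K <- chol2inv(chol(S))
    dimnames(K) <- dimnames(S)
    attr(K, "W") <- S
    attr(K, "iterations") <- 0L
    return(K)
  }
  fit <- .glasso_cd(unname(S), lambda, tol, as.integer(maxit))
  if (!fit$converged)
    stop(sprintf("glasso did not converge at lambda = %.4g within %d iterations",
                 lambda, fit$iterations))
  K <- fit$K
  dimnames(K) <- dimnames(S)
  attr(K, "W") <- fit$W
  attr(K, "iterations") <- fit$iterations
  K
}

#' Maximal KKT residual of a glasso solution
#'
#' Stationarity of the penalized likelihood requires, with
#' \eqn{W = \hat K^{-1}}: \eqn{W_{ij} - S_{ij} = \lambda\,
#' \mathrm{sign}(\hat\kappa_{ij})} on active off-diagonal entries,
#' \eqn{|W_{ij} - S_{ij}| \le \lambda} on inactive ones, and
#' \eqn{W_{jj} = S_{jj}} on the (unpenalized) diagonal.
#'
#' @param K precision estimate from [glassoFit()].
#' @param S the input matrix.
#' @param lambda the penalty used.
#' @return the largest absolute violation over all entries.
#' @export
glassoKKT <- function(K, S, lambda) {
  if (is(S, "CorrelationMatrix")) S <- corValues(S)
  W <- attr(K, "W")
  if (is.null(W)) W <- solve(K)
  D <- W - S
  p <- ncol(S)
  off <- upper.tri(S) | lower.tri(S)
  act <- off & (K != 0)
  inact <- off & (K == 0)
  viol <- abs(diag(D))
  if (any(act)) viol <- c(viol, abs(D[act] - lambda * sign(-K[act]) * -1))
  if (any(inact)) viol <- c(viol, pmax(abs(D[inact]) - lambda, 0))
  max(viol)
}

#' Extended Bayesian information criterion of a precision estimate
#'
#' \deqn{\mathrm{EBIC} = -2\,l(\hat K) + E \log n + 4 E \gamma \log p}
#' with Gaussian log-likelihood
#' \eqn{l = (n/2)(\log\det \hat K - \mathrm{tr}(S \hat K))} and
#' \eqn{E} the number of nonzero off-diagonal entries in one triangle.
#' `gamma = 0` recovers the ordinary BIC; larger values prefer sparser
#' models.
#'
#' @param K positive-definite precision estimate.
#' @param S the correlation matrix the model was fitted to.
#' @param n sample size.
#' @param gamma EBIC hyperparameter, typically 0.5.
#' @return the EBIC value.
#' @export
ebicScore <- function(K, S, n, gamma = 0.5) {
  if (is(S, "CorrelationMatrix")) S <- corValues(S)
  ch <- tryCatch(chol(K), error = function(e)
    stop("precision estimate is not positive definite; log det undefined"))
  p <- ncol(K)
  E <- sum(K[upper.tri(K)] != 0)
  ll <- (n / 2) * (2 * sum(log(diag(ch))) - sum(S * K))
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

#' EBIC-selected graphical lasso network
#'
#' Fits the graphical lasso over a decreasing log-spaced penalty grid
#' (from the largest absolute off-diagonal correlation down to
#' `lambdaMinRatio` times it) and selects the penalty minimizing the
#' extended BIC at hyperparameter `gamma`.  The selected precision
#' matrix is converted to the edge-weight matrix of regularized partial
#' correlations
#' \eqn{w_{ij} = -\hat\kappa_{ij}/\sqrt{\hat\kappa_{ii}\hat\kappa_{jj}}}.
#' EBIC ties are broken toward the larger penalty (sparser model).
#'
#' @param S a [CorrelationMatrix-class] or positive-definite correlation
#'   matrix (apply [nearestPositiveDefinite()] first if in doubt).
#' @param n sample size behind `S` (taken from a `CorrelationMatrix`
#'   automatically).
#' @param gamma EBIC hyperparameter, default 0.5.
#' @param nLambda grid size, default 100.
#' @param lambdaMinRatio smallest penalty as a fraction of the largest,
#'   default 0.01.
#' @param communities optional per-node community labels (needed for
#'   bridge statistics downstream); defaults to a single community.
#' @param tol,maxit convergence controls passed to the fits.
#' @return a [SymptomNetwork-class]; its `path` slot holds the lambda
#'   grid with edge counts, log-likelihoods and EBIC values.
#' @export
ebicGlasso <- function(S, n = NULL, gamma = 0.5, nLambda = 100L,
                       lambdaMinRatio = 0.01, communities = NULL,
                       tol = 1e-5, maxit = 500L) {
  if (is(S, "CorrelationMatrix")) {
    if (is.null(n)) n <- sampleSize(S)
    S <- corValues(S)
  }
  if (is.null(n)) stop("sample size 'n' is required")
  p <- ncol(S)
  if (n < p) warning("n < p; regularized estimates may be unstable")
  nodeNames <- colnames(S)
  if (is.null(nodeNames)) nodeNames <- paste0("V", seq_len(p))
  if (is.null(communities)) communities <- rep("all", p)

  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax < 1e-12) {
    # no marginal association at all: empty network at any penalty
    K <- diag(1 / diag(S))
    dimnames(K) <- list(nodeNames, nodeNames)
    return(.makeNetwork(K, S, lambda = 0, gamma = gamma,
                        path = data.frame(lambda = 0, edges = 0L,
                                          loglik = NA_real_, ebic = NA_real_),
                        communities = communities, n = n,
                        nodeNames = nodeNames))
  }
  lambdas <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                     length.out = nLambda))
  Sn <- unname(S)
  fits <- vector("list", nLambda)
  ebic <- loglik <- numeric(nLambda)
  edges <- integer(nLambda)
  W0 <- B0 <- NULL
  for (k in seq_len(nLambda)) {
    fit <- .glasso_cd(Sn, lambdas[k], tol, as.integer(maxit), W0, B0)
    if (!fit$converged)
      stop(sprintf("glasso did not converge at lambda = %.4g (grid point %d)",
                   lambdas[k], k))
    W0 <- fit$W; B0 <- fit$beta
    K <- fit$K
    ch <- chol(K)
    ll <- (n / 2) * (2 * sum(log(diag(ch))) - sum(Sn * K))
    E <- sum(K[upper.tri(K)] != 0)
    fits[[k]] <- K
    loglik[k] <- ll
    edges[k] <- E
    ebic[k] <- -2 * ll + E * log(n) + 4 * E * gamma * log(p)
  }
  best <- min(ebic)
  cand <- which(ebic <= best + 1e-9)
  if (length(cand) > 1L)
    message(sprintf("EBIC tie across %d grid points; keeping the sparser model",
                    length(cand)))
  sel <- cand[1L]   # grid is decreasing, so the first is the largest lambda
  K <- fits[[sel]]
  dimnames(K) <- list(nodeNames, nodeNames)
  .makeNetwork(K, S, lambda = lambdas[sel], gamma = gamma,
               path = data.frame(lambda = lambdas, edges = edges,
                                 loglik = loglik, ebic = ebic),
               communities = communities, n = n, nodeNames = nodeNames)
}

.makeNetwork <- function(K, S, lambda, gamma, path, communities, n,
                         nodeNames) {
  w <- -K / sqrt(outer(diag(K), diag(K)))
  w[K == 0] <- 0           # keep lasso zeros exact through the rescaling
  diag(w) <- 0
  w <- (w + t(w)) / 2
  w[t(w) == 0] <- 0
  dimnames(w) <- list(nodeNames, nodeNames)
  new("SymptomNetwork", weights = w, precision = K, lambda = lambda,
      gamma = gamma, path = path, communities = as.character(communities),
      n = as.integer(n), nodeNames = nodeNames)
}
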