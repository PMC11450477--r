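---
title: "Estimating psychosomatic symptom networks with symnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating psychosomatic symptom networks with symnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symnet)
```

## The scientific problem

Somatic symptoms, anxiety and depression are heavily comorbid, and survey
studies of student populations routinely find a third or more of
respondents above screening cut-offs. Classical latent-variable analyses
attribute this co-occurrence to a common underlying factor; network
analysis instead treats each symptom as a node of an interacting system
and asks which symptoms are *central* (strongly connected overall), which
ones *bridge* the somatic and the psychological clusters, and how
predictable each symptom is from its neighbors. symnet implements this
analysis end to end for 0–3 Likert questionnaire data: a 30-item somatic
health-status inventory, the 7-item GAD-7 (anxiety screening cut-off:
total ≥ 5) and the 2-item PHQ-2 (depression cut-off: total ≥ 2).

## The estimation chain and its assumptions

1. **Screening and descriptives.** Scale totals, screening prevalence
   (half-up rounding to two decimals, the convention of published survey
   tables), per-item endorsement frequencies (a score ≥ 1, i.e.
   "occasional" or more, counts as endorsement — 0 = "none" is the only
   non-endorsement level; the threshold is an argument), and Cronbach's α
   with sample variances.
2. **Item selection.** Each somatic item's Spearman correlation with the
   PHQ-2 and GAD-7 sum scores is computed; items with
   `max(r_dep, r_anx) >= 0.5` (inclusive) enter the network alongside all
   nine psychological items. The inclusive rule matters: a published
   boundary item at exactly r = 0.500 is retained, and applying the rule
   to the shipped reference correlation table
   (`referenceScaleCorrelations()`) reproduces the published 11-item
   somatic node set exactly. The cutoff is a configuration knob.
3. **Correlation input.** Spearman rank correlations (average ranks over
   the heavy ties of 4-level items) serve as a Gaussian-copula surrogate
   for a correlation matrix. Discrete-data Spearman matrices can be
   indefinite, so `nearestPositiveDefinite()` clips eigenvalues at 1e-6
   and re-standardizes, iterating because re-standardization can push the
   smallest eigenvalue back below the floor; an already-PD matrix passes
   through untouched.
4. **Network estimation.** The graphical lasso (blockwise coordinate
   descent, compiled; diagonal unpenalized; parameter-change tolerance
   1e-5, at most 500 sweeps per penalty) is fitted on a 100-point
   log-spaced λ grid from the largest absolute off-diagonal correlation
   down to 1% of it, with warm starts along the path. The extended BIC
   with γ = 0.5 selects the model; ties are broken toward the larger
   penalty (the sparser model), a deliberately conservative choice. At
   λ = 0 the implementation short-circuits to the exact inverse. Zeros
   are exact (they come from the lasso soft threshold, not from
   post-hoc thresholding), and every selected model satisfies the KKT
   stationarity conditions within 1e-4.
5. **Node indices.** Expected influence is the signed one-step sum of
   incident weights (no two-step variant); bridge expected influence sums
   only edges crossing the somatic / anxiety–depression partition.
   Standardized versions divide by the population SD — both raw and z
   values are always emitted so the convention is transparent.
   Predictability is the R² of the node's observed scores on its
   estimated neighbors' scores, clipped to [0, 1]; this neighborhood-R²
   reading of "how well a node is forecast by its neighbors" is an
   approximation to a full mixed-graphical-model refit, chosen because
   its estimand is directly testable against a closed-form least-squares
   oracle. Collinear neighbor sets fall back to a ridge solve with
   penalty 1e-6. Isolated nodes get PRE = 0.
6. **Robustness.** The nonparametric bootstrap resamples respondents with
   replacement and re-runs the whole chain (steps 3–4) per replicate;
   edge CIs are 95% percentile intervals (not BCa — the simpler
   bookkeeping matches how these networks are usually reported), and
   paired difference tests flag a pair when the (α/2, 1−α/2) percentile
   interval of replicate differences excludes zero, unadjusted for
   multiplicity. The case-dropping bootstrap subsamples without
   replacement at drop fractions 0.10–0.75 (step 0.05, truncated when a
   subsample would fall below p + 5 cases) and reports the CS
   coefficient: the largest drop fraction, reached contiguously from the
   smallest, at which ≥ 95% of subsample centralities correlate ≥ 0.7
   with the full-sample values. Replicate index sets are drawn up front
   from the seed, so a failed replicate is skipped (and counted) without
   shifting the seed-to-replicate mapping; more than 10% failures aborts.

## The synthetic-data generator

The generator is a latent-Gaussian copula with a known sparse
partial-correlation structure. `buildGroundTruth()` draws an edge support
over two communities (defaults: 11 somatic + 9 anxiety/depression nodes,
within-community density 0.20, bridge density 0.10), assigns weights
uniformly from [0.15, 0.35], all positive by default — symptom networks
are overwhelmingly positive, and the somatic–psychological bridges the
model emulates are reported as all-positive. These defaults give a mean
degree near 3, the sparsity typical of published symptom networks. The
weight matrix becomes a precision matrix (unit diagonal,
κ_ij = −w_ij); positive definiteness is enforced by adding the *exact*
diagonal shift that lifts the smallest eigenvalue to 0.05 and
re-standardizing. Because eigenvalues shift linearly under a diagonal
add, this touches only the diagonal: the support is preserved exactly and
every weight shrinks by the common factor 1/(1+δ). A shift above 2 is
refused as infeasible.

`sampleOrdinal()` draws n = 665 latent Gaussian vectors (the sample size
of the survey the package models) and discretizes each coordinate at
three per-item thresholds. Default thresholds are calibrated by
`calibrateThresholds()` to published item means and SDs
(`referenceItemMoments()`): a two-parameter discretized-normal family is
fitted first — two parameters for two targets, so the solution is well
determined and symmetric targets produce symmetric cuts — with a
free-threshold Nelder–Mead refinement when that family cannot reach the
target within the documented tolerances (mean ± 0.05, SD ± 0.1).

**What passing tests do and do not show.** The generator reproduces the
marginal distributions and a plausible sparse dependence structure, and
it makes support recovery, stability and difference-test calibration
checkable against ground truth. It does not emulate a strong common
factor (so internal-consistency coefficients on synthetic data are lower
than on real survey data), response styles, careless responding, or
missingness (real ingestion uses listwise deletion, motivated by
forced-response online administration). Results on synthetic data
therefore validate the *estimator*, not substantive claims about any
real population.

## Numerical choices and degenerate inputs

* EBIC ties → larger λ; an all-zero correlation matrix short-circuits to
  the empty network.
* Constant items are a hard error in `spearmanMatrix()` (their rank
  correlation is undefined) and named in the message.
* An empty selected somatic set is a warning; the network proceeds with
  the psychological items only.
* An empty estimated network reports a bridging percentage of 0 with an
  explanatory note rather than NaN.
* Sub-seeds for pipeline stages are derived deterministically from the
  master seed and stay within 32-bit integer range.
* Degenerate z-standardization (constant centralities) returns zeros
  with a warning; degenerate calibration targets (mean 0) return cut
  points far in the upper tail, giving an all-zero column.

## Problem sizes used in the shipped checks

The test suite validates support recovery at the full study conditions
(n = 665, p = 20, 20 seeds), stability calibration on five
strongly-connected (within-density 0.3, bridge density 0.15, weights
0.20–0.35) and five independence-null data sets at 100 subsamples per
drop level, and difference-test calibration on a mirror-symmetric
six-node truth (so the two compared edges are *exactly* equal by
construction) over 400 outer replicates of a 200-sample bootstrap — sized
so the Monte-Carlo standard error (~0.012) is well inside the margin the
check uses. Default bootstrap budgets (B = 1000 accuracy samples, 250
case-dropping samples per level) remain available through
`pipelineConfig()` for publication-grade runs.

## Known limitations

* Spearman-into-glasso treats ranked ordinal data as a Gaussian copula;
  polychoric correlations are deliberately out of scope.
* Predictability is neighborhood R², not a mixed-graphical-model
  variance decomposition; values are comparable within a network, less
  so across different node sets.
* The percentile difference test is mildly anti-conservative at small
  bootstrap sizes (measured ~0.06 at the nominal 0.05 with B = 200).
* CS coefficients are reported on the standard 0.7-correlation /
  95%-probability convention; both parameters are exposed because
  published "stability coefficients" do not always state them.
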