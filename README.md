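# symnet

Regularized partial-correlation network analysis for psychosomatic symptom
data: comorbid somatic, anxiety and depression symptoms measured with 0–3
Likert questionnaires (a 30-item somatic health-status inventory, the GAD-7
anxiety screener and the PHQ-2 depression screener).

The package is aimed at researchers who want to go beyond prevalence counts
and ask how individual symptoms *interact*: which symptoms are most central
to the comorbid network, which ones bridge the somatic and the
anxiety–depression clusters, and how much of each symptom is explainable
from its neighbors — together with the bootstrap machinery needed to say
how stable those answers are.

## The model

Let `S` be the Spearman correlation matrix of the p retained items. The
network is the Gaussian-copula partial-correlation graph estimated by the
graphical lasso, i.e. the maximizer of the penalized log-likelihood

    log det K − tr(S K) − λ ‖K‖₁,off

over positive-definite precision matrices `K`, with an unpenalized
diagonal. Edge weights are the regularized partial correlations

    w_ij = − κ̂_ij / √(κ̂_ii κ̂_jj)

The penalty λ is selected over a 100-point log-spaced grid by the extended
Bayesian information criterion

    EBIC = −2 l(K̂) + E log n + 4 E γ log p,   γ = 0.5

where `E` is the number of selected edges. On top of the selected network
the package computes, per node:

* **EI** (expected influence): the signed sum of incident edge weights;
* **BEI** (bridge expected influence): the signed sum of edge weights to
  nodes of the *other* community (somatic vs anxiety–depression);
* **PRE** (predictability): the R² of the node's scores regressed on the
  scores of its network neighbors, in [0, 1].

Robustness is assessed with a nonparametric bootstrap (95% percentile
confidence intervals per edge, paired percentile difference tests at
α = 0.05) and a case-dropping bootstrap summarized by the
correlation-stability (CS) coefficient: the largest fraction of
respondents that can be dropped while subsample centralities still
correlate ≥ 0.7 with the full-sample values in ≥ 95% of subsamples.

Because raw survey data of this kind is rarely shareable, the package
ships a first-class synthetic-data module: a latent-Gaussian copula
generator with a known sparse two-community precision matrix and per-item
thresholds calibrated to published item means/SDs, so every stage of the
pipeline can be validated against ground truth.

## Worked example

```r
library(symnet)

spec <- syntheticSpec(seed = 1)          # n = 665, 11 somatic + 9 psych items
gt   <- buildGroundTruth(spec)           # sparse two-community truth
rm   <- sampleOrdinal(gt, spec)          # 0-3 Likert responses

screeningPrevalence(rm, "PHQ2")
#> PHQ2 screening (cut-off >= 2): 239 / 665 positive (35.94%)

net <- estimateNetwork(rm)
net
#> SymptomNetwork: 20 nodes, 21 nonzero edges
#>   lambda = 0.1237 (EBIC gamma = 0.50), n = 665
#>   mean nonzero edge weight = 0.103

sm <- summarizeNetwork(net)
sm$bridgingPct
#> [1] 28.57
head(sort(expectedInfluence(net), decreasing = TRUE), 3)
#>        S8        G2       S11
#> 0.5065269 0.5003609 0.4798402
```

Here 35.94% of the simulated respondents screen positive for depression
(PHQ-2 total ≥ 2); the EBIC-selected network keeps 21 of 190 possible
edges, 28.57% of which bridge the somatic and anxiety–depression
communities; and the three highest-expected-influence symptoms are shown
with their raw EI (sums of incident edge weights). On real data loaded
with `loadResponses()`, `runPipeline(pipelineConfig(input = "responses.csv"))`
runs the same chain end to end and writes every report table as CSV.

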