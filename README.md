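# citeclust

Joint model-based clustering of paired CITE-seq count matrices: RNA UMI
counts (genes × cells) and antibody-derived tag (ADT) counts (surface
markers × cells) measured in the same single cells. The package is for
analysts who want cell-type assignments that use both modalities at once,
with per-cell posterior probabilities rather than only hard labels.

## The model

Both modalities are modeled as mixtures of Dirichlet-multinomial (DM)
distributions over `K` cell types. Cell `j` of type `k` has, per source
`s ∈ {1, 2}` (RNA, ADT),

    x_j^(s) | z_j = k, b_j  ~  DM(T_j^(s), α_(k)^(s) · b_j)

where `α_(k)^(s)` are strictly positive cluster-level Dirichlet
parameters and `b_j ~ LogNormal(0, σ_b²)` is a cell-specific random
effect *shared by both sources*, inducing the cross-modality correlation
that real cells exhibit. The DM log-density is evaluated exactly in log
space,

    log P(x | α) = log[T!/Π x_i!] + Σ_i [lnΓ(x_i+α_i) − lnΓ(α_i)]
                 + lnΓ(|α|) − lnΓ(T+|α|).

Two fitters are provided:

* `runREDM()` — Metropolis-within-Gibbs MCMC for the full random-effects
  model: exact Gibbs draws for labels, multiplicative log-normal
  random-walk Metropolis for `α` and `b` (adaptive step sizes during
  burn-in), a conjugate inverse-gamma update for `σ_b²`, multiple chains
  with maximum-likelihood chain selection, and soft assignments from
  post-burn-in label frequencies (`flagVagueCells()` marks the least
  certain cells).
* `runJointDM()` — EM for the independence variant (no random effects,
  with mixing proportions), using a fixed-point weighted DM maximizer in
  the M-step. Much faster; appropriate when among-cell variability is
  low.

Support code covers per-source K-means plus moment-based Dirichlet
initialization (`initialModelParams()`), AIC/BIC selection of `K`
(`selectK()`), a generative simulator with ground truth
(`simulateREDM()`, plus a deliberately misspecified gamma-Poisson
generator), ARI/AMI evaluation implemented from their definitions, 10x
Matrix Market / CSV readers, and a CLI.

## Worked example

```r
library(citeclust)

sim <- simulateREDM(simConfig(K = 3, cellsPerCluster = 100, G = 60,
                              D = 10, sigmaB = 0.5, seed = 1))
sim$counts
#> PairedCounts object
#>   RNA: 60 genes x 300 cells (median total 2489)
#>   ADT: 10 markers x 300 cells (median total 4790)

fit <- runREDM(sim$counts, K = 3,
               control = mcmcControl(nIter = 500, nChains = 3, seed = 1))
fit
#> DMClusterResult (redm): 300 cells in 3 clusters
#>   cluster sizes: 100, 100, 100
#>   final objective: -84059.79 (chain 1)

adjustedRandIndex(clusterLabels(fit), sim$truth$zTrue)
#> [1] 1
chain <- attr(fit, "chains")[[fit@selectedChain]]
mean(sqrt(chain@sigmaB2Samples[-(1:250)]))   # posterior mean of sigma_b
#> [1] 0.51
sum(flagVagueCells(fit, 0.05))               # least-certain 5% of cells
#> [1] 15

selectK(sim$counts, 2:4, emControl(maxIter = 50, seed = 1))$table
#>   K    logLik  nu      AIC      BIC
#> 1 2 -93800.14 141 187882.3 188404.5
#> 2 3 -85366.69 212 171157.4 171942.6
#> 3 4 -85133.39 283 170832.8 171880.9
```

An ARI of 1 means the recovered partition matches the generating truth
exactly; the posterior mean of `σ_b` (0.51) recovers the generating value
0.5; and BIC is minimized at the true `K = 3` (log-likelihood keeps
rising at `K = 4` but the penalty dominates).

The same pipeline is available from a shell via the launcher in
`inst/scripts/citeclust`:

```sh
citeclust simulate --out-dir sim --k 3 --seed 1
citeclust cluster  --rna sim/rna.csv --adt sim/adt.csv --k 3 \
                   --method redm --seed 1 --out-prefix fit
citeclust evaluate --labels-a fit_labels.csv --labels-b truth_labels.csv
```

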