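# betadrift

Tools for detecting **biotic homogenization** — the increase in
compositional similarity between nearby communities over time — from
gridded presence–absence atlases surveyed in two periods, in both a
taxonomic and a functional currency.  The intended users are community
ecologists and macroecologists working with national atlas data
(breeding birds, butterflies, plants) on a regular km grid.

## What it computes

For every grid square and each of its (≤ 8) Moore neighbours, at focal
scales of 10, 30 and 90 km:

* **Taxonomic turnover**: the Simpson-based
  `β_sim = min(b, c) / (min(b, c) + a)`, with `a` shared species and
  `b`, `c` the one-sided exclusives — insensitive to richness gradients
  and nestedness.
* **Functional turnover**: the Rao quadratic-entropy decomposition
  `β_rao = Q_γ − mean(Q_α)` over Gower distances on mixed traits
  (continuous, ordinal, categorical, multi-label), where `Q_γ` is the
  Rao entropy of the pooled community pair and `Q_α` the within-community
  values (equivalent-numbers corrected by default, so `β_rao ≥ 0`);
  nearest-functional-neighbour and mean-functional-dissimilarity
  variants are included.
* The per-square **change** in each measure between the two periods —
  negative = homogenization — and a **trait-shuffle null model** (999
  label permutations of the trait table, preserving occurrence structure
  and trait covariances exactly) with two-tailed p-values classifying
  squares into taxonomic × functional homogenization/differentiation.
* **Covariates**: earlier-period richness, Rao Q, mean binomial variance
  of local occupancy, and 15 climate variables (mean, detrended
  variance, lag-1 autocorrelation, long-term trend and a fat-tail
  quantile ratio for coldest-month minimum temperature, drought and
  growing degree days).
* **Drivers**: Bayesian intrinsic-CAR Gaussian regressions
  (`y = Xβ + φ + ε`, conjugate Gibbs sampling, sum-to-zero spatial
  effects on the Moore graph scaled to unit generalized variance)
  comparing full / biotic / climate covariate sets by DIC, plus the
  regression of functional on taxonomic change.

A synthetic-data generator (`sim_config()`, `simulate_atlas_pair()`,
`simulate_traits()`, `simulate_climate()`) produces atlas pairs with a
controllable homogenization region, trait–range coupling and climate
trend/autocorrelation/tail structure, so the whole chain is testable
against known truth.  `run_pipeline()` orchestrates an end-to-end run
from a YAML/list config into a directory of CSV outputs with a
reproducibility manifest.

## Worked example

Simulate a 15×15 atlas pair in which the central 60×60 km block is
strongly homogenized and traits are coupled to species' ranges, then
test functional change against the trait-shuffle null and regress
functional on taxonomic change:

```r
library(betadrift)

cfg <- sim_config(grid_size = 15, n_species = 40, seed = 42,
                  homog_strength = 0.8, homog_region = c(30, 90, 30, 90),
                  trait_coupling = 0.6)
pair   <- simulate_atlas_pair(cfg)
traits <- simulate_traits(cfg)
D      <- gower_dist(traits)

s1 <- neighborhood_turnover(pair$atlas1, measure = "sim")
s2 <- neighborhood_turnover(pair$atlas2, measure = "sim")
t1 <- neighborhood_turnover(pair$atlas1, D, "rao")
t2 <- neighborhood_turnover(pair$atlas2, D, "rao")
dsim <- delta_field(s1, s2)
drao <- delta_field(t1, t2)

mean(dsim$value, na.rm = TRUE)   # -0.0296  (net taxonomic homogenization)
mean(drao$value, na.rm = TRUE)   # -0.0036  (net functional homogenization)

nul <- null_delta_distribution(pair$atlas1, pair$atlas2, traits,
                               n_reps = 199, seed = 1)
nul
#> bd_null: 225 cells, 199 shuffles; rejection at alpha=0.05: 9.3%

classify_cells(dsim, drao, nul$p)$counts
#>                           functional homogenization functional differentiation
#> taxonomic homogenization                          9                          5
#> taxonomic differentiation                         4                          3

fit <- regress_rao_on_sim(drao, dsim, n_iter = 2000, n_burn = 500, seed = 2)
unlist(fit$slope)
#>      median       lower       upper substantial
#> 0.007525309 0.005464810 0.009616141 1.000000000
```

The induced signal is recovered: the mean change in both turnover
measures is negative, the null model rejects in 9.3% of squares
(concentrated in the homogenized block — under zero coupling the rate is
calibrated to ≈ 5%), and functional change tracks taxonomic change with
a positive slope whose 95% credible interval excludes zero.

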