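Package: betadrift
Title: Taxonomic and Functional Homogenization of Gridded Species Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting biotic homogenization as a reduction in
    neighbourhood spatial turnover between two census periods of a gridded
    species atlas.  Computes Simpson-based taxonomic turnover (beta_sim) and
    the Rao quadratic entropy decomposition of functional turnover (beta_rao,
    with nearest-functional-neighbour and mean-functional-dissimilarity
    variants) over Moore-neighbourhood moving windows at nested spatial
    scales, tests functional change against a constrained trait-shuffle null
    model, derives biotic covariates and fifteen climate time-series
    covariates (including a fat-tail quantile-ratio statistic), and fits
    intrinsic conditional autoregressive (ICAR) Gaussian regressions by Gibbs
    sampling with DIC-based model comparison.  A synthetic-data generator
    produces atlas pairs, mixed-type trait tables and monthly climate series
    with known structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
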