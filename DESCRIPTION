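Package: hybcorr
Title: Phylogenetic Correlates of Plant Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes hybridization propensity and hybrid ratio from
    flora-derived counts of hybrids and nonhybrid species, scores plant
    groups on life-history, reproductive, genetic and opportunity traits,
    and relates the two with phylogenetic comparative methods: maximum
    likelihood estimation of Pagel's lambda with likelihood-ratio tests,
    univariate phylogenetic generalized least squares regression under
    Brownian motion, Ornstein-Uhlenbeck and early-burst covariance models
    with AIC/BIC comparison and Benjamini-Hochberg correction, and
    phylogenetic path analysis over candidate directed acyclic graphs
    (d-separation basis sets, Fisher's C, CICc). Includes a synthetic-data
    generator (Yule trees, correlated traits with tunable phylogenetic
    signal, flora-style hybrid counts with planted effects) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    phytools,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
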