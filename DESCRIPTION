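Package: ensdm
Title: Ensemble Species Distribution Models and Invasion Risk Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits TSS-weighted ensembles of presence/pseudo-absence
    classifiers (random forest, gradient boosting, logistic regression)
    to occurrence records over gridded environmental layers, following the
    biomod2-style protocol: fishnet thinning of occurrences, Pearson
    collinearity screening, replicated pseudo-absence sets, repeated
    75/25 splits, threshold-optimised true-skill-statistic evaluation and
    gating, weighted-average habitat suitability mapping with four-class
    discretisation, permutation-based variable contribution tables with
    best-suitable-range extraction, and an invasion risk index that
    contrasts an invader's suitability surface with a native species'
    surface. Includes a virtual-species simulator (correlated random
    landscapes, parametric niches, presence sampling from known truth) so
    the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
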