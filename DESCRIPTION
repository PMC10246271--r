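Package: fcmarker
Title: Multi-Site Functional Connectivity Neuromarkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates resting-state functional-connectivity
    neuromarkers on multi-site case-control data. Provides empirical-Bayes
    (ComBat) site-effect harmonization preserving diagnosis, age and sex
    effects; ensembles of L1-penalized logistic classifiers trained with
    nested cross-validation and majority-class subsampling; diagnostic
    probabilities and imbalance-aware performance metrics; label-permutation
    significance tests with maximum-statistic control for discriminative-edge
    identification; cross-dataset reproducibility statistics (t-value
    correlations, sign-consistency binomial tests); resting-state-network
    enrichment by hypergeometric tails; and cross-disorder dimensional
    mapping. A synthetic multi-site generator with planted site, covariate
    and diagnosis effects makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
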