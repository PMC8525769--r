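Package: dualhgf
Title: Dual-Stream Hierarchical Gaussian Filters for Perceptual Decisions
    Under Social Influence
Version: 0.1.0
Authors@R:
    person("dualhgf", "maintainers", email = "maintainers@dualhgf.invalid",
           role = c("aut", "cre"))
Description: Simulation and model-based analysis of a two-phase perceptual
    classification task in which an uninformative partner (collaborator or
    competitor) bets on each upcoming stimulus. Implements a two-level,
    dual-stream (social and non-social) hierarchical Gaussian filter with a
    recency bias and precision-weighted belief combination, softmax response
    models, a Rescorla-Wagner baseline, MAP model inversion with Laplace
    approximation of the model evidence, random-effects Bayesian model
    selection with family aggregation and protected exceedance probabilities,
    behavioral self-deception and overconfidence metrics
    (confidence-weighted self-deception, rank-difference insight), and a
    synthetic cohort generator with configurable group structure so that the
    full pipeline can be exercised end to end without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
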