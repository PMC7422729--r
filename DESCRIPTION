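Package: g3plt
Title: Item Response Modeling with a Time-Modulated Three-Parameter Logistic Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a generalization of the three-parameter logistic (3PL) item
    response model in which the correct-response probability depends jointly on
    examinee ability, item parameters, and a standardized log response time
    (G3PLT). Provides the probability kernel with its 3PL limit and analytic
    inversions, maximum-likelihood ability scoring, a Metropolis-Hastings
    within Gibbs sampler (implemented in C++) with Gelman-Rubin diagnostics and
    highest-posterior-density intervals, Bayesian model assessment via the
    deviance information criterion and the log pseudomarginal likelihood
    (max-adjusted conditional predictive ordinates), replication-level
    parameter-recovery metrics, and seeded simulators for structured
    response-time data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
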