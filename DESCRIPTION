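Package: qmediate
Title: High-Dimensional Quantile Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects and tests high-dimensional mediators of an
    exposure-outcome relationship across the full outcome distribution.
    The outcome is modelled by quantile regression at a user-chosen level
    tau while each candidate mediator follows a linear model in the
    exposure and covariates.  A three-step procedure -- marginal quantile
    screening, minimax-concave-penalty (MCP) regularized smoothed quantile
    regression, and a joint-significance decision statistic -- identifies
    mediators whose exposure->mediator and mediator->outcome paths are both
    active at the chosen quantile, and reports controlled direct and
    indirect effects.  Includes a simulation framework with
    bias/SSE/model-size/TPP/FDP evaluation metrics and command-line entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    optparse,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
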