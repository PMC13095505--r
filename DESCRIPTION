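Package: bar12
Title: Bayesian Autoregressive Phase 1-2 Dose Finding for Cell Therapy
    Trials with Manufacturing Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the BAR12 Bayesian autoregressive phase 1-2
    dose-finding design for cell-therapy trials in which the manufacturing
    process is modified ("tweaked") one or more times during the trial.
    Provides the bivariate binary toxicity/efficacy dose-response model
    with a shared patient frailty, spike-and-slab first-order
    autoregressive priors that borrow strength across trial stages,
    prior calibration by effective-sample-size and boundary-mass criteria,
    posterior inference by adaptive Markov chain Monte Carlo, utility-based
    dose acceptability and adaptive-randomization decision rules, the
    conventional "Identical" and "Separate" comparator designs, and an
    operating-characteristics simulator with a library of stress-test
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    parallel,
    MASS
Config/testthat/edition: 3
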