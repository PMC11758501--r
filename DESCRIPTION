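Package: pmtddesign
Title: Covariate-Aware Bayesian Model-Based Dose-Finding Designs and
    Operating-Characteristics Simulation
Version: 0.1.0
Authors@R:
    person("pkg", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Implements Bayesian logistic regression model (BLRM) dose-finding
    designs for Phase I trials, with extensions that include patient
    covariates in the dose-toxicity model (BLRMc), a dose-allocation-change
    inclusion criterion, and penalized covariate priors (Bayesian LASSO and
    Spike-and-Slab).  Provides the true-model machinery for simulation
    scenarios (two-parameter logistic and Emax dose-toxicity families,
    marginal-probability calibration, personalized-MTD distributions), a
    sequential trial simulator, and an operating-characteristics engine that
    scores personalized-MTD allocation and overdosing for enrolled and
    additional patients, with geometric-mean aggregation across scenarios and
    hyperparameter calibration grids.  Posterior inference uses either dense
    grid quadrature or an adaptive random-walk Metropolis sampler implemented
    in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
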