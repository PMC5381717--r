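Package: psjm
Title: Flexible Joint Models with Individual-Level P-Splines for Dynamic
    Survival Prediction
Version: 0.1.0
Authors@R: person("psjm", "maintainers", email = "psjm@example.org",
    role = c("aut", "cre"))
Description: Joint modelling of a continuous longitudinal outcome and a
    discrete-time-to-event outcome using individual-level penalized splines
    with a truncated linear basis. The individual spline coefficients act as
    shared random effects that drive a probit model for the discrete hazard,
    so each subject's marginal likelihood has a closed form (Gaussian
    conjugacy plus one multivariate normal orthant probability) and the
    posterior of the random coefficients given a subject's history is a
    multivariate skew-normal distribution, from which exact (MCMC-free)
    draws yield dynamic predictions of conditional survival probabilities.
    Includes maximum penalized likelihood estimation with AIC-based
    smoothing selection, a generative simulator, and comparator methods
    (time-varying-covariate probit survival model, two-stage approach,
    random intercept-and-slope joint model).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
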