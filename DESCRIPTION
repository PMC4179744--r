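Package: occamfun
Title: Bayesian Model Selection for Human Function Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for studying how observers
    learn functional relationships between a spatial cue and a target
    onset time in an interception task. Provides a synthetic-participant
    generator (stationary sessions with separated training and test
    regions, and non-stationary sessions in which the generating
    polynomial switches covertly), maximum-likelihood fits of candidate
    function-learning accounts (polynomial regression, per-region
    interpolation and extrapolation heuristics, and Gaussian-process
    regression with a squared-exponential kernel) with Gaussian
    predictive distributions, marginal-likelihood and Bayes-factor model
    comparison, a Bayesian model selection engine that integrates
    polynomial coefficients analytically under Gaussian priors and
    marginalizes the response noise numerically, sliding-window posterior
    and parameter time courses, and acquisition-time analyses against a
    simulated omniscient-observer baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
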