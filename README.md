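# occamfun

Tools for studying how an observer can acquire a hidden *function* — a
mapping from a cue (lateral position, mm) to a response-relevant quantity
(target onset time, ms) — at two levels at once: the discrete function
class (constant, linear, quadratic, ...) and its continuous parameters.
The package provides a synthetic-participant simulator for interception
style experiments, a Bayesian model-selection core with an automatic
Occam penalty, a model zoo for stationary (train/test region) sessions,
and sliding-window time-course analyses for sessions in which the hidden
function is covertly switched.

## What it does

* **Simulation** — `session_design()` / `switch_design()` describe
  stationary and switching sessions; `simulate_session()` produces trial
  tables from an omniscient truth-plus-Gaussian-noise observer, with the
  interception hit rule (`onset <= response + 300 <= onset + 150`) and a
  hit-rate exclusion rule.
* **Bayesian model selection** — `model_posteriors()` computes posterior
  probabilities over the candidate polynomial classes. Coefficients are
  integrated out analytically under deliberately mislocated, inflated
  Gaussian priors; the unknown noise sd is marginalised numerically over
  a uniform grid on (0, 5000] ms. The marginal likelihood's dimensionality
  penalty does the work: no complexity penalty is hand-coded.
* **Time courses** — `posterior_timecourse()` runs the selection in a
  sliding 50-trial window (a 500-trial session yields 451 frames);
  `mle_parameter_timecourse()` tracks windowed maximum-likelihood
  coefficients; `extract_acquisitions()` measures trials-to-criterion
  after each covert function switch, and `simulated_baseline()` provides
  the omniscient-observer reference distribution.
* **Stationary model comparison** — `fit_model_zoo()` fits polynomials,
  an interpolation heuristic, an extrapolation (local-lines) heuristic
  and a squared-exponential GP; `test_nll()` scores held-out test
  regions, `marginal_likelihood_numeric()` integrates parameter
  uncertainty for Bayes factors on the conventional `2 ln K` evidence
  scale (`bf_category()`).
* **I/O** — flat CSV trial tables (`read_trials()` / `write_trials()`)
  and a one-call pipeline (`run_config()` + `run_pipeline()`) that writes
  reports plus a `config.txt` recording the seed, the defaults in force
  and a config hash.

## Quick start

```r
library(occamfun)

## A switching session: constant -> linear -> quadratic
design <- default_switch_designs()$G1
trials <- simulate_session(design, noise_sd = 50, seed = 1)
tc     <- posterior_timecourse(trials, W = 50)
extract_acquisitions(tc, design, thresholds = 0.33)

## A stationary session with held-out test regions
cfg <- run_config(1, seed = 1, generating = "linear")
run_pipeline(cfg)$report
```

The methods vignette (`vignettes/function-learning-methods.Rmd`) walks
through the statistical details, including the exact analytic form of
the coefficient integral and the known sensitivity of the
constant/quadratic baseline asymmetry to the noise-prior
parameterisation.

## Testing

The package uses testthat (edition 3). `tests/testthat/test-acceptance.R`
holds one block per acceptance criterion; everything else is the
ordinary unit/property suite:

```r
testthat::test_dir("tests/testthat", package = "occamfun",
                   load_package = "installed")
```

`scripts/acceptance.R --seed <int> --out <path>` recomputes the headline
quantities against the installed package and writes them as JSON.
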