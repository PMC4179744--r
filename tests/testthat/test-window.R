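test_that("sliding windows enumerate all contiguous frames", {
  w <- sliding_windows(500, 50)
  expect_identical(nrow(w), 451L)
  expect_identical(w$start[1], 1L)
  expect_identical(w$end[451], 500L)
  expect_true(all(w$end - w$start == 49L))
  expect_identical(nrow(sliding_windows(50, 50)), 1L)
  expect_identical(nrow(sliding_windows(51, 50)), 2L)
  expect_error(sliding_windows(49, 50), "exceeds")
  expect_error(sliding_windows(10, 0), ">= 1")
})

test_that("posterior time course matches per-window model_posteriors", {
  design <- switch_design(exp2_functions())
  tab <- simulate_session(design, 50, seed = 71)
  tc <- posterior_timecourse(tab, W = 50)
  expect_s3_class(tc, "posterior_timecourse")
  expect_identical(nrow(tc), 451L)
  expect_named(tc, c("frame", "last_trial", "p_constant", "p_linear",
                     "p_quadratic"))
  expect_identical(attr(tc, "W"), 50L)
  expect_identical(attr(tc, "anchor"), "trailing")
  expect_equal(tc$last_trial, tc$frame + 49L)
  rows <- rowSums(as.matrix(tc[, 3:5]))
  expect_equal(rows, rep(1, 451), tolerance = 1e-12)

  set.seed(72)
  for (f in sample(451, 3)) {
    idx <- f:(f + 49L)
    mp <- model_posteriors(tab$response_ms[idx], tab$x_mm[idx])
    expect_equal(unname(unlist(tc[f, 3:5])), unname(mp$posterior),
                 tolerance = 1e-12)
    expect_equal(unname(attr(tc, "log_marginal")[f, ]),
                 unname(mp$log_marginal), tolerance = 1e-12)
  }
  expect_error(posterior_timecourse(transform(tab, response_ms = NA)),
               "responses")
})

test_that("window posteriors are invariant to trial order within the window", {
  set.seed(73)
  x <- stats::runif(50, -100, 100)
  y <- 1350 + 7 * x + stats::rnorm(50, 0, 30)
  p1 <- model_posteriors(y, x)$posterior
  perm <- sample(50)
  p2 <- model_posteriors(y[perm], x[perm])$posterior
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("windowed MLEs are exact on noiseless data", {
  design <- switch_design(exp2_functions())
  stim <- sample_stimuli(design, seed = 74)
  tab <- simulate_responses(stim, design, observer_spec(1e-9, seed = 75))
  params <- mle_parameter_timecourse(tab[1:150, ], W = 50)
  # frames fully inside segment 1 (constant 1350): constant-model MLE
  seg1 <- params$model == "constant" & params$last_trial <= 100
  expect_lt(max(abs(params$mle[seg1] - 1350)), 1e-6)
  # frames fully inside segment 2 (linear 1350 + 7x)
  lin <- params$model == "linear" & params$frame >= 101
  est <- params[lin, ]
  expect_lt(max(abs(est$mle[est$term_degree == 0] - 1350)), 1e-6)
  expect_lt(max(abs(est$mle[est$term_degree == 1] - 7)), 1e-8)
  expect_lt(max(params$noise_sd[lin]), 1e-6)
})

test_that("constant-model windowed MLE equals the window mean", {
  set.seed(76)
  y <- stats::rnorm(50, 1500, 80)
  x <- stats::runif(50, -100, 100)
  fit <- occamfun:::window_mle(y, x, 0L, default_search_ranges(0))
  expect_equal(fit$theta, mean(y), tolerance = 1e-10)
  expect_equal(fit$noise_sd, sqrt(mean((y - mean(y))^2)), tolerance = 1e-10)
})

test_that("box constraints bind when the OLS solution escapes the range", {
  set.seed(77)
  x <- stats::runif(50, -100, 100)
  y <- 1350 + 7 * x + stats::rnorm(50, 0, 5)
  ranges <- cbind(lo = c(-10000, -1), hi = c(10000, 1))   # slope capped at 1
  fit <- occamfun:::window_mle(y, x, 1L, ranges)
  expect_true(all(fit$theta >= ranges[, 1] - 1e-8 &
                    fit$theta <= ranges[, 2] + 1e-8))
  expect_equal(fit$theta[2], 1, tolerance = 1e-4)
  # the constrained solution beats clamping OLS naively
  ols <- qr.coef(qr(cbind(1, x)), y)
  naive <- pmin(pmax(ols, ranges[, 1]), ranges[, 2])
  rss <- function(th) sum((y - cbind(1, x) %*% th)^2)
  expect_lte(rss(fit$theta), rss(naive) + 1e-6)
})

test_that("trajectory smoothing preserves constants, ramps and length", {
  expect_identical(smooth_trajectory(numeric(0)), numeric(0))
  expect_equal(smooth_trajectory(rep(3.5, 40)), rep(3.5, 40),
               tolerance = 1e-12)
  ramp <- seq(0, 10, length.out = 101)
  sm <- smooth_trajectory(ramp, radius = 4)
  interior <- 20:80
  expect_equal(sm[interior], ramp[interior], tolerance = 1e-8)
  expect_length(sm, 101L)
  expect_identical(smooth_trajectory(ramp, radius = 0), ramp)
  set.seed(78)
  noisy <- stats::rnorm(200)
  expect_lt(stats::sd(smooth_trajectory(noisy, 5)), stats::sd(noisy))
})

test_that("the active model dominates frames well inside each segment", {
  design <- switch_design(exp2_functions())
  tab <- simulate_session(design, 10, seed = 79)
  tc <- posterior_timecourse(tab, W = 50)
  top_at <- function(trial) {
    row <- tc[tc$last_trial == trial, c("p_constant", "p_linear", "p_quadratic")]
    c("constant", "linear", "quadratic")[which.max(unlist(row))]
  }
  expect_identical(top_at(95), "constant")    # window 46..95, all segment 1
  expect_identical(top_at(240), "linear")     # window 191..240, all segment 2
  expect_identical(top_at(480), "quadratic")  # window 431..480, all segment 3
})

test_that("selection extent averages the right frames and validates input", {
  design <- switch_design(exp2_functions())
  tab <- simulate_session(design, 10, seed = 80)
  tc <- posterior_timecourse(tab, W = 50)
  ext <- selection_extent(tc, design)
  expect_identical(ext$segment, 1:3)
  expect_identical(ext$model, c("constant", "linear", "quadratic"))
  seg2 <- tc$last_trial > 100 & tc$last_trial <= 250
  expect_equal(ext$extent[2], mean(tc$p_linear[seg2]), tolerance = 1e-12)
  short <- switch_design(exp2_functions(), n_trials = 400L)
  expect_error(selection_extent(tc, short), "longer than the design")
})
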