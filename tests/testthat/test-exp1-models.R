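trial_frame <- function(x, y) {
  data.frame(trial = seq_along(x), phase = "interleaved", x_mm = x,
             onset_ms = y, response_ms = y, trial_type = "train", hit = TRUE,
             stringsAsFactors = FALSE)
}

test_that("fit_polynomial reproduces a hand-worked least-squares fit", {
  # (x, y) on the exact line y = 5 - 2x
  tf <- trial_frame(c(-2, -1, 0, 1, 2), c(9, 7, 5, 3, 1))
  fit <- fit_polynomial(tf, 1L)
  expect_equal(fit$params, c(5, -2), tolerance = 1e-12)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-12)

  # noisy fixture cross-checked against lm(): same coefficients, and the
  # covariance equals vcov(lm) rescaled from the unbiased to the MLE
  # variance estimate
  set.seed(4)
  x <- stats::runif(40, -100, 100)
  y <- 1250 - 5 * x + stats::rnorm(40, 0, 30)
  fit <- fit_polynomial(trial_frame(x, y), 1L)
  ref <- stats::lm(y ~ x)
  expect_equal(fit$params, unname(stats::coef(ref)), tolerance = 1e-10)
  expect_equal(fit$residual_sd^2, mean(stats::resid(ref)^2), tolerance = 1e-10)
  expect_equal(unname(fit$param_covariance),
               unname(stats::vcov(ref)) * (40 - 2) / 40, tolerance = 1e-8)
})

test_that("fit_polynomial recovers noiseless coefficients to 1e-8 relative", {
  set.seed(8)
  for (d in 0:3) {
    truth <- stats::rnorm(d + 1L, 0, c(1000, 10, 1, 0.1)[seq_len(d + 1L)])
    x <- stats::runif(30, -100, 100)
    y <- as.numeric(design_matrix(x, d) %*% truth)
    fit <- fit_polynomial(trial_frame(x, y), d)
    expect_lt(max(abs(fit$params - truth) / pmax(abs(truth), 1e-12)), 1e-8)
  }
  expect_error(fit_polynomial(trial_frame(c(0, 1), c(1, 2)), 1L), "at least")
  expect_error(fit_polynomial(trial_frame(rep(3, 5), 1:5), 1L),
               "rank-deficient")
})

test_that("polynomial predictive variance propagates the coefficient covariance", {
  set.seed(12)
  x <- stats::runif(25, -100, 100)
  y <- 1700 + 0.5 * x - 0.1 * x^2 + stats::rnorm(25, 0, 40)
  fit <- fit_polynomial(trial_frame(x, y), 1L)
  xs <- c(-80, 0, 35)
  pr <- predict_polynomial(fit, xs)
  S <- fit$param_covariance
  manual <- S[1, 1] + xs^2 * S[2, 2] + 2 * xs * S[1, 2] + fit$residual_sd^2
  expect_equal(pr$sd_ms^2, manual, tolerance = 1e-10)
  expect_equal(pr$mean_ms, fit$params[1] + fit$params[2] * xs,
               tolerance = 1e-10)
})

test_that("interpolation heuristic: one global line is reproduced in the gaps", {
  regions <- rbind(c(-100, -60), c(60, 100))
  set.seed(3)
  x <- c(stats::runif(20, -100, -60), stats::runif(20, 60, 100))
  y <- 1250 - 5 * x                                  # noiseless global line
  fit <- fit_interpolation_heuristic(trial_frame(x, y), regions)
  xs <- c(-30, 0, 42)
  pr <- predict_interpolation(fit, xs)
  expect_equal(pr$mean_ms, 1250 - 5 * xs, tolerance = 1e-8)
})

test_that("interpolation heuristic: flanks are flat, gaps mix edge predictions", {
  regions <- rbind(c(-100, -60), c(60, 100))
  set.seed(5)
  x <- c(stats::runif(25, -100, -60), stats::runif(25, 60, 100))
  y <- 1250 - 5 * x + stats::rnorm(50, 0, 20)
  fit <- fit_interpolation_heuristic(trial_frame(x, y), regions)
  segs <- fit$segments

  # beyond the outer boundaries the prediction is constant
  flank <- predict_interpolation(fit, c(-120, -110, -101))
  expect_true(all(abs(diff(flank$mean_ms)) < 1e-10))
  edgeL <- sum(segs[[1]]$coef * c(1, -100))
  expect_equal(flank$mean_ms[1], edgeL, tolerance = 1e-10)

  # in the gap the mean and variance follow the documented mixture
  xg <- 12
  w <- (60 - xg) / (60 - (-60))
  sL <- c(1, -60); sR <- c(1, 60)
  mL <- sum(segs[[1]]$coef * sL); mR <- sum(segs[[2]]$coef * sR)
  pvL <- drop(t(sL) %*% segs[[1]]$cov %*% sL)
  pvR <- drop(t(sR) %*% segs[[2]]$cov %*% sR)
  vman <- w^2 * pvL + (1 - w)^2 * pvR +
    w * segs[[1]]$residual_sd^2 + (1 - w) * segs[[2]]$residual_sd^2
  pr <- predict_interpolation(fit, xg)
  expect_equal(pr$mean_ms, w * mL + (1 - w) * mR, tolerance = 1e-10)
  expect_equal(pr$sd_ms^2, vman, tolerance = 1e-10)

  # inside a region the prediction follows that region's line
  pin <- predict_interpolation(fit, -80)
  expect_equal(pin$mean_ms, sum(segs[[1]]$coef * c(1, -80)), tolerance = 1e-10)
})

test_that("extrapolation heuristic follows the |x|-style intersection geometry", {
  regions <- rbind(c(-100, -60), c(60, 100))
  set.seed(6)
  xL <- stats::runif(20, -100, -60); xR <- stats::runif(20, 60, 100)
  x <- c(xL, xR)
  y <- abs(x)                                        # lines -x and +x meet at 0
  fit <- fit_extrapolation_heuristic(trial_frame(x, y), regions)
  gap <- predict_extrapolation(fit, c(-30, -5, 5, 30))
  expect_equal(gap$mean_ms, c(30, 5, 5, 30), tolerance = 1e-6)
  # peripheral positions extrapolate the nearest segment's line
  out <- predict_extrapolation(fit, c(-130, 130))
  expect_equal(out$mean_ms, c(130, 130), tolerance = 1e-6)
})

test_that("extrapolation heuristic falls back to interpolation for parallel lines", {
  regions <- rbind(c(-100, -60), c(60, 100))
  set.seed(7)
  xL <- stats::runif(20, -100, -60); xR <- stats::runif(20, 60, 100)
  x <- c(xL, xR)
  y <- ifelse(x < 0, 2 * x + 100, 2 * x - 100)       # parallel, offset lines
  fit <- fit_extrapolation_heuristic(trial_frame(x, y), regions)
  xs <- c(-20, 0, 40)
  ex <- predict_extrapolation(fit, xs)
  ip <- predict_interpolation(
    fit_interpolation_heuristic(trial_frame(x, y), regions), xs)
  expect_equal(ex$mean_ms, ip$mean_ms, tolerance = 1e-8)
  expect_equal(ex$sd_ms, ip$sd_ms, tolerance = 1e-8)
})

test_that("heuristic fitting requires enough trials per region", {
  regions <- rbind(c(-100, -60), c(60, 100))
  tf <- trial_frame(c(-90, -70, 65, 70, 80), c(1, 2, 3, 4, 5))
  expect_error(fit_interpolation_heuristic(tf, regions), "fewer than 3")
})

test_that("GP marginal likelihood matches a dense Gaussian-density oracle", {
  set.seed(9)
  x <- stats::runif(12, -100, 100)
  y <- stats::rnorm(12, 0, 50)
  ell <- 40; sf <- 60; sn <- 20
  K <- sf^2 * exp(-outer(x, x, `-`)^2 / (2 * ell^2)) + sn^2 * diag(12)
  L <- chol(K)
  z <- backsolve(L, y, transpose = TRUE)
  oracle <- -0.5 * (12 * log(2 * pi) + sum(z^2)) - sum(log(diag(L)))
  expect_equal(occamfun:::gp_log_marginal(x, y, ell, sf, sn), oracle,
               tolerance = 1e-10)
})

test_that("GP predictions interpolate near data and revert to the prior far away", {
  x <- seq(-60, 60, by = 10)
  y <- 1500 + 50 * sin(x / 30)
  model <- structure(
    list(family = "gp", length_scale = 30, signal_sd = 60, noise_sd = 1,
         train_x = x, train_y = y, prior_mean = mean(y)),
    class = "fitted_model"
  )
  at_data <- predict_gp(model, x)
  expect_lt(max(abs(at_data$mean_ms - y)), 1.5)
  far <- predict_gp(model, c(-2000, 2000))
  expect_equal(far$mean_ms, rep(mean(y), 2), tolerance = 1e-6)
  expect_equal(far$sd_ms, rep(sqrt(60^2 + 1), 2), tolerance = 1e-6)
})

test_that("fit_gp finds hyperparameters that explain smooth structure", {
  set.seed(10)
  x <- stats::runif(60, -100, 100)
  y <- 1700 + 0.5 * x - 0.1 * x^2 + stats::rnorm(60, 0, 20)
  fit <- fit_gp(trial_frame(x, y))
  expect_identical(fit$family, "gp")
  expect_true(all(c(fit$length_scale, fit$signal_sd, fit$noise_sd) > 0))
  # the fitted marginal is at least as good as a mid-grid handpicked start
  hand <- occamfun:::gp_log_marginal(x, y - mean(y), 50, stats::sd(y), 20)
  expect_gte(fit$log_marginal, hand - 1e-6)
  pr <- predict_gp(fit, seq(-90, 90, by = 20))
  truth <- 1700 + 0.5 * seq(-90, 90, by = 20) - 0.1 * seq(-90, 90, by = 20)^2
  expect_lt(max(abs(pr$mean_ms - truth)), 60)
  expect_error(fit_gp(trial_frame(1, 2)), "at least 2")
})

test_that("test_nll is the summed Gaussian negative log density", {
  pr <- data.frame(x_mm = 1:3, mean_ms = c(10, 20, 30), sd_ms = c(1, 2, 3),
                   family = "polynomial1")
  test <- trial_frame(1:3, c(11, 19, 33))
  manual <- -sum(stats::dnorm(c(11, 19, 33), c(10, 20, 30), c(1, 2, 3),
                              log = TRUE))
  expect_equal(test_nll(pr, test), manual, tolerance = 1e-12)
  expect_identical(test_nll(pr[0, ], test[0, ]), 0)
  expect_error(test_nll(pr[1:2, ], test), "one predictive")
  pr$sd_ms[2] <- 0
  expect_error(test_nll(pr, test), "positive")
})

test_that("split_session and fit_model_zoo partition and fit the session", {
  design <- session_design(exp1_functions()$linear)
  tab <- simulate_session(design, 50, seed = 21)
  parts <- split_session(tab)
  expect_identical(nrow(parts$train), 60L)
  expect_identical(nrow(parts$test), 60L)
  expect_false(any(parts$train$phase == "burn_in"))
  expect_true(all(parts$test$trial_type == "test"))

  zoo <- fit_model_zoo(tab, design$train_regions, degrees = 0:1)
  expect_named(zoo, c("polynomial0", "polynomial1", "interpolation",
                      "extrapolation", "gp"))
  for (m in zoo) {
    pr <- predict_model(m, parts$test$x_mm)
    expect_identical(nrow(pr), 60L)
    expect_true(all(pr$sd_ms > 0))
  }
})
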