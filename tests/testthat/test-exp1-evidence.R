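# A fitted polynomial plus matched test data for evidence tests.
evidence_fixture <- function(degree = 1L, n_train = 40L, n_test = 30L,
                             sd = 25, seed = 51) {
  set.seed(seed)
  truth <- c(1250, -5, -0.1, 0.001)[seq_len(degree + 1L)]
  xtr <- stats::runif(n_train, -100, 100)
  ytr <- as.numeric(design_matrix(xtr, degree) %*% truth) +
    stats::rnorm(n_train, 0, sd)
  train <- data.frame(trial = seq_len(n_train), phase = "interleaved",
                      x_mm = xtr, onset_ms = ytr, response_ms = ytr,
                      trial_type = "train", hit = TRUE)
  xte <- stats::runif(n_test, -100, 100)
  yte <- as.numeric(design_matrix(xte, degree) %*% truth) +
    stats::rnorm(n_test, 0, sd)
  test <- data.frame(trial = n_train + seq_len(n_test), phase = "interleaved",
                     x_mm = xte, onset_ms = yte, response_ms = yte,
                     trial_type = "test", hit = NA)
  list(model = fit_polynomial(train, degree), test = test)
}

# Closed-form log marginal for a linear-in-theta model under a uniform
# box prior, with the box truncation evaluated axis-wise via pnorm in the
# whitened coordinates (valid here because the posteriors of these
# fixtures are axis-aligned enough that truncation is negligible; we also
# assert that).
closed_form_box_marginal <- function(model, test, ranges) {
  s <- model$residual_sd
  A <- design_matrix(test$x_mm, model$degree)
  y <- test$response_ms
  M <- crossprod(A) / s^2
  b <- as.numeric(crossprod(A, y)) / s^2
  c0 <- -0.5 * sum(y^2) / s^2 - length(y) * log(sqrt(2 * pi) * s)
  mu <- solve(M, b)
  # full-space Gaussian integral of exp(c0 + b't - t'Mt/2)
  lZ_full <- c0 + 0.5 * sum(b * mu) +
    0.5 * (length(b) * log(2 * pi) - determinant(M)$modulus[1])
  # axis-wise mass retained inside the box (diagonal approximation used
  # only to confirm that truncation is numerically irrelevant)
  sds <- sqrt(diag(solve(M)))
  mass <- prod(stats::pnorm((ranges[, 2] - mu) / sds) -
                 stats::pnorm((ranges[, 1] - mu) / sds))
  list(lZ = lZ_full - sum(log(ranges[, 2] - ranges[, 1])), mass = mass)
}

test_that("grid evidence matches the conjugate closed form for polynomials", {
  for (degree in 0:2) {
    fx <- evidence_fixture(degree)
    ranges <- default_parameter_ranges(fx$model)
    ref <- closed_form_box_marginal(fx$model, fx$test, ranges)
    expect_gt(ref$mass, 1 - 1e-12)   # box truncation negligible by design
    ev <- marginal_likelihood_numeric(fx$model, fx$test, method = "grid")
    expect_identical(ev$method, "grid")
    expect_equal(ev$log_marginal, ref$lZ, tolerance = 1e-6)
  }
})

test_that("doubling a parameter range lowers the evidence by ~log 2", {
  fx <- evidence_fixture(1L)
  r1 <- default_parameter_ranges(fx$model)
  r2 <- r1; r2[1, ] <- 2 * r2[1, ]
  e1 <- marginal_likelihood_numeric(fx$model, fx$test, ranges = r1,
                                    method = "grid")
  e2 <- marginal_likelihood_numeric(fx$model, fx$test, ranges = r2,
                                    method = "grid")
  expect_equal(e1$log_marginal - e2$log_marginal, log(2), tolerance = 1e-3)
})

test_that("importance-sampling evidence agrees with the grid within its error", {
  fx <- evidence_fixture(1L)
  eg <- marginal_likelihood_numeric(fx$model, fx$test, method = "grid")
  em <- marginal_likelihood_numeric(fx$model, fx$test, method = "mc",
                                    seed = 99, n_mc = 5e4)
  expect_identical(em$method, "mc")
  expect_true(is.finite(em$mc_rel_se))
  expect_lt(abs(em$log_marginal - eg$log_marginal),
            4 * em$mc_rel_se + 0.02)
  # seeded: identical on repetition, different under another seed
  em2 <- marginal_likelihood_numeric(fx$model, fx$test, method = "mc",
                                     seed = 99, n_mc = 5e4)
  expect_identical(em$log_marginal, em2$log_marginal)
})

test_that("evidence integration rejects ranges that exclude the MLE", {
  fx <- evidence_fixture(1L)
  bad <- default_parameter_ranges(fx$model)
  bad[1, ] <- c(-10, 10)   # intercept MLE ~1250 lies outside
  expect_error(marginal_likelihood_numeric(fx$model, fx$test, ranges = bad),
               "outside the integration ranges")
})

test_that("default ranges cover every family and the zoo's MLEs", {
  design <- session_design(exp1_functions()$linear)
  tab <- simulate_session(design, 50, seed = 61)
  zoo <- fit_model_zoo(tab, design$train_regions, degrees = 0:1)
  for (m in zoo) {
    r <- default_parameter_ranges(m)
    th <- occamfun:::model_theta_hat(m)
    expect_identical(nrow(r), length(th$mle))
    expect_true(all(th$mle >= r[, 1] & th$mle <= r[, 2]))
  }
})

test_that("Bayes factors and the evidence scale follow the conventions", {
  ref <- occamfun:::new_model_evidence("polynomial1", -100, "grid", 1, NA,
                                       cbind(0, 1), NULL)
  worse <- occamfun:::new_model_evidence("gp", -103.5, "grid", 1, NA,
                                         cbind(0, 1), NULL)
  bf <- bayes_factor(worse, ref)
  expect_equal(bf$two_ln_K, 7, tolerance = 1e-12)
  expect_equal(bf$K, exp(3.5), tolerance = 1e-12)
  expect_identical(bf$category, "strong")
  better <- occamfun:::new_model_evidence("gp", -99, "grid", 1, NA,
                                          cbind(0, 1), NULL)
  expect_identical(bayes_factor(better, ref)$category, "against reference")
  expect_identical(bf_category(c(0, 1.99, 2, 5.9, 6, 9.9, 10, 50)),
                   c("not worth a mention", "not worth a mention",
                     "positive", "positive", "strong", "strong",
                     "very strong", "very strong"))
})

test_that("delta_nll_table puts the reference first with delta zero", {
  design <- session_design(exp1_functions()$linear)
  tab <- simulate_session(design, 50, seed = 62)
  zoo <- fit_model_zoo(tab, design$train_regions, degrees = 0:1)
  parts <- split_session(tab)
  out <- delta_nll_table(zoo, parts$test, reference = "polynomial1")
  expect_identical(out$label[1], "polynomial1")
  expect_equal(out$delta_nll[1], 0)
  expect_setequal(out$label, names(zoo))
  expect_equal(out$delta_nll, out$nll - out$nll[1], tolerance = 1e-12)
  expect_error(delta_nll_table(zoo, parts$test, reference = "nope"))
})
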