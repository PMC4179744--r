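#' Fit a polynomial response model by maximum likelihood
#'
#' Ordinary least squares on the Vandermonde design, which is the
#' Gaussian-noise MLE. The residual standard deviation is the MLE
#' (divisor `n`), and the coefficient covariance is
#' `(X'X)^-1 * sigma_hat^2`.
#'
#' @param train Trial table of training trials (uses `x_mm`,
#'   `response_ms`).
#' @param degree Polynomial degree (>= 0). Needs at least `degree + 2`
#'   trials so the residual variance has a degree of freedom.
#' @return A `fitted_model` with fields `family`, `degree`, `params`
#'   (coefficients, ascending degree), `param_covariance`, `residual_sd`.
#' @export
fit_polynomial <- function(train, degree) {
  x <- train$x_mm
  y <- train$response_ms
  m <- degree + 1L
  if (length(x) < m + 1L) stop("need at least degree + 2 training trials")
  V <- design_matrix(x, degree)
  qr_v <- qr(V)
  if (qr_v$rank < m) stop("rank-deficient design: too few distinct x values")
  coef <- qr.coef(qr_v, y)
  resid <- y - V %*% coef
  sigma2 <- sum(resid^2) / length(y)
  cov <- chol2inv(qr.R(qr_v)) * sigma2
  structure(
    list(family = "polynomial", degree = as.integer(degree),
         params = as.numeric(coef), param_covariance = cov,
         residual_sd = sqrt(sigma2), train_regions = NULL),
    class = "fitted_model"
  )
}

# Parameter-propagation variance v' Sigma v at each x for one polynomial fit.
propagation_var <- function(params_cov, degree, x) {
  V <- design_matrix(x, degree)
  rowSums((V %*% params_cov) * V)
}

#' Gaussian predictive distribution of a fitted polynomial
#'
#' The predictive mean is the fitted polynomial at `x_star`. The variance
#' propagates the coefficient covariance, `v' Sigma v` with
#' `v = (1, x*, ..., x*^d)` — for a line this is
#' `var(b0) + var(b1) x*^2 + 2 x* cov(b0, b1)` — plus the residual
#' (observation) variance, so that test-trial likelihoods are proper.
#'
#' @param model A `fitted_model` from [fit_polynomial()].
#' @param x_star Numeric vector of test positions (mm).
#' @return Data frame `x_mm`, `mean_ms`, `sd_ms`, `family`.
#' @export
predict_polynomial <- function(model, x_star) {
  stopifnot(model$family == "polynomial")
  mean <- as.numeric(design_matrix(x_star, model$degree) %*% model$params)
  pv <- propagation_var(model$param_covariance, model$degree, x_star)
  data.frame(x_mm = x_star, mean_ms = mean,
             sd_ms = sqrt(pv + model$residual_sd^2),
             family = paste0("polynomial", model$degree),
             stringsAsFactors = FALSE)
}

# Fit one line per training region; shared by both heuristics.
fit_segments <- function(train, regions) {
  regions <- validate_regions(regions)
  segments <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    sel <- train$x_mm >= regions[i, 1] & train$x_mm <= regions[i, 2]
    if (sum(sel) < 3L) {
      stop(sprintf("region [%g, %g] has fewer than 3 training trials",
                   regions[i, 1], regions[i, 2]))
    }
    seg <- fit_polynomial(train[sel, , drop = FALSE], 1L)
    segments[[i]] <- list(lo = regions[i, 1], hi = regions[i, 2],
                          coef = seg$params, cov = seg$param_covariance,
                          residual_sd = seg$residual_sd)
  }
  segments
}

#' Interpolation heuristic
#'
#' Fits a separate line segment to each training region. Predictions
#' inside a region follow that region's line; between two regions they
#' interpolate linearly between the neighbouring segments' edge values;
#' beyond the outermost regions they stay flat at the nearest segment's
#' value at its outer boundary. This mimics associative-map accounts that
#' interpolate locally but do not extrapolate.
#'
#' @inheritParams fit_polynomial
#' @param regions Training-region matrix (see [session_design()]).
#' @return A `fitted_model` with `family = "interpolation"` carrying the
#'   per-region segment fits.
#' @export
fit_interpolation_heuristic <- function(train, regions) {
  structure(
    list(family = "interpolation", segments = fit_segments(train, regions),
         train_regions = validate_regions(regions)),
    class = "fitted_model"
  )
}

# Segment mean and propagation variance at x (no residual term).
segment_at <- function(seg, x) {
  v <- cbind(1, x)
  list(mean = as.numeric(v %*% seg$coef),
       pvar = rowSums((v %*% seg$cov) * v))
}

# Classify each x against the ordered region list: returns a list with the
# containing-region index (NA if in a gap/flank) and neighbour indices.
locate_x <- function(segments, x) {
  los <- vapply(segments, `[[`, numeric(1), "lo")
  his <- vapply(segments, `[[`, numeric(1), "hi")
  inside <- rep(NA_integer_, length(x))
  for (i in seq_along(segments)) {
    inside[x >= los[i] & x <= his[i]] <- i
  }
  list(inside = inside, los = los, his = his)
}

#' Predict with the interpolation heuristic
#'
#' @param model Result of [fit_interpolation_heuristic()].
#' @param x_star Test positions (mm).
#' @return Data frame `x_mm`, `mean_ms`, `sd_ms`, `family`. Between two
#'   regions the variance combines the two edge predictions as independent
#'   (`w^2 vL + (1-w)^2 vR`) and adds the weight-averaged residual
#'   variance; flank predictions are constant in `x_star`.
#' @export
predict_interpolation <- function(model, x_star) {
  stopifnot(model$family == "interpolation")
  segs <- model$segments
  loc <- locate_x(segs, x_star)
  n <- length(x_star)
  mean <- numeric(n); var <- numeric(n)
  for (k in seq_len(n)) {
    x <- x_star[k]
    i <- loc$inside[k]
    if (!is.na(i)) {
      s <- segment_at(segs[[i]], x)
      mean[k] <- s$mean
      var[k] <- s$pvar + segs[[i]]$residual_sd^2
    } else if (x < loc$los[1]) {
      s <- segment_at(segs[[1]], loc$los[1])
      mean[k] <- s$mean
      var[k] <- s$pvar + segs[[1]]$residual_sd^2
    } else if (x > loc$his[length(segs)]) {
      j <- length(segs)
      s <- segment_at(segs[[j]], loc$his[j])
      mean[k] <- s$mean
      var[k] <- s$pvar + segs[[j]]$residual_sd^2
    } else {
      i <- max(which(loc$his < x))     # left neighbour
      xL <- loc$his[i]; xR <- loc$los[i + 1]
      w <- (xR - x) / (xR - xL)
      sL <- segment_at(segs[[i]], xL)
      sR <- segment_at(segs[[i + 1]], xR)
      mean[k] <- w * sL$mean + (1 - w) * sR$mean
      var[k] <- w^2 * sL$pvar + (1 - w)^2 * sR$pvar +
        w * segs[[i]]$residual_sd^2 + (1 - w) * segs[[i + 1]]$residual_sd^2
    }
  }
  data.frame(x_mm = x_star, mean_ms = mean, sd_ms = sqrt(var),
             family = "interpolation", stringsAsFactors = FALSE)
}

#' Extrapolation heuristic
#'
#' Same per-region line segments as the interpolation heuristic, but
#' predictions extrapolate: peripheral test positions follow the nearest
#' segment's line (variance growing with distance by linear propagation);
#' in a gap flanked by two regions, if the two neighbouring lines
#' intersect inside the gap each line is used on its own side of the
#' intersection, otherwise the gap falls back to linear interpolation.
#' This mirrors partition-based (population-of-linear-experts) accounts.
#'
#' @inheritParams fit_interpolation_heuristic
#' @return A `fitted_model` with `family = "extrapolation"`.
#' @export
fit_extrapolation_heuristic <- function(train, regions) {
  structure(
    list(family = "extrapolation", segments = fit_segments(train, regions),
         train_regions = validate_regions(regions)),
    class = "fitted_model"
  )
}

#' Predict with the extrapolation heuristic
#'
#' @param model Result of [fit_extrapolation_heuristic()].
#' @param x_star Test positions (mm).
#' @return Data frame `x_mm`, `mean_ms`, `sd_ms`, `family`.
#' @export
predict_extrapolation <- function(model, x_star) {
  stopifnot(model$family == "extrapolation")
  segs <- model$segments
  loc <- locate_x(segs, x_star)
  interp <- NULL                       # lazily computed fallback
  n <- length(x_star)
  mean <- numeric(n); var <- numeric(n)
  for (k in seq_len(n)) {
    x <- x_star[k]
    i <- loc$inside[k]
    if (!is.na(i)) {
      s <- segment_at(segs[[i]], x)
      mean[k] <- s$mean
      var[k] <- s$pvar + segs[[i]]$residual_sd^2
      next
    }
    if (x < loc$los[1] || x > loc$his[length(segs)]) {
      # peripheral: nearest segment extrapolated (ties go to the lower-x one)
      d <- pmax(loc$los - x, x - loc$his, 0)
      j <- which.min(d)
      s <- segment_at(segs[[j]], x)
      mean[k] <- s$mean
      var[k] <- s$pvar + segs[[j]]$residual_sd^2
      next
    }
    i <- max(which(loc$his < x))
    xL <- loc$his[i]; xR <- loc$los[i + 1]
    cL <- segs[[i]]$coef; cR <- segs[[i + 1]]$coef
    use_intersection <- FALSE
    if (cL[2] != cR[2]) {
      x_int <- (cR[1] - cL[1]) / (cL[2] - cR[2])
      use_intersection <- x_int >= xL && x_int <= xR
    }
    if (use_intersection) {
      j <- if (x <= x_int) i else i + 1L
      s <- segment_at(segs[[j]], x)
      mean[k] <- s$mean
      var[k] <- s$pvar + segs[[j]]$residual_sd^2
    } else {
      if (is.null(interp)) {
        interp_model <- structure(
          list(family = "interpolation", segments = segs,
               train_regions = model$train_regions),
          class = "fitted_model"
        )
        interp <- predict_interpolation(interp_model, x_star)
      }
      mean[k] <- interp$mean_ms[k]
      var[k] <- interp$sd_ms[k]^2
    }
  }
  data.frame(x_mm = x_star, mean_ms = mean, sd_ms = sqrt(var),
             family = "extrapolation", stringsAsFactors = FALSE)
}

# Squared-exponential kernel matrix.
se_kernel <- function(x1, x2, length_scale, signal_sd) {
  d <- outer(x1, x2, "-")
  signal_sd^2 * exp(-d^2 / (2 * length_scale^2))
}

gp_log_marginal <- function(x, y, length_scale, signal_sd, noise_sd) {
  n <- length(y)
  K <- se_kernel(x, x, length_scale, signal_sd)
  diag(K) <- diag(K) + noise_sd^2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
}

#' Fit squared-exponential GP hyperparameters
#'
#' Maximises the Gaussian-process log marginal likelihood over the three
#' hyperparameters (length scale in mm, signal sd and noise sd in ms) by
#' local optimisation in log space from a small multi-start grid. The GP
#' prior mean is the training-response mean; regression is performed on
#' centred responses.
#'
#' @inheritParams fit_polynomial
#' @param init Optional named list/vector with `length_scale`,
#'   `signal_sd`, `noise_sd` used as an additional start.
#' @return A `fitted_model` with `family = "gp"`, the fitted
#'   hyperparameters, the achieved `log_marginal`, and the training data
#'   (needed for prediction).
#' @export
fit_gp <- function(train, init = NULL) {
  x <- train$x_mm
  y <- train$response_ms
  if (length(x) < 2L) stop("GP fit needs at least 2 training trials")
  ybar <- mean(y)
  yc <- y - ybar
  sy <- max(stats::sd(yc), 1e-6)
  span <- max(diff(range(x)), 1e-6)
  starts <- expand.grid(
    length_scale = span * c(0.05, 0.2, 0.6),
    signal_sd = sy * c(0.5, 1.5),
    noise_sd = sy * c(0.1, 0.5)
  )
  if (!is.null(init)) {
    starts <- rbind(starts, data.frame(length_scale = init$length_scale,
                                       signal_sd = init$signal_sd,
                                       noise_sd = init$noise_sd))
  }
  nlm_obj <- function(logp) {
    -gp_log_marginal(x, yc, exp(logp[1]), exp(logp[2]), exp(logp[3]))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- log(as.numeric(starts[i, ]))
    fit <- tryCatch(
      stats::optim(p0, nlm_obj, method = "Nelder-Mead",
                   control = list(maxit = 300)),
      error = function(e) NULL
    )
    cand <- if (is.null(fit)) list(par = p0, value = nlm_obj(p0)) else fit
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  hp <- exp(best$par)
  structure(
    list(family = "gp",
         length_scale = hp[1], signal_sd = hp[2], noise_sd = hp[3],
         log_marginal = -best$value,
         train_x = x, train_y = y, prior_mean = ybar),
    class = "fitted_model"
  )
}

#' GP predictive distribution
#'
#' Standard squared-exponential GP conditionals; the predictive variance
#' includes the fitted observation-noise variance, so far from the data
#' the predictive sd tends to `sqrt(signal_sd^2 + noise_sd^2)` and the
#' mean tends to the GP prior mean.
#'
#' @param model A `fitted_model` from [fit_gp()].
#' @param x_star Test positions (mm).
#' @return Data frame `x_mm`, `mean_ms`, `sd_ms`, `family`.
#' @export
predict_gp <- function(model, x_star) {
  stopifnot(model$family == "gp")
  x <- model$train_x
  yc <- model$train_y - model$prior_mean
  K <- se_kernel(x, x, model$length_scale, model$signal_sd)
  diag(K) <- diag(K) + model$noise_sd^2
  L <- chol(K)
  Ks <- se_kernel(x, x_star, model$length_scale, model$signal_sd)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  mean <- model$prior_mean + as.numeric(crossprod(Ks, alpha))
  v <- forwardsolve(t(L), Ks)
  var <- pmax(model$signal_sd^2 - colSums(v^2), 0) + model$noise_sd^2
  data.frame(x_mm = x_star, mean_ms = mean, sd_ms = sqrt(var),
             family = "gp", stringsAsFactors = FALSE)
}

#' Predict from any fitted Experiment-1 model
#'
#' Dispatches on the model family.
#'
#' @param model A `fitted_model`.
#' @param x_star Test positions (mm).
#' @return Data frame `x_mm`, `mean_ms`, `sd_ms`, `family`.
#' @export
predict_model <- function(model, x_star) {
  switch(model$family,
    polynomial = predict_polynomial(model, x_star),
    interpolation = predict_interpolation(model, x_star),
    extrapolation = predict_extrapolation(model, x_star),
    gp = predict_gp(model, x_star),
    stop("unknown model family: ", model$family)
  )
}

#' Summed negative log likelihood of test responses
#'
#' Evaluates each test response under its Gaussian predictive
#' distribution and sums the negative log densities. Lower is better; the
#' generating function should minimise it when the observer uses that
#' function.
#'
#' @param predictives Data frame from a `predict_*` function, one row per
#'   test trial, aligned with `test`.
#' @param test Trial table of test trials (uses `response_ms`).
#' @return Summed negative log likelihood (nats); 0 for an empty test set.
#' @export
test_nll <- function(predictives, test) {
  if (nrow(test) == 0L) return(0)
  if (nrow(predictives) != nrow(test)) {
    stop("need exactly one predictive distribution per test trial")
  }
  if (any(predictives$sd_ms <= 0)) stop("predictive sd must be positive")
  -sum(stats::dnorm(test$response_ms, predictives$mean_ms,
                    predictives$sd_ms, log = TRUE))
}

#' Split a stationary session for model fitting
#'
#' Burn-in trials are dropped (the observer is assumed to still be
#' familiarising); the remaining interleaved training trials are the fit
#' set and the interleaved test trials the evaluation set.
#'
#' @param table Trial table of a stationary session.
#' @return List with elements `train` and `test`.
#' @export
split_session <- function(table) {
  inter <- table[table$phase != "burn_in", , drop = FALSE]
  list(train = inter[inter$trial_type == "train", , drop = FALSE],
       test = inter[inter$trial_type == "test", , drop = FALSE])
}

#' Fit the full Experiment-1 model zoo
#'
#' Fits, on the post-burn-in training trials: polynomials of the
#' requested degrees, the interpolation and extrapolation heuristics, and
#' the squared-exponential GP.
#'
#' @param table Trial table of a stationary session.
#' @param regions Training-region matrix.
#' @param degrees Integer vector of polynomial degrees to fit.
#' @return Named list of `fitted_model` objects (names
#'   `polynomial<d>`, `interpolation`, `extrapolation`, `gp`).
#' @export
fit_model_zoo <- function(table, regions, degrees = 0:3) {
  parts <- split_session(table)
  zoo <- list()
  for (d in degrees) {
    zoo[[paste0("polynomial", d)]] <- fit_polynomial(parts$train, d)
  }
  zoo$interpolation <- fit_interpolation_heuristic(parts$train, regions)
  zoo$extrapolation <- fit_extrapolation_heuristic(parts$train, regions)
  zoo$gp <- fit_gp(parts$train)
  zoo
}
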