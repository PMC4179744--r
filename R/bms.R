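#' Polynomial design matrix
#'
#' Row `i` is `(1, x_i, ..., x_i^degree)`.
#'
#' @param x Numeric vector of stimulus positions.
#' @param degree Polynomial degree (>= 0).
#' @return An `n x (degree + 1)` matrix.
#' @export
design_matrix <- function(x, degree) {
  outer(as.numeric(x), 0:degree, `^`)
}

#' Gaussian prior over polynomial coefficients
#'
#' Independent Gaussian priors, one per coefficient (ascending degree).
#' Means are deliberately placed far from any veridical value and the
#' standard deviations are inflated to at least ten times the absolute
#' mean, so the prior location barely influences the marginal likelihood;
#' what remains is the dimensionality penalty that drives model selection.
#'
#' @param mean Numeric vector of prior means, one per coefficient.
#' @param sd Numeric vector of prior standard deviations (> 0). When a
#'   mean is nonzero its sd must be at least `10 * abs(mean)`.
#' @return A `coefficient_prior` with fields `mean`, `sd`, `precision`.
#' @export
coefficient_prior <- function(mean, sd) {
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (length(mean) != length(sd) || any(sd <= 0)) {
    stop("'mean' and 'sd' must have equal length and sd > 0")
  }
  if (any(mean != 0 & sd < 10 * abs(mean))) {
    stop("prior sd must be >= 10 * |mean| for nonzero means")
  }
  structure(list(mean = mean, sd = sd, precision = 1 / sd^2),
            class = "coefficient_prior")
}

#' Default coefficient priors for the candidate polynomial set
#'
#' One prior per candidate degree. Per-coefficient means are
#' `(5000, 50, 5)` ms/mm^d for the constant, linear and quadratic terms —
#' far from every generating-function value — with sds ten times the
#' means.
#'
#' @param degrees Candidate polynomial degrees (default `0:2`).
#' @return Named list of [coefficient_prior()] objects.
#' @export
default_coefficient_priors <- function(degrees = 0:2) {
  mu <- c(5000, 50, 5, 0.5)
  priors <- lapply(degrees, function(d) {
    coefficient_prior(mu[seq_len(d + 1L)], 10 * mu[seq_len(d + 1L)])
  })
  names(priors) <- paste0("degree", degrees)
  priors
}

#' Uniform prior grid over the response-noise standard deviation
#'
#' The observation-noise level is unknown and is marginalised numerically
#' under a uniform prior over `(0, max_sd]` ms, evaluated on an evenly
#' spaced grid with trapezoid weights (normalised to sum to one).
#'
#' @param max_sd Upper end of the noise range (default 5000 ms).
#' @param n Number of grid points (default 500).
#' @return A `noise_prior` with fields `grid` and `weights`.
#' @export
noise_prior <- function(max_sd = 5000, n = 500L) {
  stopifnot(max_sd > 0, n >= 1L)
  grid <- seq(max_sd / n, max_sd, length.out = n)
  w <- if (n == 1L) 1 else {
    w <- rep(1, n); w[c(1, n)] <- 0.5; w / sum(w)
  }
  structure(list(grid = grid, weights = w), class = "noise_prior")
}

#' Log marginal likelihood with coefficients integrated analytically
#'
#' For a polynomial model with independent Gaussian coefficient priors
#' and i.i.d. Gaussian observation noise of known sd `sigma`, the
#' coefficients integrate out in closed form: the responses are jointly
#' Gaussian with mean `F mu` and covariance
#' `sigma^2 I + F diag(sd^2) F'`. The log density is evaluated via the
#' thin SVD of `F diag(sd)` so the cost is `O(n m^2)` regardless of the
#' noise value, which makes the subsequent noise-grid sweep cheap.
#'
#' @param y Response vector (ms).
#' @param x Stimulus positions (mm).
#' @param degree Polynomial degree of the candidate model.
#' @param prior A [coefficient_prior()] with `degree + 1` entries.
#' @param sigma Noise standard deviation(s), ms; vectorised.
#' @return Log marginal likelihood in nats, one value per `sigma`.
#' @export
log_marginal_given_noise <- function(y, x, degree, prior, sigma) {
  stopifnot(inherits(prior, "coefficient_prior"),
            length(prior$mean) == degree + 1L, all(sigma > 0))
  n <- length(y)
  F <- design_matrix(x, degree)
  r <- y - as.numeric(F %*% prior$mean)
  M <- F * rep(prior$sd, each = n)     # F %*% diag(prior sd)
  sv <- svd(M, nu = min(n, ncol(M)), nv = 0)
  lambda <- sv$d^2                     # eigenvalues of F D F'
  cc <- as.numeric(crossprod(sv$u, r))^2
  q0 <- sum(r^2)
  s2 <- sigma^2
  # vectorised over the sigma grid
  logdet <- n * log(s2) +
    colSums(log1p(outer(lambda, s2, `/`)))
  quad <- (q0 - colSums(cc * (lambda / outer(lambda, s2, `+`)))) / s2
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

#' Log marginal likelihood with the noise level marginalised
#'
#' Averages `exp(log_marginal_given_noise)` over the noise grid with the
#' prior's quadrature weights, accumulated in log space.
#'
#' @inheritParams log_marginal_given_noise
#' @param noise A [noise_prior()].
#' @return Log marginal likelihood (nats). `-Inf` (with a warning) if
#'   every grid point underflows.
#' @export
log_marginal <- function(y, x, degree, prior, noise = noise_prior()) {
  stopifnot(inherits(noise, "noise_prior"))
  lp <- log_marginal_given_noise(y, x, degree, prior, noise$grid)
  out <- logsumexp(lp, log(noise$weights))
  if (!is.finite(out)) warning("marginal likelihood underflowed on the whole noise grid")
  out
}

#' Posterior probabilities from per-model log marginals
#'
#' Softmax under a uniform model prior.
#'
#' @param log_marginals Named numeric vector of log marginal likelihoods.
#' @return Named probability vector summing to one.
#' @export
posterior_from_log_marginals <- function(log_marginals) {
  m <- max(log_marginals)
  p <- exp(log_marginals - m)
  p / sum(p)
}

#' Bayesian model selection over the candidate polynomial set
#'
#' Computes each candidate model's marginal likelihood (coefficients
#' integrated analytically, noise numerically) and the posterior simplex
#' under a uniform model prior. With the default candidate set
#' `{constant, linear, quadratic}` the procedure has no free parameters:
#' priors, noise grid and model prior are all fixed by the defaults.
#'
#' @param y Response vector (ms).
#' @param x Stimulus positions (mm).
#' @param degrees Candidate polynomial degrees (default `0:2`).
#' @param priors List of [coefficient_prior()]s, one per degree.
#' @param noise A [noise_prior()].
#' @return A `model_posterior`: list with `posterior` (named probability
#'   vector), `log_marginal` (named vector) and `degenerate` (TRUE when
#'   the window holds fewer observations than the largest model's
#'   coefficient count).
#' @export
model_posteriors <- function(y, x, degrees = 0:2,
                             priors = default_coefficient_priors(degrees),
                             noise = noise_prior()) {
  stopifnot(length(y) >= 1L, length(y) == length(x),
            length(priors) == length(degrees))
  lm <- vapply(seq_along(degrees), function(j) {
    log_marginal(y, x, degrees[j], priors[[j]], noise)
  }, numeric(1))
  names(lm) <- model_labels(degrees)
  structure(
    list(posterior = posterior_from_log_marginals(lm),
         log_marginal = lm,
         degenerate = length(y) < max(degrees) + 1L),
    class = "model_posterior"
  )
}

model_labels <- function(degrees) {
  lab <- c("constant", "linear", "quadratic", "cubic")
  ifelse(degrees <= 3, lab[degrees + 1L], paste0("degree", degrees))
}
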