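# Independent reference implementations used as oracles. These avoid the
# package's fast code paths on purpose: they use dense matrices, direct
# density formulas and explicit quadrature.

lse <- function(x, lw = NULL) {
  if (!is.null(lw)) x <- x + lw
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Dense-covariance oracle: y ~ N(F mu, sigma^2 I + F D F') evaluated with
# a full n x n Cholesky factorisation.
dense_log_marginal_given_noise <- function(y, x, degree, prior, sigma) {
  F <- design_matrix(x, degree)
  n <- length(y)
  S <- sigma^2 * diag(n) + F %*% diag(prior$sd^2, degree + 1L) %*% t(F)
  L <- chol(S)
  r <- y - as.numeric(F %*% prior$mean)
  z <- backsolve(L, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + sum(z^2)) - sum(log(diag(L)))
}

# Brute-force tensor-grid oracle for the coefficient integral
# (likelihood x Gaussian coefficient prior). The grid is laid out in the
# whitened posterior coordinates -- the change of variables is exact, and
# node placement stays well conditioned even when the likelihood spike is
# orders of magnitude narrower than the prior.
grid_log_marginal_given_noise <- function(y, x, degree, prior, sigma,
                                          n_nodes = 61L, half_width = 9) {
  F <- design_matrix(x, degree)
  m <- degree + 1L
  n <- length(y)
  D_inv <- diag(1 / prior$sd^2, m)
  P <- crossprod(F) / sigma^2 + D_inv
  S <- solve(P)
  mu_post <- as.numeric(S %*% (crossprod(F, y) / sigma^2 + D_inv %*% prior$mean))
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  E <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), m)
  log_jac <- 0.5 * sum(log(pmax(eg$values, .Machine$double.xmin)))

  z1 <- seq(-half_width, half_width, length.out = n_nodes)
  w1 <- rep(z1[2] - z1[1], n_nodes)
  w1[c(1, n_nodes)] <- w1[1] / 2
  idx <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), m)))
  Z <- matrix(z1[idx], ncol = m)
  lw <- rowSums(matrix(log(w1)[idx], ncol = m))

  theta <- sweep(Z %*% t(E), 2L, mu_post, `+`)
  resid2 <- rowSums((matrix(y, nrow(theta), n, byrow = TRUE) -
                       theta %*% t(F))^2)
  ll <- -0.5 * n * log(2 * pi * sigma^2) - resid2 / (2 * sigma^2)
  lp <- rowSums(vapply(seq_len(m), function(j) {
    stats::dnorm(theta[, j], prior$mean[j], prior$sd[j], log = TRUE)
  }, numeric(nrow(theta))))
  lse(ll + lp, lw) + log_jac
}

# Fixture set for the analytic-marginal oracle: >= 20 small problems,
# n <= 8, degrees 0-2, assorted prior and noise scales (chosen before any
# outcome was observed).
oracle_fixtures <- function() {
  fixtures <- list()
  set.seed(20240915)
  scales <- list(
    list(xr = 2, prior_mu = c(2, -1, 0.5), sigma = c(0.5, 1, 5)),
    list(xr = 100, prior_mu = c(5000, 50, 5), sigma = c(20, 50, 400))
  )
  for (sc in scales) {
    for (degree in 0:2) {
      for (rep in 1:4) {
        n <- sample(max(degree + 1L, 2L):8L, 1L)
        x <- stats::runif(n, -sc$xr, sc$xr)
        mu <- sc$prior_mu[seq_len(degree + 1L)]
        prior <- coefficient_prior(mu, 10 * abs(mu))
        truth <- mu * stats::runif(degree + 1L, -0.2, 0.2)
        sigma <- sample(sc$sigma, 1L)
        y <- as.numeric(design_matrix(x, degree) %*% truth) +
          stats::rnorm(n, 0, sigma)
        fixtures[[length(fixtures) + 1L]] <-
          list(y = y, x = x, degree = degree, prior = prior, sigma = sigma)
      }
    }
  }
  fixtures
}

# Small window fixtures drawn from the switching-session generating
# functions, reused by the prior-insensitivity tests.
window_fixtures <- function(noise_sd = 50, n = 50L, seeds = 1:4) {
  f <- exp2_functions()
  out <- list()
  for (nm in names(f)) {
    for (s in seeds) {
      set.seed(s * 1000L + match(nm, names(f)))
      x <- stats::runif(n, -100, 100)
      y <- eval_function(f[[nm]], x) + stats::rnorm(n, 0, noise_sd)
      out[[length(out) + 1L]] <- list(x = x, y = y, generating = nm)
    }
  }
  out
}
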