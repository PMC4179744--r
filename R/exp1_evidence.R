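#' Default integration ranges for Experiment-1 marginal likelihoods
#'
#' Uniform parameter priors span roughly two orders of magnitude around
#' the veridical coefficient scales: constant terms +/- 10000 ms, linear
#' terms +/- 100 ms/mm, quadratic +/- 10 ms/mm^2, cubic +/- 1 ms/mm^3.
#' Heuristic segments reuse the constant/linear ranges per segment; GP
#' hyperparameters get broad positive ranges (length scale 0.5-2000 mm —
#' near-linear data can push the fitted length scale well beyond the
#' 200 mm stimulus span — signal and noise sd 0.5-5000 ms).
#'
#' @param model A `fitted_model`.
#' @return Two-column matrix (`lo`, `hi`), one row per parameter.
#' @export
default_parameter_ranges <- function(model) {
  by_degree <- c(10000, 100, 10, 1)
  rng <- function(half) cbind(lo = -half, hi = half)
  switch(model$family,
    polynomial = rng(by_degree[seq_len(model$degree + 1L)]),
    interpolation = ,
    extrapolation = rng(rep(by_degree[1:2], length(model$segments))),
    gp = cbind(lo = c(0.5, 0.5, 0.5), hi = c(2000, 5000, 5000)),
    stop("unknown model family")
  )
}

# MLE vector and per-parameter standard errors used to focus quadrature.
model_theta_hat <- function(model) {
  switch(model$family,
    polynomial = list(mle = model$params,
                      se = sqrt(diag(model$param_covariance))),
    interpolation = ,
    extrapolation = list(
      mle = unlist(lapply(model$segments, `[[`, "coef")),
      se = unlist(lapply(model$segments, function(s) sqrt(diag(s$cov))))
    ),
    gp = list(mle = c(model$length_scale, model$signal_sd, model$noise_sd),
              se = 0.5 * c(model$length_scale, model$signal_sd, model$noise_sd))
  )
}

# Linear map A and plug-in observation sd s such that the test-response
# means are A %*% theta. Exact for polynomials and the interpolation
# heuristic (whose interpolation weights are fixed by the region
# geometry, not by theta).
linear_evaluator <- function(model, x_star) {
  if (model$family == "polynomial") {
    return(list(A = design_matrix(x_star, model$degree),
                s = rep(model$residual_sd, length(x_star))))
  }
  segs <- model$segments
  loc <- locate_x(segs, x_star)
  m <- 2L * length(segs)
  A <- matrix(0, length(x_star), m)
  s2 <- numeric(length(x_star))
  put <- function(row, seg_idx, w, x) {
    cols <- c(2L * seg_idx - 1L, 2L * seg_idx)
    row[cols] <- row[cols] + w * c(1, x)
    row
  }
  for (k in seq_along(x_star)) {
    x <- x_star[k]
    i <- loc$inside[k]
    row <- numeric(m)
    if (!is.na(i)) {
      row <- put(row, i, 1, x)
      s2[k] <- segs[[i]]$residual_sd^2
    } else if (x < loc$los[1]) {
      row <- put(row, 1L, 1, loc$los[1])
      s2[k] <- segs[[1]]$residual_sd^2
    } else if (x > loc$his[length(segs)]) {
      j <- length(segs)
      row <- put(row, j, 1, loc$his[j])
      s2[k] <- segs[[j]]$residual_sd^2
    } else {
      i <- max(which(loc$his < x))
      xL <- loc$his[i]; xR <- loc$los[i + 1]
      w <- (xR - x) / (xR - xL)
      row <- put(row, i, w, xL)
      row <- put(row, i + 1L, 1 - w, xR)
      s2[k] <- w * segs[[i]]$residual_sd^2 + (1 - w) * segs[[i + 1]]$residual_sd^2
    }
    A[k, ] <- row
  }
  list(A = A, s = sqrt(s2))
}

# Per-theta log likelihood of the test set for families whose mean is not
# linear in theta. Returns a function mapping a theta matrix (rows =
# parameter vectors) to a log-likelihood vector.
general_evaluator <- function(model, test) {
  x_star <- test$x_mm
  y <- test$response_ms
  if (model$family == "extrapolation") {
    segs <- model$segments
    # plug-in observation sds from the MLE branch geometry
    s <- sqrt(pmax(predict_extrapolation(model, x_star)$sd_ms^2 -
                     extrap_propagation_var(model, x_star), 1e-12))
    function(theta) {
      apply(theta, 1L, function(th) {
        mu <- extrap_mean_for_theta(segs, th, x_star)
        sum(stats::dnorm(y, mu, s, log = TRUE))
      })
    }
  } else if (model$family == "gp") {
    function(theta) {
      apply(theta, 1L, function(th) {
        m2 <- model
        m2$length_scale <- th[1]; m2$signal_sd <- th[2]; m2$noise_sd <- th[3]
        pr <- predict_gp(m2, x_star)
        sum(stats::dnorm(y, pr$mean_ms, pr$sd_ms, log = TRUE))
      })
    }
  } else {
    stop("no general evaluator for family ", model$family)
  }
}

extrap_propagation_var <- function(model, x_star) {
  pr <- predict_extrapolation(model, x_star)
  # recover the propagation part is branch-dependent; approximate with the
  # residual-free geometry by re-predicting with zeroed residual sds
  m0 <- model
  for (i in seq_along(m0$segments)) m0$segments[[i]]$residual_sd <- 0
  predict_extrapolation(m0, x_star)$sd_ms^2
}

# Mean predictions of the extrapolation heuristic for an arbitrary
# segment-parameter vector th = (int1, slope1, int2, slope2, ...).
extrap_mean_for_theta <- function(segs, th, x_star) {
  segs2 <- segs
  for (i in seq_along(segs2)) {
    segs2[[i]]$coef <- th[c(2L * i - 1L, 2L * i)]
  }
  loc <- locate_x(segs2, x_star)
  mu <- numeric(length(x_star))
  for (k in seq_along(x_star)) {
    x <- x_star[k]
    i <- loc$inside[k]
    if (!is.na(i)) {
      mu[k] <- sum(segs2[[i]]$coef * c(1, x)); next
    }
    if (x < loc$los[1] || x > loc$his[length(segs2)]) {
      d <- pmax(loc$los - x, x - loc$his, 0)
      j <- which.min(d)
      mu[k] <- sum(segs2[[j]]$coef * c(1, x)); next
    }
    i <- max(which(loc$his < x))
    xL <- loc$his[i]; xR <- loc$los[i + 1]
    cL <- segs2[[i]]$coef; cR <- segs2[[i + 1]]$coef
    x_int <- if (cL[2] != cR[2]) (cR[1] - cL[1]) / (cL[2] - cR[2]) else NA_real_
    if (!is.na(x_int) && x_int >= xL && x_int <= xR) {
      cc <- if (x <= x_int) cL else cR
      mu[k] <- sum(cc * c(1, x))
    } else {
      w <- (xR - x) / (xR - xL)
      mu[k] <- w * sum(cL * c(1, xL)) + (1 - w) * sum(cR * c(1, xR))
    }
  }
  mu
}

# Non-uniform trapezoid nodes on [lo, hi]: a coarse cover of the whole
# range plus a dense core around the MLE so a likelihood spike much
# narrower than the prior range is still resolved.
axis_nodes <- function(lo, hi, center, sd_core, n_core = 161L, n_coarse = 41L) {
  core_lo <- max(lo, center - 12 * sd_core)
  core_hi <- min(hi, center + 12 * sd_core)
  nodes <- sort(unique(c(seq(lo, hi, length.out = n_coarse),
                         seq(core_lo, core_hi, length.out = n_core),
                         center)))
  n <- length(nodes)
  w <- numeric(n)
  w[1] <- (nodes[2] - nodes[1]) / 2
  w[n] <- (nodes[n] - nodes[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (nodes[3:n] - nodes[1:(n - 2)]) / 2
  list(nodes = nodes, w = w)
}

# log of integral over the uniform prior box of exp(ll(theta)), for a
# quadratic log likelihood ll(theta) = c0 + b'theta - theta' M theta / 2.
quad_tensor_quadratic <- function(c0, b, M, axes) {
  m <- length(axes)
  if (m == 1L) {
    t1 <- axes[[1]]$nodes
    ll <- c0 + b[1] * t1 - 0.5 * M[1, 1] * t1^2
    return(logsumexp(ll, log(axes[[1]]$w)))
  }
  if (m == 2L) {
    t1 <- axes[[1]]$nodes; t2 <- axes[[2]]$nodes
    g1 <- b[1] * t1 - 0.5 * M[1, 1] * t1^2
    g2 <- b[2] * t2 - 0.5 * M[2, 2] * t2^2
    ll <- c0 + outer(g1, g2, `+`) - M[1, 2] * outer(t1, t2)
    lw <- outer(log(axes[[1]]$w), log(axes[[2]]$w), `+`)
    return(logsumexp(as.numeric(ll), as.numeric(lw)))
  }
  if (m == 3L) {
    t1 <- axes[[1]]$nodes; t2 <- axes[[2]]$nodes; t3 <- axes[[3]]$nodes
    g1 <- b[1] * t1 - 0.5 * M[1, 1] * t1^2
    g2 <- b[2] * t2 - 0.5 * M[2, 2] * t2^2
    base <- outer(g1, g2, `+`) - M[1, 2] * outer(t1, t2)
    lw12 <- outer(log(axes[[1]]$w), log(axes[[2]]$w), `+`)
    parts <- vapply(seq_along(t3), function(k) {
      tk <- t3[k]
      ll <- c0 + base + tk * (b[3] - M[1, 3] * t1) - 0.5 * M[3, 3] * tk^2
      ll <- ll - M[2, 3] * tk * rep(t2, each = length(t1))
      logsumexp(as.numeric(ll), as.numeric(lw12))
    }, numeric(1))
    return(logsumexp(parts, log(axes[[3]]$w)))
  }
  stop("tensor quadrature supports at most 3 parameters")
}

#' Marginal likelihood of test data by numerical integration
#'
#' Integrates the test-set likelihood of a fitted Experiment-1 model over
#' a uniform prior box on its parameters. Models whose predictions are
#' linear in the parameters (polynomials, interpolation heuristic) with
#' up to three parameters use deterministic tensor-grid quadrature on
#' MLE-refined trapezoid nodes; higher-dimensional and non-linear
#' families (cubic polynomial, heuristic segments, extrapolation, GP) use
#' seeded importance-sampling Monte Carlo with a defensive
#' uniform/Gaussian mixture proposal. Observation noise enters as the
#' plug-in residual sd from the training fit.
#'
#' @param model A `fitted_model`.
#' @param test Test-trial table (uses `x_mm`, `response_ms`).
#' @param ranges Two-column matrix of per-parameter uniform-prior bounds;
#'   must contain the MLE. Defaults to [default_parameter_ranges()].
#' @param seed Integer seed for Monte-Carlo paths.
#' @param method `"auto"` (default), `"grid"` or `"mc"`.
#' @param n_mc Monte-Carlo sample count (default 1e5).
#' @return A `model_evidence`: `label`, `log_marginal` (nats),
#'   `method`, `n_eval`, `mc_rel_se` (NA for grids), `ranges`, `seed`.
#' @export
marginal_likelihood_numeric <- function(model, test, ranges = NULL,
                                        seed = NULL,
                                        method = c("auto", "grid", "mc"),
                                        n_mc = 1e5L) {
  method <- match.arg(method)
  if (is.null(ranges)) ranges <- default_parameter_ranges(model)
  ranges <- as.matrix(ranges)
  th <- model_theta_hat(model)
  m <- length(th$mle)
  stopifnot(nrow(ranges) == m)
  if (any(th$mle < ranges[, 1] | th$mle > ranges[, 2])) {
    stop("MLE lies outside the integration ranges; widen the ranges")
  }
  log_prior <- -sum(log(ranges[, 2] - ranges[, 1]))
  label <- if (model$family == "polynomial") {
    paste0("polynomial", model$degree)
  } else model$family
  se <- pmax(th$se, 1e-9)
  linear <- model$family %in% c("polynomial", "interpolation")

  if (method == "auto") {
    method <- if (m <= 3L) "grid" else "mc"
  }
  if (method == "grid" && m > 3L) method <- "mc"

  if (method == "grid" && linear) {
    ev <- linear_evaluator(model, test$x_mm)
    yt <- test$response_ms / ev$s
    At <- ev$A / ev$s
    c0 <- -0.5 * sum(yt^2) - sum(log(sqrt(2 * pi) * ev$s))
    b <- as.numeric(crossprod(At, yt))
    M <- crossprod(At)
    axes <- lapply(seq_len(m), function(j) {
      axis_nodes(ranges[j, 1], ranges[j, 2], th$mle[j], se[j])
    })
    lZ <- quad_tensor_quadratic(c0, b, M, axes) + log_prior
    n_eval <- prod(vapply(axes, function(a) length(a$nodes), numeric(1)))
    return(new_model_evidence(label, lZ, "grid", n_eval, NA_real_, ranges, seed))
  }

  if (method == "grid") {                      # non-linear family, m <= 3
    llfun <- general_evaluator(model, test)
    axes <- lapply(seq_len(m), function(j) {
      axis_nodes(ranges[j, 1], ranges[j, 2], th$mle[j], se[j],
                 n_core = 13L, n_coarse = 9L)
    })
    grid <- as.matrix(expand.grid(lapply(axes, `[[`, "nodes")))
    lw <- as.numeric(Reduce(function(a, b) outer(a, b, `+`),
                            lapply(axes, function(a) log(a$w))))
    ll <- llfun(grid)
    lZ <- logsumexp(ll, lw) + log_prior
    return(new_model_evidence(label, lZ, "grid", nrow(grid), NA_real_,
                              ranges, seed))
  }

  # importance-sampling Monte Carlo
  with_seed(seed, {
    n_mc <- as.integer(n_mc)
    vol <- prod(ranges[, 2] - ranges[, 1])
    from_unif <- stats::runif(n_mc) < 0.5
    theta <- matrix(0, n_mc, m)
    for (j in seq_len(m)) {
      theta[, j] <- ifelse(from_unif,
                           stats::runif(n_mc, ranges[j, 1], ranges[j, 2]),
                           stats::rnorm(n_mc, th$mle[j], 3 * se[j]))
    }
    inside <- rep(TRUE, n_mc)
    for (j in seq_len(m)) {
      inside <- inside & theta[, j] >= ranges[j, 1] & theta[, j] <= ranges[j, 2]
    }
    lq <- numeric(n_mc)
    dens_n <- matrix(0, n_mc, m)
    for (j in seq_len(m)) {
      dens_n[, j] <- stats::dnorm(theta[, j], th$mle[j], 3 * se[j], log = TRUE)
    }
    lq <- log(0.5 / vol + 0.5 * exp(rowSums(dens_n)))
    ll <- rep(-Inf, n_mc)
    if (linear) {
      ev <- linear_evaluator(model, test$x_mm)
      yt <- test$response_ms / ev$s
      At <- ev$A / ev$s
      c0 <- -0.5 * sum(yt^2) - sum(log(sqrt(2 * pi) * ev$s))
      ll[inside] <- c0 + theta[inside, , drop = FALSE] %*% crossprod(At, yt) -
        0.5 * rowSums((theta[inside, , drop = FALSE] %*% crossprod(At)) *
                        theta[inside, , drop = FALSE])
    } else {
      llfun <- general_evaluator(model, test)
      ll[inside] <- llfun(theta[inside, , drop = FALSE])
    }
    lterm <- ll - log(vol) - lq           # log( L * prior / q )
    lZ <- logsumexp(lterm) - log(n_mc)
    terms <- exp(lterm - lZ)              # normalised IS weights * L
    rel_se <- stats::sd(terms) / sqrt(n_mc)
    new_model_evidence(label, lZ, "mc", n_mc, rel_se, ranges, seed)
  })
}

new_model_evidence <- function(label, log_marginal, method, n_eval,
                               mc_rel_se, ranges, seed) {
  structure(
    list(label = label, log_marginal = log_marginal, method = method,
         n_eval = n_eval, mc_rel_se = mc_rel_se, ranges = ranges,
         seed = seed),
    class = "model_evidence"
  )
}

#' Bayes factor of the reference (generating) function against a model
#'
#' `K = exp(log_marginal_reference - log_marginal_model)`, so `K > 1`
#' favours the reference. `2 ln K` is graded on the conventional
#' evidence scale: 0-2 not worth a mention, 2-6 positive, 6-10 strong,
#' above 10 very strong (bins right-open). Negative values indicate
#' evidence against the reference and are categorised as
#' `"against reference"`.
#'
#' @param evidence_model,evidence_reference `model_evidence` objects for
#'   the same test data.
#' @return A `bayes_factor_report`: `K`, `two_ln_K`, `category`.
#' @export
bayes_factor <- function(evidence_model, evidence_reference) {
  two_ln_K <- 2 * (evidence_reference$log_marginal - evidence_model$log_marginal)
  structure(
    list(K = exp(two_ln_K / 2), two_ln_K = two_ln_K,
         category = bf_category(two_ln_K)),
    class = "bayes_factor_report"
  )
}

#' @rdname bayes_factor
#' @param two_ln_K Numeric vector of `2 ln K` values.
#' @export
bf_category <- function(two_ln_K) {
  cut_pts <- c(0, 2, 6, 10, Inf)
  labels <- c("not worth a mention", "positive", "strong", "very strong")
  out <- character(length(two_ln_K))
  neg <- two_ln_K < 0
  out[neg] <- "against reference"
  out[!neg] <- labels[findInterval(two_ln_K[!neg], cut_pts,
                                   rightmost.closed = TRUE)]
  out
}

#' Delta-NLL comparison table
#'
#' Summed test negative log likelihood of every model minus that of the
#' reference (generating-function) model. Positive values mean the model
#' predicts the test responses worse than the reference.
#'
#' @param models Named list of `fitted_model`s.
#' @param test Test-trial table; all models are evaluated on it.
#' @param reference Name (in `models`) of the reference model.
#' @param evidences Optional named list of `model_evidence` objects; when
#'   provided (including the reference), a `two_ln_k` column is added.
#' @return Data frame `label`, `nll`, `delta_nll` (and `two_ln_k`,
#'   `category` if evidences are given), sorted by label with the
#'   reference row first.
#' @export
delta_nll_table <- function(models, test, reference, evidences = NULL) {
  stopifnot(reference %in% names(models))
  nll <- vapply(models, function(mod) {
    test_nll(predict_model(mod, test$x_mm), test)
  }, numeric(1))
  out <- data.frame(label = names(models), nll = as.numeric(nll),
                    delta_nll = as.numeric(nll - nll[[reference]]),
                    stringsAsFactors = FALSE)
  if (!is.null(evidences)) {
    stopifnot(reference %in% names(evidences))
    ref_ev <- evidences[[reference]]
    out$two_ln_k <- vapply(out$label, function(lab) {
      if (!lab %in% names(evidences)) return(NA_real_)
      bayes_factor(evidences[[lab]], ref_ev)$two_ln_K
    }, numeric(1))
    out$category <- ifelse(is.na(out$two_ln_k), NA_character_,
                           bf_category(out$two_ln_k))
  }
  ord <- order(out$label != reference, out$label)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
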