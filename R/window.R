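#' Sliding window frames
#'
#' All contiguous spans of `W` trials, step 1. A session of `n` trials
#' yields `n - W + 1` frames; each frame is anchored (reported) at its
#' last trial so that time courses are causal.
#'
#' @param n_trials Session length.
#' @param W Window width (default 50).
#' @return Data frame `frame`, `start`, `end`.
#' @export
sliding_windows <- function(n_trials, W = 50L) {
  n_trials <- as.integer(n_trials); W <- as.integer(W)
  if (W > n_trials) stop("window width exceeds the number of trials")
  if (W < 1L) stop("window width must be >= 1")
  starts <- seq_len(n_trials - W + 1L)
  data.frame(frame = starts, start = starts, end = starts + W - 1L)
}

#' Posterior time course over a sliding window
#'
#' Runs [model_posteriors()] on every window frame of a session and
#' returns the per-frame posterior simplex over the candidate set,
#' anchored at the frame's last trial.
#'
#' @param table Trial table with responses on all trials.
#' @param W Window width (default 50).
#' @param degrees,priors,noise Passed to [model_posteriors()].
#' @return A `posterior_timecourse`: data frame with `frame`,
#'   `last_trial`, one `p_<label>` column per candidate model, and the
#'   per-model log marginals as attribute `"log_marginal"` (matrix).
#' @export
posterior_timecourse <- function(table, W = 50L, degrees = 0:2,
                                 priors = default_coefficient_priors(degrees),
                                 noise = noise_prior()) {
  if (anyNA(table$response_ms)) stop("all trials must carry responses")
  frames <- sliding_windows(nrow(table), W)
  labels <- model_labels(degrees)
  post <- matrix(NA_real_, nrow(frames), length(degrees))
  logm <- matrix(NA_real_, nrow(frames), length(degrees))
  for (f in seq_len(nrow(frames))) {
    idx <- frames$start[f]:frames$end[f]
    mp <- model_posteriors(table$response_ms[idx], table$x_mm[idx],
                           degrees, priors, noise)
    post[f, ] <- mp$posterior
    logm[f, ] <- mp$log_marginal
  }
  out <- data.frame(frame = frames$frame, last_trial = frames$end)
  for (j in seq_along(labels)) out[[paste0("p_", labels[j])]] <- post[, j]
  attr(out, "log_marginal") <- `colnames<-`(logm, labels)
  attr(out, "W") <- as.integer(W)
  attr(out, "anchor") <- "trailing"
  class(out) <- c("posterior_timecourse", class(out))
  out
}

#' Default coefficient search ranges for windowed MLE
#'
#' Two orders of magnitude beyond the veridical scales: constant term
#' -10000..10000 ms, linear -100..100 ms/mm, quadratic -10..10 ms/mm^2.
#'
#' @param degree Polynomial degree.
#' @return Two-column matrix `lo`, `hi`, one row per coefficient.
#' @export
default_search_ranges <- function(degree) {
  half <- c(10000, 100, 10, 1)[seq_len(degree + 1L)]
  cbind(lo = -half, hi = half)
}

# Windowed MLE for one polynomial model: OLS if inside the box, otherwise
# bound-constrained least squares. The noise sd is re-estimated in every
# window as the residual MLE.
window_mle <- function(y, x, degree, ranges) {
  V <- design_matrix(x, degree)
  qr_v <- qr(V)
  theta <- tryCatch(qr.coef(qr_v, y), error = function(e) NULL)
  if (is.null(theta) || anyNA(theta) ||
      any(theta < ranges[, 1] | theta > ranges[, 2])) {
    start <- pmin(pmax(if (is.null(theta) || anyNA(theta)) {
      rep(0, degree + 1L)
    } else theta, ranges[, 1]), ranges[, 2])
    obj <- function(th) sum((y - V %*% th)^2)
    fit <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = ranges[, 1], upper = ranges[, 2])
    theta <- fit$par
  }
  resid <- y - V %*% theta
  list(theta = as.numeric(theta), noise_sd = sqrt(sum(resid^2) / length(y)))
}

#' Windowed maximum-likelihood parameter trajectories
#'
#' Per window frame and candidate model, the coefficient vector that
#' maximises the window likelihood, with the noise level re-estimated in
#' every window. Unconstrained OLS solutions are accepted when they fall
#' inside the search box; otherwise a bound-constrained search is used.
#' Trajectories are also returned smoothed with [smooth_trajectory()].
#'
#' @param table Trial table.
#' @param W Window width (default 50).
#' @param degrees Candidate polynomial degrees.
#' @param search_ranges List of range matrices, one per degree (defaults
#'   to [default_search_ranges()]).
#' @param smooth_radius Gaussian kernel radius for the smoothed variant.
#' @return Long data frame `frame`, `last_trial`, `model`, `term_degree`,
#'   `mle`, `smoothed`, plus a `noise_sd` column with the per-window noise
#'   MLE of that model.
#' @export
mle_parameter_timecourse <- function(table, W = 50L, degrees = 0:2,
                                     search_ranges = lapply(degrees, default_search_ranges),
                                     smooth_radius = 5L) {
  frames <- sliding_windows(nrow(table), W)
  labels <- model_labels(degrees)
  rows <- list()
  for (j in seq_along(degrees)) {
    d <- degrees[j]
    est <- matrix(NA_real_, nrow(frames), d + 1L)
    nsd <- numeric(nrow(frames))
    for (f in seq_len(nrow(frames))) {
      idx <- frames$start[f]:frames$end[f]
      fit <- window_mle(table$response_ms[idx], table$x_mm[idx], d,
                        search_ranges[[j]])
      est[f, ] <- fit$theta
      nsd[f] <- fit$noise_sd
    }
    for (term in 0:d) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = frames$frame, last_trial = frames$end,
        model = labels[j], term_degree = term,
        mle = est[, term + 1L],
        smoothed = smooth_trajectory(est[, term + 1L], smooth_radius),
        noise_sd = nsd,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian kernel smoothing of a trajectory
#'
#' Discrete Gaussian kernel with sd equal to `radius` data points,
#' truncated at three sds and renormalised where it overhangs the series
#' edges. A constant series is returned unchanged and a linear ramp is
#' preserved in the interior (kernel symmetry).
#'
#' @param series Numeric vector.
#' @param radius Kernel sd in data points (default 5).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_trajectory <- function(series, radius = 5L) {
  n <- length(series)
  if (n == 0L || radius <= 0) return(series)
  half <- ceiling(3 * radius)
  kern <- stats::dnorm(-half:half, 0, radius)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    k <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(series[lo:hi] * k) / sum(k)
  }
  out
}

#' Mean in-segment posterior (extent of selection)
#'
#' For each generating function of a switching session, the mean
#' posterior probability of that function over the frames anchored inside
#' its segment (including the frames of the first segment, where learning
#' may still be incomplete).
#'
#' @param timecourse A [posterior_timecourse()] result.
#' @param design The [switch_design()] that generated the session.
#' @return Data frame `segment`, `model`, `extent`.
#' @export
selection_extent <- function(timecourse, design) {
  stopifnot(inherits(design, "switch_design"))
  if (max(timecourse$last_trial) > design$n_trials) {
    stop("time course longer than the design")
  }
  seg <- active_function_index(design, timecourse$last_trial)
  labels <- names(design$function_sequence)
  if (is.null(labels)) {
    labels <- vapply(design$function_sequence, function(f) {
      model_labels(f$degree)
    }, character(1))
  }
  out <- lapply(seq_along(design$function_sequence), function(k) {
    col <- paste0("p_", model_labels(design$function_sequence[[k]]$degree))
    if (!col %in% names(timecourse)) {
      stop("candidate set lacks a model matching segment ", k)
    }
    data.frame(segment = k, model = labels[k],
               extent = mean(timecourse[[col]][seg == k]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
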