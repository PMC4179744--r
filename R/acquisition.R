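transition_letter <- function(degree) c("C", "L", "Q", "X")[degree + 1L]

#' Trials to reach a posterior selection threshold after a switch
#'
#' The acquisition clock starts at the switch trial: the acquisition time
#' is the smallest `k >= 1` such that the frame anchored at trial
#' `switch_trial + k` assigns the correct (incoming) model a posterior at
#' or above `threshold`. If the threshold is never reached before the
#' segment ends the result is censored.
#'
#' @param timecourse A [posterior_timecourse()].
#' @param switch_trial Trial after which the new function became active.
#' @param correct_model Label of the incoming model (e.g. `"linear"`),
#'   matching a `p_<label>` column.
#' @param threshold Posterior threshold in (0, 1).
#' @param segment_end Last trial of the post-switch segment (defaults to
#'   the end of the time course).
#' @return List `trials` (integer or `NA`), `censored` (logical).
#' @export
acquisition_time <- function(timecourse, switch_trial, correct_model,
                             threshold,
                             segment_end = max(timecourse$last_trial)) {
  stopifnot(threshold > 0, threshold < 1)
  col <- paste0("p_", correct_model)
  if (!col %in% names(timecourse)) stop("no posterior column for ", correct_model)
  sel <- timecourse$last_trial > switch_trial &
    timecourse$last_trial <= segment_end
  lt <- timecourse$last_trial[sel]
  p <- timecourse[[col]][sel]
  hit <- which(p >= threshold)
  if (length(hit) == 0L) {
    list(trials = NA_integer_, censored = TRUE)
  } else {
    list(trials = as.integer(lt[min(hit)] - switch_trial), censored = FALSE)
  }
}

#' Acquisition times for every switch of a session
#'
#' @param timecourse A [posterior_timecourse()].
#' @param design The session's [switch_design()].
#' @param thresholds Posterior thresholds (default
#'   `c(0.33, 0.5, 0.66, 0.99)`).
#' @return Data frame `transition` (e.g. `"CL"` = constant-to-linear),
#'   `from`, `to`, `threshold`, `trials`, `censored`.
#' @export
extract_acquisitions <- function(timecourse, design,
                                 thresholds = c(0.33, 0.5, 0.66, 0.99)) {
  stopifnot(inherits(design, "switch_design"))
  degs <- vapply(design$function_sequence, `[[`, integer(1), "degree")
  ends <- c(design$switch_trials[-1], design$n_trials)
  rows <- list()
  for (k in seq_along(design$switch_trials)) {
    from_d <- degs[k]; to_d <- degs[k + 1L]
    for (th in thresholds) {
      at <- acquisition_time(timecourse, design$switch_trials[k],
                             model_labels(to_d), th, ends[k])
      rows[[length(rows) + 1L]] <- data.frame(
        transition = paste0(transition_letter(from_d), transition_letter(to_d)),
        from = model_labels(from_d), to = model_labels(to_d),
        threshold = th, trials = at$trials, censored = at$censored,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Default switching-session group designs
#'
#' Four groups covering all six ordered transitions between the constant,
#' linear and quadratic generating functions: G1 C-L-Q, G2 Q-L-C,
#' G3 C-Q-L, G4 Q-C-L, each with switches after trials 100 and 250 in a
#' 500-trial session.
#'
#' @return Named list of [switch_design()]s.
#' @export
default_switch_designs <- function() {
  f <- exp2_functions()
  seqs <- list(
    G1 = f[c("constant", "linear", "quadratic")],
    G2 = f[c("quadratic", "linear", "constant")],
    G3 = f[c("constant", "quadratic", "linear")],
    G4 = f[c("quadratic", "constant", "linear")]
  )
  lapply(seqs, switch_design)
}

#' Omniscient-observer acquisition baseline
#'
#' Monte-Carlo baseline for interpreting acquisition times: a simulated
#' observer that knows the generating functions, their parameters and the
#' switch schedule responds with truth-plus-noise; each run is pushed
#' through the same windowed model-selection analysis as real data and
#' acquisition times are extracted. Runs are spread round-robin over the
#' supplied designs so all transition directions are sampled.
#'
#' @param designs List of [switch_design()]s (default
#'   [default_switch_designs()]).
#' @param noise_sds Noise levels to simulate (ms); the first one is the
#'   primary level, the rest are sensitivity output.
#' @param runs Monte-Carlo runs per noise level (default 500).
#' @param W Window width.
#' @param thresholds Posterior thresholds.
#' @param seed Integer seed; every run derives its own child seed.
#' @param degrees,priors,noise Model-selection settings, as in
#'   [posterior_timecourse()].
#' @return List with `raw` (one row per run x transition x threshold:
#'   `noise_sd`, `run`, `design`, `transition`, `threshold`, `trials`,
#'   `censored`) and `summary` (per `noise_sd` x `transition` x
#'   `threshold`: mean/sd of uncensored times and censoring count).
#' @export
simulated_baseline <- function(designs = default_switch_designs(),
                               noise_sds = c(10, 30, 50, 100, 150, 200, 400),
                               runs = 500L, W = 50L, thresholds = 0.33,
                               seed = 1L, degrees = 0:2,
                               priors = default_coefficient_priors(degrees),
                               noise = noise_prior()) {
  stopifnot(runs >= 1L)
  raw <- list()
  for (si in seq_along(noise_sds)) {
    sd_i <- noise_sds[si]
    for (r in seq_len(runs)) {
      di <- (r - 1L) %% length(designs) + 1L
      design <- designs[[di]]
      tab <- simulate_session(design, sd_i,
                              child_seed(seed, si * 100003L + r))
      tc <- posterior_timecourse(tab, W, degrees, priors, noise)
      acq <- extract_acquisitions(tc, design, thresholds)
      acq$noise_sd <- sd_i
      acq$run <- r
      acq$design <- names(designs)[di] %||% paste0("design", di)
      raw[[length(raw) + 1L]] <- acq
    }
  }
  raw <- do.call(rbind, raw)
  summary <- stats::aggregate(
    trials ~ noise_sd + transition + threshold, data = raw,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)),
    na.action = stats::na.omit
  )
  summary <- cbind(summary[1:3], as.data.frame(summary$trials))
  cens <- stats::aggregate(censored ~ noise_sd + transition + threshold,
                           data = raw, FUN = sum)
  names(cens)[4] <- "n_censored"
  summary <- merge(summary, cens,
                   by = c("noise_sd", "transition", "threshold"))
  list(raw = raw, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Acquisition-time asymmetry per transition pair
#'
#' For each complexity pair (constant/linear, linear/quadratic,
#' constant/quadratic) present in both directions, the per-id difference
#' of mean acquisition times between the complexifying direction (toward
#' the higher-degree function, e.g. CL) and the simplifying direction
#' (e.g. LC). The default orientation is complex-minus-simple (CL - LC);
#' set `orientation = "simple_minus_complex"` for the opposite (LC - CL)
#' reporting convention. The orientation is recorded on the result.
#'
#' @param results Data frame with columns `transition`, `trials`,
#'   `censored` and an id column.
#' @param id Name of the id column (participant or run), default `"run"`.
#' @param orientation `"complex_minus_simple"` (default) or
#'   `"simple_minus_complex"`.
#' @return Data frame `pair`, id, `diff` (`NA` when one direction is
#'   entirely censored for that id), with attribute `"orientation"`.
#' @export
transition_differences <- function(results, id = "run",
                                   orientation = c("complex_minus_simple",
                                                   "simple_minus_complex")) {
  orientation <- match.arg(orientation)
  order_c <- c(C = 1, L = 2, Q = 3)
  tr <- as.character(results$transition)
  from <- substr(tr, 1, 1); to <- substr(tr, 2, 2)
  complexifying <- order_c[to] > order_c[from]
  pair_label <- ifelse(complexifying, tr, paste0(to, from))  # complex dir name
  rows <- list()
  for (p in sort(unique(pair_label))) {
    simple_dir <- paste0(substr(p, 2, 2), substr(p, 1, 1))
    sub <- results[pair_label == p, , drop = FALSE]
    for (i in sort(unique(sub[[id]]))) {
      si <- sub[sub[[id]] == i, , drop = FALSE]
      cx <- si$trials[si$transition == p & !si$censored]
      sp <- si$trials[si$transition == simple_dir & !si$censored]
      has_cx <- any(si$transition == p)
      has_sp <- any(si$transition == simple_dir)
      if (!has_cx || !has_sp) next   # this id never saw one direction
      d <- if (length(cx) == 0L || length(sp) == 0L) {
        NA_real_                     # fully censored direction
      } else {
        mean(cx) - mean(sp)
      }
      if (orientation == "simple_minus_complex" && !is.na(d)) d <- -d
      rows[[length(rows) + 1L]] <-
        data.frame(pair = p, id = i, diff = d, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(0), id = integer(0), diff = numeric(0))
  names(out)[2] <- id
  attr(out, "orientation") <- orientation
  out
}

#' One-sample t-test of participant differences against a baseline
#'
#' Two-tailed one-sample t-test of per-participant acquisition-time
#' differences against the simulated-baseline difference, computed from
#' the textbook formula `t = (mean(x) - mu) / (sd(x) / sqrt(n))` with
#' `n - 1` degrees of freedom.
#'
#' @param participant_diffs Numeric vector, one difference per
#'   participant.
#' @param baseline_diff The baseline difference (scalar).
#' @return List `t`, `dof`, `p`, `mean_diff`, `baseline_diff`.
#' @export
compare_to_baseline <- function(participant_diffs, baseline_diff) {
  x <- participant_diffs[!is.na(participant_diffs)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 participants")
  s <- stats::sd(x)
  delta <- mean(x) - baseline_diff
  if (s == 0) {
    warning("zero variance across participants; t is infinite")
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    t_stat <- delta / (s / sqrt(n))
  }
  p <- if (is.infinite(t_stat)) 0 else if (t_stat == 0 && s == 0) 1 else
    2 * stats::pt(-abs(t_stat), n - 1L)
  list(t = t_stat, dof = n - 1L, p = p,
       mean_diff = mean(x), baseline_diff = baseline_diff)
}

#' Acquisition table across selection thresholds
#'
#' Applies [extract_acquisitions()] at each threshold. For any monotone
#' posterior trajectory the time to threshold is non-decreasing in the
#' threshold, and censoring can only increase.
#'
#' @param timecourse A [posterior_timecourse()].
#' @param design The session's [switch_design()].
#' @param thresholds Posterior thresholds (default
#'   `c(0.33, 0.5, 0.66, 0.99)`).
#' @return Data frame as in [extract_acquisitions()].
#' @export
threshold_sweep <- function(timecourse, design,
                            thresholds = c(0.33, 0.5, 0.66, 0.99)) {
  extract_acquisitions(timecourse, design, thresholds)
}
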