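#' Experiment designs
#'
#' `session_design()` describes a stationary interception session: one
#' hidden generating function, disjoint training and test regions along
#' the cue axis, a block of burn-in training trials, and an interleaved
#' block alternating test and training trials. `switch_design()` describes
#' a non-stationary session in which the generating function is replaced
#' covertly at fixed trials while stimuli are sampled uniformly over the
#' whole span.
#'
#' Regions are matrices with one row per closed interval and columns
#' `lo`, `hi` (mm). Defaults follow the task geometry: a 200 mm span
#' centred on 0.
#'
#' @param generating A [polynomial_function()].
#' @param train_regions,test_regions Two-column matrices of disjoint
#'   closed x-intervals (mm).
#' @param n_burn_in Number of initial training-only trials (default 50).
#' @param n_interleaved Number of subsequent trials alternating test and
#'   train (default 120, i.e. 60 of each).
#' @return A `session_design` object.
#' @seealso [region_preset()] for the two built-in region layouts.
#' @export
session_design <- function(generating,
                           train_regions = region_preset("interpolation")$train,
                           test_regions = region_preset("interpolation")$test,
                           n_burn_in = 50L,
                           n_interleaved = 120L) {
  stopifnot(inherits(generating, "polynomial_function"))
  train_regions <- validate_regions(train_regions)
  test_regions <- validate_regions(test_regions)
  if (regions_overlap(train_regions, test_regions)) {
    stop("train and test regions must be disjoint")
  }
  structure(
    list(generating = generating,
         train_regions = train_regions, test_regions = test_regions,
         n_burn_in = as.integer(n_burn_in),
         n_interleaved = as.integer(n_interleaved)),
    class = "session_design"
  )
}

#' @param function_sequence List of three [polynomial_function()]s, active
#'   in order.
#' @param switch_trials Integer vector; function `k + 1` becomes active
#'   from trial `switch_trials[k] + 1` (1-based). Default `c(100, 250)`.
#' @param n_trials Session length (default 500).
#' @param span Two-element numeric, the sampled x-range in mm.
#' @rdname session_design
#' @export
switch_design <- function(function_sequence,
                          switch_trials = c(100L, 250L),
                          n_trials = 500L,
                          span = c(-100, 100)) {
  stopifnot(is.list(function_sequence),
            all(vapply(function_sequence, inherits, TRUE, "polynomial_function")))
  switch_trials <- as.integer(switch_trials)
  n_trials <- as.integer(n_trials)
  if (length(function_sequence) != length(switch_trials) + 1L) {
    stop("need one more function than switch trials")
  }
  if (is.unsorted(switch_trials, strictly = TRUE) || any(switch_trials >= n_trials) ||
      any(switch_trials < 1L)) {
    stop("'switch_trials' must be strictly increasing and < n_trials")
  }
  structure(
    list(function_sequence = function_sequence,
         switch_trials = switch_trials, n_trials = n_trials,
         span = as.numeric(span)),
    class = "switch_design"
  )
}

#' Built-in training/test region layouts
#'
#' `"interpolation"`: three training intervals `[-100,-60]`, `[-20,20]`,
#' `[60,100]` with the two interior gaps as test regions, so every test
#' stimulus is flanked by trained regions. `"extrapolation"`: two central
#' training intervals `[-60,-20]`, `[20,60]` with the central gap and both
#' peripheral flanks as test regions, exercising extrapolation beyond the
#' trained range.
#'
#' @param name `"interpolation"` or `"extrapolation"`.
#' @return List with `train` and `test` region matrices.
#' @export
region_preset <- function(name = c("interpolation", "extrapolation")) {
  name <- match.arg(name)
  reg <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("lo", "hi")
    m
  }
  switch(name,
    interpolation = list(
      train = reg(-100, -60, -20, 20, 60, 100),
      test  = reg(-60, -20, 20, 60)
    ),
    extrapolation = list(
      train = reg(-60, -20, 20, 60),
      test  = reg(-100, -60, -20, 20, 60, 100)
    )
  )
}

validate_regions <- function(regions) {
  regions <- as.matrix(regions)
  if (ncol(regions) != 2L || nrow(regions) < 1L || any(regions[, 1] > regions[, 2])) {
    stop("regions must be a matrix of intervals with lo <= hi")
  }
  colnames(regions) <- c("lo", "hi")
  regions[order(regions[, 1]), , drop = FALSE]
}

regions_overlap <- function(a, b) {
  for (i in seq_len(nrow(a))) {
    # shared endpoints are allowed; interiors must not intersect
    if (any(a[i, 1] < b[, 2] & b[, 1] < a[i, 2])) return(TRUE)
  }
  FALSE
}

#' Simulated-observer specification
#'
#' The control observer is omniscient: it responds with the value of the
#' currently active generating function plus zero-mean Gaussian noise, and
#' it tracks function switches instantly.
#'
#' @param noise_sd Response noise standard deviation (ms), > 0.
#' @param seed Integer seed for the response noise.
#' @return An `observer_spec` object.
#' @export
observer_spec <- function(noise_sd, seed = NULL) {
  noise_sd <- as.numeric(noise_sd)
  if (length(noise_sd) != 1L || is.na(noise_sd) || noise_sd <= 0) {
    stop("'noise_sd' must be a single positive number")
  }
  structure(list(noise_sd = noise_sd, knowledge = "omniscient", seed = seed),
            class = "observer_spec")
}

# Which generating function is active on each trial of a switch design.
active_function_index <- function(design, trials) {
  findInterval(trials, design$switch_trials + 0.5) + 1L
}

#' Sample the stimulus sequence of a session
#'
#' Stationary sessions draw the burn-in block uniformly from the training
#' regions (probability proportional to region length) and then alternate
#' test and training stimuli, starting with a test trial. Switching
#' sessions draw every stimulus uniformly and independently over the full
#' span. Sequences are serially uncorrelated by construction.
#'
#' @param design A `session_design` or `switch_design`.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @return A data frame with columns `trial`, `x_mm`, `trial_type`
#'   (`"train"`/`"test"`), `phase`.
#' @export
sample_stimuli <- function(design, seed = NULL) {
  UseMethod("sample_stimuli")
}

runif_regions <- function(n, regions) {
  len <- regions[, 2] - regions[, 1]
  if (sum(len) <= 0) {
    # degenerate point regions: sample the points uniformly
    idx <- sample.int(nrow(regions), n, replace = TRUE)
    return(regions[idx, 1])
  }
  idx <- sample.int(nrow(regions), n, replace = TRUE, prob = len / sum(len))
  regions[idx, 1] + stats::runif(n) * len[idx]
}

#' @export
sample_stimuli.session_design <- function(design, seed = NULL) {
  with_seed(seed, {
    n_test <- design$n_interleaved %/% 2L
    n_train_inter <- design$n_interleaved - n_test
    x_burn <- runif_regions(design$n_burn_in, design$train_regions)
    x_test <- runif_regions(n_test, design$test_regions)
    x_train <- runif_regions(n_train_inter, design$train_regions)
    # interleaved block alternates test, train, test, train, ...
    inter_type <- rep(c("test", "train"), length.out = design$n_interleaved)
    x_inter <- numeric(design$n_interleaved)
    x_inter[inter_type == "test"] <- x_test
    x_inter[inter_type == "train"] <- x_train
    n <- design$n_burn_in + design$n_interleaved
    data.frame(
      trial = seq_len(n),
      x_mm = c(x_burn, x_inter),
      trial_type = c(rep("train", design$n_burn_in), inter_type),
      phase = c(rep("burn_in", design$n_burn_in),
                rep("interleaved", design$n_interleaved)),
      stringsAsFactors = FALSE
    )
  })
}

#' @export
sample_stimuli.switch_design <- function(design, seed = NULL) {
  with_seed(seed, {
    n <- design$n_trials
    data.frame(
      trial = seq_len(n),
      x_mm = stats::runif(n, design$span[1], design$span[2]),
      trial_type = rep("train", n),
      phase = paste0("segment", active_function_index(design, seq_len(n))),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate observer responses for a stimulus sequence
#'
#' Adds the noiseless onset of the active generating function (`onset_ms`)
#' and the observer's noisy response (`response_ms = onset + N(0, sd^2)`)
#' to a stimulus table. Test trials in stationary sessions receive
#' responses as well (the observer responds on every trial; only feedback
#' is withheld). Hits are determined on training trials only.
#'
#' @param stimuli Output of [sample_stimuli()].
#' @param design The design that produced `stimuli`.
#' @param observer An [observer_spec()].
#' @return A trial table data frame with columns `trial`, `phase`, `x_mm`,
#'   `onset_ms`, `response_ms`, `trial_type`, `hit` (`NA` on test trials).
#' @export
simulate_responses <- function(stimuli, design, observer) {
  stopifnot(inherits(observer, "observer_spec"))
  if (inherits(design, "switch_design")) {
    fi <- active_function_index(design, stimuli$trial)
    onset <- numeric(nrow(stimuli))
    for (k in seq_along(design$function_sequence)) {
      sel <- fi == k
      if (any(sel)) onset[sel] <- eval_function(design$function_sequence[[k]],
                                                stimuli$x_mm[sel])
    }
  } else {
    onset <- eval_function(design$generating, stimuli$x_mm)
  }
  noise <- with_seed(observer$seed,
                     stats::rnorm(nrow(stimuli), 0, observer$noise_sd))
  response <- onset + noise
  hit <- ifelse(stimuli$trial_type == "train",
                determine_hit(response, onset), NA)
  data.frame(
    trial = stimuli$trial, phase = stimuli$phase, x_mm = stimuli$x_mm,
    onset_ms = onset, response_ms = response,
    trial_type = stimuli$trial_type, hit = hit,
    stringsAsFactors = FALSE
  )
}

#' Convenience wrapper: simulate a full session
#'
#' @inheritParams simulate_responses
#' @param design A session or switch design.
#' @param seed Integer; seeds both the stimulus sequence and the response
#'   noise (via derived child seeds).
#' @param noise_sd Observer response noise sd (ms).
#' @return A trial table (see [simulate_responses()]).
#' @export
simulate_session <- function(design, noise_sd, seed) {
  stim <- sample_stimuli(design, seed = child_seed(seed, 1L))
  simulate_responses(stim, design,
                     observer_spec(noise_sd, seed = child_seed(seed, 2L)))
}

#' Hit determination
#'
#' The bullet is launched at the response time and takes 300 ms to reach
#' the target's height; the target is visible for 150 ms from its onset.
#' A trial is a hit iff the bullet arrives while the target is visible:
#' `onset <= response + 300 <= onset + 150`. A response at the onset time
#' itself is always a miss (the shot arrives 300 ms after the target has
#' gone).
#'
#' @param response Response (key press) times, ms.
#' @param onset Target onset times, ms.
#' @param travel_ms Bullet travel time (default 300 ms).
#' @param visible_ms Target visibility duration (default 150 ms).
#' @return Logical vector.
#' @export
determine_hit <- function(response, onset, travel_ms = 300, visible_ms = 150) {
  arrival <- response + travel_ms
  onset <= arrival & arrival <= onset + visible_ms
}

#' Hit rate of a session
#'
#' Fraction of feedback (training) trials scored as hits.
#'
#' @param table A trial table with `trial_type` and `hit` columns.
#' @return A number in `[0, 1]`.
#' @export
hit_rate <- function(table) {
  feedback <- table$trial_type == "train" & !is.na(table$hit)
  if (!any(feedback)) stop("no feedback trials with hit flags")
  mean(table$hit[feedback])
}

#' Participant exclusion by hit rate
#'
#' A participant is excluded only if their hit rate falls below the
#' threshold in every session; a single session at or above threshold
#' retains them.
#'
#' @param rates Named list, one numeric vector of per-session hit rates
#'   per participant.
#' @param threshold Exclusion threshold (default 0.10).
#' @return Character vector of retained participant names.
#' @export
exclude_participants <- function(rates, threshold = 0.10) {
  if (length(rates) == 0L) return(character(0))
  keep <- vapply(rates, function(r) any(r >= threshold), logical(1))
  names(rates)[keep]
}
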