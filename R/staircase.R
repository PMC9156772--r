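#' 3-down-1-up staircase state
#'
#' The backward-mask contrast starts at 60% and is made harder (contrast up
#' one step) after three consecutive correct responses, easier (one step
#' down) after any incorrect response. With equal step sizes the procedure
#' converges on the 79.4%-correct point of the psychometric function.
#'
#' @param contrast Starting mask contrast.
#' @param step_size Contrast step, applied symmetrically.
#' @returns A list of class `staircase_state`.
#' @export
staircase_init <- function(contrast = 0.60, step_size = 0.05) {
  structure(list(
    contrast = contrast,
    consecutive_correct = 0L,
    step_size = step_size,
    direction = "none",
    reversals = numeric(0)
  ), class = "staircase_state")
}

#' Advance the staircase by one response
#'
#' On the third consecutive correct response the contrast increases one step
#' and the counter resets; on an incorrect response the contrast decreases
#' one step and the counter resets; otherwise only the counter advances.
#' A reversal (recorded at the pre-change contrast) occurs whenever the
#' direction of change flips. Contrast is clipped to `[0, 1]`.
#'
#' @param state A `staircase_state`.
#' @param correct Logical flag for the current trial.
#' @returns The updated `staircase_state`.
#' @export
staircase_step <- function(state, correct) {
  if (!is_flag(correct)) stop_contract("correct must be TRUE or FALSE")
  move <- 0
  if (!correct) {
    move <- -state$step_size
    state$consecutive_correct <- 0L
  } else if (state$consecutive_correct >= 2L) {
    move <- state$step_size
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
  }
  if (move != 0) {
    new_dir <- if (move > 0) "up" else "down"
    if (state$direction != "none" && state$direction != new_dir) {
      state$reversals <- c(state$reversals, state$contrast)
    }
    state$direction <- new_dir
    state$contrast <- min(1, max(0, state$contrast + move))
  }
  state
}

#' Run a simulated staircase block
#'
#' Simulates `n_trials` yes/no detection trials (50% target rate) through the
#' observer at the running mask contrast. The observer responds with its base
#' criterion and lapse rate; a staircase block precedes the threat
#' manipulation, so no context shift or non-response applies.
#'
#' @param observer An [observer_params()].
#' @param n_trials Number of trials (>= 10).
#' @param start_contrast,step_size Staircase settings.
#' @param seed Optional integer seed.
#' @returns A list of class `staircase_track`: `track` (tibble: trial,
#'   contrast, correct, is_reversal), `reversals`, `final_contrast`,
#'   `accuracy`, and `convergence_failure` (TRUE when the contrast pins
#'   against a boundary, e.g. for near-chance observers).
#' @export
run_staircase <- function(observer, n_trials = 40, start_contrast = 0.60,
                          step_size = 0.05, seed = NULL) {
  if (n_trials < 10) stop_config("n_trials must be at least 10")
  local_seed(seed, {
    state <- staircase_init(start_contrast, step_size)
    contrast <- correct <- numeric(n_trials)
    n_rev <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      contrast[i] <- state$contrast
      target <- runif(1) < 0.5
      dp <- dprime_at_contrast(observer, state$contrast)
      evidence <- rnorm(1, mean = dp * target)
      present <- evidence > dp / 2 + observer$criterion_base
      if (runif(1) < observer$lapse_rate) present <- runif(1) < 0.5
      correct[i] <- as.numeric(present == target)
      state <- staircase_step(state, correct[i] == 1)
      n_rev[i] <- length(state$reversals)
    }
    at_bound <- contrast <= 1e-9 | contrast >= 1 - 1e-9
    structure(list(
      track = tibble::tibble(
        trial = seq_len(n_trials), contrast = contrast,
        correct = as.logical(correct),
        is_reversal = c(n_rev[1] > 0L, diff(n_rev) > 0L)
      ),
      reversals = state$reversals,
      final_contrast = state$contrast,
      accuracy = mean(correct),
      convergence_failure = mean(at_bound) > 0.25
    ), class = "staircase_track")
  })
}

#' Reversal-based contrast estimate
#'
#' Arithmetic mean of the reversal contrasts, excluding the first three.
#'
#' @param track A `staircase_track` (or a numeric vector of reversals).
#' @returns The estimated converged contrast.
#' @export
reversal_average <- function(track) {
  rev <- if (is.numeric(track)) track else track$reversals
  if (length(rev) < 4) {
    stop(errorCondition(
      "at least 4 reversals are required to average (first three discarded)",
      class = c("threatsdt_insufficient_reversals", "error")))
  }
  mean(rev[-(1:3)])
}

#' Classify a staircase track as converged or trending
#'
#' A numeric surrogate for the experimenter's visual convergence check: the
#' least-squares slope of contrast over trials. A downward trend (slope below
#' `-slope_tol` per trial) calls for a restart from 50% contrast, an upward
#' trend for a restart from 70%.
#'
#' @param track A `staircase_track`.
#' @param slope_tol Absolute slope (contrast units per trial) tolerated as
#'   fluctuation.
#' @returns `"converged"`, `"restart_low"`, or `"restart_high"`.
#' @export
check_track <- function(track, slope_tol = 0.002) {
  tr <- track$track
  slope <- coef(lm(contrast ~ trial, data = tr))[["trial"]]
  if (slope < -slope_tol) "restart_low"
  else if (slope > slope_tol) "restart_high"
  else "converged"
}

#' Titrate the mask contrast for one observer
#'
#' Runs one staircase block per target orientation (two independent runs).
#' If either track shows a monotone trend, both blocks restart from 50%
#' (downward trend) or 70% (upward); at most `max_rounds` rounds. The final
#' contrast is the mean of the two reversal averages (falling back to final
#' contrasts when a run yields fewer than four reversals).
#'
#' @param observer An [observer_params()].
#' @param n_trials Trials per staircase block.
#' @param seed Optional integer seed.
#' @param max_rounds Maximum restart rounds.
#' @returns A list: `contrast`, `tracks` (last round's pair), `rounds`,
#'   `failure` (TRUE if any track flagged convergence failure).
#' @export
calibrate_contrast <- function(observer, n_trials = 40, seed = NULL,
                               max_rounds = 3) {
  seeds <- if (is.null(seed)) rep(list(NULL), 2 * max_rounds)
           else as.list(derive_seeds(seed, 2 * max_rounds))
  start <- 0.60
  for (round in seq_len(max_rounds)) {
    t1 <- run_staircase(observer, n_trials, start, seed = seeds[[2 * round - 1]])
    t2 <- run_staircase(observer, n_trials, start, seed = seeds[[2 * round]])
    verdicts <- c(check_track(t1), check_track(t2))
    if (all(verdicts == "converged") || round == max_rounds) break
    start <- if (any(verdicts == "restart_low")) 0.50 else 0.70
  }
  est <- function(tr) {
    if (length(tr$reversals) >= 4) reversal_average(tr) else tr$final_contrast
  }
  list(contrast = mean(c(est(t1), est(t2))),
       tracks = list(t1, t2),
       rounds = round,
       failure = t1$convergence_failure || t2$convergence_failure)
}

#' Serialise a staircase track
#'
#' Writes the per-trial track as CSV and a JSON summary (reversal average
#' when defined, verdict, accuracy).
#'
#' @param track A `staircase_track`.
#' @param csv_path,json_path Output files (either may be `NULL` to skip).
#' @returns The summary list, invisibly.
#' @export
write_staircase <- function(track, csv_path = NULL, json_path = NULL) {
  summary <- list(
    n_trials = nrow(track$track),
    accuracy = track$accuracy,
    n_reversals = length(track$reversals),
    reversal_average = if (length(track$reversals) >= 4)
      reversal_average(track) else NA_real_,
    verdict = check_track(track),
    convergence_failure = track$convergence_failure
  )
  if (!is.null(csv_path)) {
    out <- as.data.frame(track$track)
    out$correct <- as.integer(out$correct)
    out$is_reversal <- as.integer(out$is_reversal)
    write.csv(out, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
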