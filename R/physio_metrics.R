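#' Detect beats in a pulse waveform
#'
#' Light smoothing followed by local-maximum detection with a physiological
#' refractory period; the manual-correction step of interactive tools is
#' replaced by flagging physiologically implausible inter-beat intervals.
#'
#' @param pulse A `physio_trace` (channel `"pulse"`) covering at least 2 s.
#' @param min_ibi_s,max_ibi_s Plausible inter-beat interval range; intervals
#'   outside it are flagged. `min_ibi_s` also acts as the detector's
#'   refractory period.
#' @param smooth_s Moving-average smoothing window.
#' @returns A list of class `beat_series`: `times` (strictly increasing beat
#'   times, s), `ibi_s`, `flagged` (implausible intervals), `quality`
#'   (`"ok"` or `"degenerate"` for flat/empty traces).
#' @export
detect_beats <- function(pulse, min_ibi_s = 0.33, max_ibi_s = 2,
                         smooth_s = 0.1) {
  if (length(pulse$samples) < 2 * pulse$sample_rate_hz) {
    stop_contract("detect_beats() needs at least 2 s of data")
  }
  rate <- pulse$sample_rate_hz
  s <- moving_average(pulse$samples, max(1L, round(smooth_s * rate)))
  rng <- diff(range(s))
  degenerate <- structure(list(times = numeric(0), ibi_s = numeric(0),
                               flagged = logical(0), quality = "degenerate"),
                          class = "beat_series")
  if (!is.finite(rng) || rng < 1e-8) return(degenerate)

  thr <- min(s) + 0.4 * rng
  d <- diff(s)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[s[cand] > thr]
  if (length(cand) < 2) return(degenerate)

  # enforce the refractory period greedily in time order
  keep <- cand[1]
  for (i in cand[-1]) {
    if ((i - keep[length(keep)]) / rate >= min_ibi_s) keep <- c(keep, i)
  }
  times <- pulse$t0 + (keep - 1L) / rate
  ibi <- diff(times)
  structure(list(times = times, ibi_s = ibi,
                 flagged = ibi < min_ibi_s | ibi > max_ibi_s,
                 quality = "ok"),
            class = "beat_series")
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2) |> fill_ends(x))
}

fill_ends <- function(f, x) {
  f <- as.numeric(f)
  na <- is.na(f)
  f[na] <- x[na]
  f
}

#' Instantaneous BPM series from beat times
#'
#' Step-interpolated rate: between consecutive beats i and i+1 the value is
#' `60 / (t[i+1] - t[i])`, resampled on a uniform grid.
#'
#' @param beats A `beat_series` or a numeric vector of beat times (>= 2).
#' @param rate_hz Output sampling rate.
#' @returns A `physio_trace` (channel `"bpm"`) starting at the first beat.
#' @export
bpm_series <- function(beats, rate_hz = 50) {
  times <- if (inherits(beats, "beat_series")) beats$times else beats
  if (length(times) < 2) stop_contract("bpm_series() needs at least 2 beats")
  ibi <- diff(times)
  tout <- seq(times[1], times[length(times)], by = 1 / rate_hz)
  vals <- approx(x = times[-length(times)], y = 60 / ibi, xout = tout,
                 method = "constant", rule = 2)$y
  physio_trace("bpm", rate_hz, vals, t0 = times[1])
}

# Mean of trace samples over [from, to) on the session clock; NA if the
# trace does not fully cover the window.
window_mean <- function(trace, from, to) {
  rate <- trace$sample_rate_hz
  i1 <- floor((from - trace$t0) * rate) + 1L
  i2 <- ceiling((to - trace$t0) * rate)
  if (i1 < 1L || i2 > length(trace$samples) || i2 < i1) return(NA_real_)
  mean(trace$samples[i1:i2])
}

#' Event-related heart-rate change for one trial
#'
#' Mean BPM in the scoring window (default 1-5 s after the event) minus the
#' mean over the baseline period (default 1 s before the event). Returns a
#' missing value, not an error, when the trace does not cover the windows;
#' such trials drop out of aggregation.
#'
#' @param bpm A `physio_trace` (channel `"bpm"`).
#' @param event_time_s Event time on the session clock (trial onset or
#'   stimulus onset, per `alignment`).
#' @param window Scoring window relative to the event (s).
#' @param baseline_s Baseline duration before the event (s).
#' @param alignment Label recording what the event time refers to.
#' @param trial_index Optional trial label.
#' @returns A one-row tibble: `trial_index`, `alignment`, `delta_bpm`.
#' @export
trial_hr_change <- function(bpm, event_time_s, window = c(1, 5),
                            baseline_s = 1, alignment = "trial_onset",
                            trial_index = NA_integer_) {
  delta <- window_mean(bpm, event_time_s + window[1], event_time_s + window[2]) -
    window_mean(bpm, event_time_s - baseline_s, event_time_s)
  tibble::tibble(trial_index = trial_index, alignment = alignment,
                 delta_bpm = delta)
}

# Vectorised window scoring used by the session-level pipeline (identical
# arithmetic to trial_hr_change, via cumulative sums).
windowed_deltas <- function(trace, event_times, window = c(1, 5),
                            baseline_s = 1) {
  rate <- trace$sample_rate_hz
  cs <- cumsum(trace$samples)
  n <- length(trace$samples)
  seg_mean <- function(from, to) {
    i1 <- floor((from - trace$t0) * rate) + 1L
    i2 <- ceiling((to - trace$t0) * rate)
    bad <- i1 < 1L | i2 > n | i2 < i1
    i1c <- pmax(pmin(i1, n), 1L); i2c <- pmax(pmin(i2, n), 1L)
    out <- (cs[i2c] - ifelse(i1c > 1L, cs[i1c - 1L], 0)) / (i2c - i1c + 1L)
    out[bad] <- NA_real_
    out
  }
  seg_mean(event_times + window[1], event_times + window[2]) -
    seg_mean(event_times - baseline_s, event_times)
}

#' Score the skin-conductance response of one trial
#'
#' Finds trough-to-peak deflections whose onset (trough) falls within the
#' latency window after stimulus onset and whose trough-to-peak rise time is
#' within the allowed range; among qualifying candidates the largest
#' amplitude is returned. Amplitude 0 (not missing) when no candidate
#' qualifies; the square-root-transformed amplitude is always populated.
#'
#' @param eda A `physio_trace` (channel `"eda"`).
#' @param stimulus_time_s Stimulus onset on the session clock (s); the trace
#'   must cover up to `stimulus_time_s + 10.5` s.
#' @param onset_window_s Allowed SCR onset latency after stimulus onset.
#' @param rise_range_s Allowed trough-to-peak rise time, measured from SCR
#'   onset.
#' @param min_amplitude_us Minimum trough-to-peak deflection treated as a
#'   response (microsiemens).
#' @param smooth_s Moving-average smoothing applied before extrema search.
#' @param trial_index Optional trial label.
#' @returns A one-row tibble: `trial_index`, `amplitude_us`,
#'   `sqrt_amplitude`, `onset_latency_s`, `rise_time_s`, `n_candidates`.
#'   All-`NA` measurements (with `amplitude_us = NA`) signal insufficient
#'   trace coverage.
#' @export
score_scr <- function(eda, stimulus_time_s,
                      onset_window_s = c(0.5, 5.133),
                      rise_range_s = c(0.5, 5),
                      min_amplitude_us = 0.01,
                      smooth_s = 0.25,
                      trial_index = NA_integer_) {
  rate <- eda$sample_rate_hz
  i1 <- floor((stimulus_time_s - eda$t0) * rate) + 1L
  i2 <- ceiling((stimulus_time_s + 10.5 - eda$t0) * rate)
  miss <- tibble::tibble(trial_index = trial_index, amplitude_us = NA_real_,
                         sqrt_amplitude = NA_real_, onset_latency_s = NA_real_,
                         rise_time_s = NA_real_, n_candidates = 0L)
  if (i1 < 1L || i2 > length(eda$samples)) return(miss)

  s <- moving_average(eda$samples[i1:i2], max(1L, round(smooth_s * rate)))
  runs <- rising_runs(s)
  if (nrow(runs) == 0) {
    return(tibble::tibble(trial_index = trial_index, amplitude_us = 0,
                          sqrt_amplitude = 0, onset_latency_s = NA_real_,
                          rise_time_s = NA_real_, n_candidates = 0L))
  }
  onset_lat <- eda$t0 + (i1 - 1L + runs$trough - 1L) / rate - stimulus_time_s
  rise <- (runs$peak - runs$trough) / rate
  amp <- s[runs$peak] - s[runs$trough]
  ok <- onset_lat >= onset_window_s[1] & onset_lat <= onset_window_s[2] &
    rise >= rise_range_s[1] & rise <= rise_range_s[2] &
    amp >= min_amplitude_us
  if (!any(ok)) {
    return(tibble::tibble(trial_index = trial_index, amplitude_us = 0,
                          sqrt_amplitude = 0, onset_latency_s = NA_real_,
                          rise_time_s = NA_real_, n_candidates = 0L))
  }
  best <- which(ok)[which.max(amp[ok])]
  tibble::tibble(trial_index = trial_index,
                 amplitude_us = amp[best],
                 sqrt_amplitude = sqrt(amp[best]),
                 onset_latency_s = onset_lat[best],
                 rise_time_s = rise[best],
                 n_candidates = sum(ok))
}

# Maximal strictly rising runs of a series: each run contributes a candidate
# (trough index, peak index). Flat stretches break runs, so a kernel rising
# out of a flat tonic level starts its run at the last flat sample.
rising_runs <- function(s) {
  d <- diff(s)
  r <- d > 1e-12
  if (!any(r)) return(data.frame(trough = integer(0), peak = integer(0)))
  starts <- which(r & !c(FALSE, r[-length(r)]))
  ends <- which(r & !c(r[-1], FALSE))
  data.frame(trough = starts, peak = ends + 1L)
}

#' Score a whole session's physiology
#'
#' Applies the trial-level scorers to every experimental trial of a session:
#' heart-rate change aligned to trial onset and to stimulus onset, and the
#' SCR amplitude (square-root transformed). Trials whose windows are not
#' covered yield missing values.
#'
#' @param schedule A `session_schedule`.
#' @param bpm,eda `physio_trace`s for the session (either may be `NULL`,
#'   yielding missing columns).
#' @param window,baseline_s Heart-rate scoring windows (s).
#' @returns A tibble with one row per experimental trial: `trial_index`,
#'   `delta_bpm_trial`, `delta_bpm_stim`, `sqrt_scr`, `scr_amplitude_us`.
#' @export
score_session_physio <- function(schedule, bpm = NULL, eda = NULL,
                                 window = c(1, 5), baseline_s = 1) {
  trials <- schedule$trials[schedule$trials$phase == "experimental", ]
  out <- tibble::tibble(
    subject_id = schedule$subject_id,
    trial_index = trials$trial_index,
    delta_bpm_trial = NA_real_,
    delta_bpm_stim = NA_real_,
    sqrt_scr = NA_real_,
    scr_amplitude_us = NA_real_
  )
  if (!is.null(bpm)) {
    out$delta_bpm_trial <- windowed_deltas(bpm, trials$trial_onset_s,
                                           window, baseline_s)
    out$delta_bpm_stim <- windowed_deltas(bpm, trials$stimulus_onset_s,
                                          window, baseline_s)
  }
  if (!is.null(eda)) {
    scr <- lapply(seq_len(nrow(trials)), function(i) {
      score_scr(eda, trials$stimulus_onset_s[i],
                trial_index = trials$trial_index[i])
    })
    scr <- do.call(rbind, scr)
    out$sqrt_scr <- scr$sqrt_amplitude
    out$scr_amplitude_us <- scr$amplitude_us
  }
  out
}
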