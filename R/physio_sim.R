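#' Event-locked physiological effect parameters
#'
#' Parameters of the synthetic cardiac and electrodermal responses.
#' Heart rate: every experimental trial adds an event-locked deceleration
#' kernel (raised-cosine dip from `decel_onset_s` to `decel_recovery_s`,
#' nadir at `decel_peak_s`), deeper under threat. The kernel is normalised so
#' that the study's scoring windows (mean over 1-5 s post trial onset minus a
#' 1 s pre-trial baseline) recover exactly the programmed depth. Correct
#' target detections carry an additional anticipatory deceleration
#' (`decel_hit_extra_bpm`) shaped as a sustained plateau locked to trial
#' onset; because it is flat across both the stimulus-aligned baseline and
#' scoring window, the hit-miss difference is present when scoring is aligned
#' to trial onset and (by construction) cancels when aligned to stimulus
#' onset. The hit/miss adjustments are centred using `expected_hit_rate` so
#' the marginal condition means stay at the programmed depths.
#'
#' Skin conductance: a trial elicits a response with condition-dependent
#' probability; response amplitudes are parameterised on the square-root
#' scale (the scale of the study's statistics), so the subject-level mean
#' sqrt-amplitude over all trials (zeros included) equals
#' `scr_sqrt_threat` / `scr_sqrt_safe`.
#'
#' @param baseline_bpm Tonic heart rate.
#' @param decel_threat_bpm,decel_safe_bpm Scored deceleration per condition
#'   (negative BPM).
#' @param decel_hit_extra_bpm Hit-minus-miss deceleration difference on
#'   target trials (BPM; positive = hits decelerate more, negative values
#'   describe subjects with the reversed pattern).
#' @param decel_trial_sd_bpm Trial-to-trial SD of the kernel depth.
#' @param decel_onset_s,decel_peak_s,decel_recovery_s Kernel time course (s
#'   after trial onset).
#' @param expected_hit_rate Expected hit rate used to centre the hit/miss
#'   adjustment.
#' @param scr_sqrt_threat,scr_sqrt_safe Subject mean sqrt SCR amplitude
#'   (sqrt-microsiemens) per condition.
#' @param scr_prob_threat,scr_prob_safe Probability that a trial elicits a
#'   scoreable SCR.
#' @param scr_trial_sd Trial-to-trial SD of sqrt amplitude given a response.
#' @param scr_latency_range_s SCR onset latency after stimulus onset (uniform
#'   draw; inside the scoring window of [score_scr()]).
#' @param scr_rise_s,scr_decay_s SCR kernel rise and decay constants.
#' @param eda_tonic_us Tonic skin-conductance level (microsiemens).
#' @param noise_sd_bpm,noise_sd_eda White measurement noise per channel.
#' @param sample_rate_hz Simulation sample rate (matches the downsampled
#'   analysis rate, not the acquisition rate).
#' @returns A list of class `physio_effect_params`.
#' @export
physio_effect_params <- function(baseline_bpm = 70,
                                 decel_threat_bpm = -4.38,
                                 decel_safe_bpm = -2.99,
                                 decel_hit_extra_bpm = 0.4,
                                 decel_trial_sd_bpm = 3,
                                 decel_onset_s = 0.5,
                                 decel_peak_s = 3,
                                 decel_recovery_s = 6,
                                 expected_hit_rate = 0.665,
                                 scr_sqrt_threat = 0.24,
                                 scr_sqrt_safe = 0.09,
                                 scr_prob_threat = 0.6,
                                 scr_prob_safe = 0.3,
                                 scr_trial_sd = 0.08,
                                 scr_latency_range_s = c(0.7, 2.5),
                                 scr_rise_s = 1.5,
                                 scr_decay_s = 3,
                                 eda_tonic_us = 5,
                                 noise_sd_bpm = 1,
                                 noise_sd_eda = 0.003,
                                 sample_rate_hz = 50) {
  if (scr_rise_s < 0.5 || scr_rise_s > 5) {
    stop_config("scr_rise_s must lie in [0.5, 5] (the scoreable rise-time range)")
  }
  assert_prob(c(scr_prob_threat, scr_prob_safe), "SCR probabilities")
  structure(as.list(environment()), class = "physio_effect_params")
}

#' A uniformly sampled physiological trace
#'
#' @param channel `"bpm"`, `"pulse"`, or `"eda"`.
#' @param sample_rate_hz Sampling rate (> 0).
#' @param samples Numeric vector of samples (finite).
#' @param t0 Time of the first sample on the session clock (s).
#' @param events Tibble of `(time_s, label, trial_index)` event markers.
#' @returns A list of class `physio_trace`.
#' @export
physio_trace <- function(channel, sample_rate_hz, samples, t0 = 0,
                         events = NULL) {
  if (sample_rate_hz <= 0) stop_config("sample_rate_hz must be positive")
  if (any(!is.finite(samples))) stop_config("trace samples must be finite")
  structure(list(channel = channel, sample_rate_hz = sample_rate_hz,
                 samples = samples, t0 = t0,
                 events = events %||%
                   tibble::tibble(time_s = numeric(0), label = character(0),
                                  trial_index = integer(0))),
            class = "physio_trace")
}

#' @export
print.physio_trace <- function(x, ...) {
  cat("<physio_trace>", x$channel, "|", length(x$samples), "samples @",
      x$sample_rate_hz, "Hz |", nrow(x$events), "events\n")
  invisible(x)
}

trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$sample_rate_hz
}

# Unit deceleration dip (0 to 1 and back, raised cosine in two halves).
decel_shape <- function(t, onset, peak, recovery) {
  out <- numeric(length(t))
  ris <- t >= onset & t <= peak
  fal <- t > peak & t <= recovery
  out[ris] <- 0.5 * (1 - cos(pi * (t[ris] - onset) / (peak - onset)))
  out[fal] <- 0.5 * (1 + cos(pi * (t[fal] - peak) / (recovery - peak)))
  out
}

# Window score (mean over [1,5] s minus mean over [-1,0] s) of the unit dip;
# used to normalise kernels so scoring recovers the programmed depth.
decel_shape_score <- function(onset, peak, recovery, rate = 200) {
  tg <- seq(1, 5, by = 1 / rate)
  mean(decel_shape(tg, onset, peak, recovery))  # baseline window is zero
}

# Sustained anticipatory component carried by hits: ramps up over
# [0.5, 1] s, holds through 7 s, ramps off by 8 s. Its mean over the 1-5 s
# scoring window is exactly 1, and it is flat over any stimulus-aligned
# baseline/window pair for stimulus onsets in 1-3 s, so baseline correction
# removes it under stimulus alignment.
hit_plateau_shape <- function(t) {
  out <- numeric(length(t))
  up <- t >= 0.5 & t < 1
  flat <- t >= 1 & t <= 7
  dn <- t > 7 & t <= 8
  out[up] <- (t[up] - 0.5) / 0.5
  out[flat] <- 1
  out[dn] <- (8 - t[dn])
  out
}

#' Generate a session's beats-per-minute trace
#'
#' Baseline heart rate plus event-locked deceleration kernels (all
#' experimental trials; neutral manipulation trials use the safe depth) plus
#' white noise. Hit/miss-dependent anticipatory components are added on
#' target trials as described in [physio_effect_params()].
#'
#' @param schedule A `session_schedule`.
#' @param results Response tibble aligned with `schedule$trials`
#'   ([simulate_responses()]).
#' @param fx A [physio_effect_params()]; per-subject trait depths may be set
#'   through `decel_threat_bpm` / `decel_safe_bpm`.
#' @param seed Optional integer seed.
#' @returns A `physio_trace` (channel `"bpm"`) with trial- and
#'   stimulus-onset event markers.
#' @export
generate_bpm_trace <- function(schedule, results, fx = physio_effect_params(),
                               seed = NULL) {
  trials <- schedule$trials
  if (nrow(trials) != nrow(results)) {
    stop_contract("schedule and results must have the same number of trials")
  }
  rate <- fx$sample_rate_hz
  dur <- max(trials$trial_onset_s + trials$trial_duration_ms / 1000) + 10
  n <- ceiling(dur * rate)
  tt <- (seq_len(n) - 1L) / rate

  norm <- decel_shape_score(fx$decel_onset_s, fx$decel_peak_s, fx$decel_recovery_s)
  kern_len <- ceiling((fx$decel_recovery_s + 0.5) * rate)
  plat_len <- ceiling(8.5 * rate)

  local_seed(seed, {
    samples <- rep(fx$baseline_bpm, n) + rnorm(n, 0, fx$noise_sd_bpm)
    depth <- ifelse(trials$condition == "threat",
                    fx$decel_threat_bpm, fx$decel_safe_bpm) +
      rnorm(nrow(trials), 0, fx$decel_trial_sd_bpm)
    hit <- trials$stimulus == "target" & results$response == "present"
    miss <- trials$stimulus == "target" & results$response != "present"
    adj <- numeric(nrow(trials))
    adj[hit] <- -(1 - fx$expected_hit_rate) * fx$decel_hit_extra_bpm
    adj[miss] <- fx$expected_hit_rate * fx$decel_hit_extra_bpm

    for (i in seq_len(nrow(trials))) {
      i0 <- floor(trials$trial_onset_s[i] * rate) + 1L
      idx <- i0:min(i0 + kern_len, n)
      rel <- tt[idx] - trials$trial_onset_s[i]
      samples[idx] <- samples[idx] + depth[i] / norm *
        decel_shape(rel, fx$decel_onset_s, fx$decel_peak_s, fx$decel_recovery_s)
      if (adj[i] != 0) {
        idx2 <- i0:min(i0 + plat_len, n)
        samples[idx2] <- samples[idx2] +
          adj[i] * hit_plateau_shape(tt[idx2] - trials$trial_onset_s[i])
      }
    }
    ev <- tibble::tibble(
      time_s = c(trials$trial_onset_s, trials$stimulus_onset_s),
      label = rep(c("trial_onset", "stimulus_onset"), each = nrow(trials)),
      trial_index = rep(trials$trial_index, 2L)
    )
    physio_trace("bpm", rate, samples, t0 = 0, events = ev)
  })
}

#' Synthesise a pulse waveform from a BPM trace
#'
#' Inverse of beat detection: integrates the instantaneous rate into a beat
#' phase (inter-beat interval = 60/BPM) and places one dominant
#' raised-cosine pulse per beat, plus measurement noise. Used to exercise
#' [detect_beats()] end to end.
#'
#' @param bpm A `physio_trace` with positive BPM samples.
#' @param pulse_width_s Width of each pulse.
#' @param noise_sd Additive white noise SD.
#' @param seed Optional integer seed.
#' @returns A `physio_trace` (channel `"pulse"`).
#' @export
generate_pulse_trace <- function(bpm, pulse_width_s = 0.3, noise_sd = 0.02,
                                 seed = NULL) {
  if (any(bpm$samples <= 0)) stop_config("BPM must be positive everywhere")
  rate <- bpm$sample_rate_hz
  phase <- cumsum(bpm$samples / 60) / rate
  beat_idx <- which(diff(floor(c(0, phase))) >= 1)
  beat_times <- bpm$t0 + (beat_idx - 1L) / rate
  n <- length(bpm$samples)
  tt <- trace_times(bpm)
  samples <- numeric(n)
  half <- pulse_width_s / 2
  w <- ceiling(half * rate)
  for (b in beat_times) {
    i0 <- max(1L, floor((b - bpm$t0) * rate) + 1L - w)
    idx <- i0:min(i0 + 2L * w, n)
    rel <- tt[idx] - b
    in_p <- abs(rel) <= half
    samples[idx[in_p]] <- samples[idx[in_p]] +
      0.5 * (1 + cos(pi * rel[in_p] / half))
  }
  local_seed(seed, samples <- samples + rnorm(n, 0, noise_sd))
  physio_trace("pulse", rate, samples, t0 = bpm$t0, events = bpm$events)
}

#' Canonical skin-conductance response kernel
#'
#' Zero before onset, smooth rise to its maximum (= `amplitude`) at
#' `t = rise_s`, exponential decay afterwards. Linear in amplitude.
#'
#' @param t Time since SCR onset (s, vectorised).
#' @param amplitude Peak amplitude (microsiemens).
#' @param rise_s,decay_s Rise time and decay constant (> 0).
#' @returns Numeric kernel values.
#' @export
scr_kernel <- function(t, amplitude, rise_s, decay_s) {
  if (rise_s <= 0 || decay_s <= 0) stop_config("rise_s and decay_s must be positive")
  out <- numeric(length(t))
  ris <- t >= 0 & t <= rise_s
  dec <- t > rise_s
  out[ris] <- amplitude * 0.5 * (1 - cos(pi * t[ris] / rise_s))
  out[dec] <- amplitude * exp(-(t[dec] - rise_s) / decay_s)
  out
}

#' Generate a session's electrodermal trace
#'
#' Tonic level plus event-locked SCR kernels. Each experimental trial
#' elicits an SCR with condition-dependent probability; onset latency is
#' drawn inside the scoring window; amplitudes are drawn on the square-root
#' scale and squared (see [physio_effect_params()]). Neutral manipulation
#' trials elicit safe-level responses.
#'
#' @inheritParams generate_bpm_trace
#' @returns A `physio_trace` (channel `"eda"`).
#' @export
generate_eda_trace <- function(schedule, results, fx = physio_effect_params(),
                               seed = NULL) {
  trials <- schedule$trials
  if (nrow(trials) != nrow(results)) {
    stop_contract("schedule and results must have the same number of trials")
  }
  rate <- fx$sample_rate_hz
  dur <- max(trials$trial_onset_s + trials$trial_duration_ms / 1000) + 12
  n <- ceiling(dur * rate)
  tt <- (seq_len(n) - 1L) / rate
  kern_len <- ceiling((fx$scr_rise_s + 6 * fx$scr_decay_s) * rate)

  local_seed(seed, {
    samples <- rep(fx$eda_tonic_us, n) + rnorm(n, 0, fx$noise_sd_eda)
    threat <- trials$condition == "threat"
    p <- ifelse(threat, fx$scr_prob_threat, fx$scr_prob_safe)
    mean_sqrt <- ifelse(threat, fx$scr_sqrt_threat, fx$scr_sqrt_safe) / p
    respond <- runif(nrow(trials)) < p
    amp_sqrt <- pmax(mean_sqrt + rnorm(nrow(trials), 0, fx$scr_trial_sd), 0.02)
    latency <- runif(nrow(trials), fx$scr_latency_range_s[1],
                     fx$scr_latency_range_s[2])
    for (i in which(respond)) {
      onset <- trials$stimulus_onset_s[i] + latency[i]
      i0 <- floor(onset * rate) + 1L
      if (i0 > n) next
      idx <- i0:min(i0 + kern_len, n)
      samples[idx] <- samples[idx] +
        scr_kernel(tt[idx] - onset, amp_sqrt[i]^2, fx$scr_rise_s, fx$scr_decay_s)
    }
    ev <- tibble::tibble(
      time_s = trials$stimulus_onset_s,
      label = rep("stimulus_onset", nrow(trials)),
      trial_index = trials$trial_index
    )
    physio_trace("eda", rate, samples, t0 = 0, events = ev)
  })
}

#' Write / read a trace as CSV plus a JSON sidecar
#'
#' Two-column CSV (`time_s`, `value`) and a sidecar carrying channel,
#' sampling rate and the event list (a BIDS-physio-like plain-text layout).
#'
#' @param trace A `physio_trace`.
#' @param csv_path Data file; the sidecar is written next to it as
#'   `<csv_path>.json`.
#' @returns `csv_path` invisibly; `read_trace()` returns the `physio_trace`.
#' @export
write_trace <- function(trace, csv_path) {
  df <- data.frame(time_s = trace_times(trace), value = trace$samples)
  write.csv(df, csv_path, row.names = FALSE)
  side <- list(channel = trace$channel, sample_rate_hz = trace$sample_rate_hz,
               t0 = trace$t0, events = as.data.frame(trace$events))
  jsonlite::write_json(side, paste0(csv_path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(csv_path)
}

#' @rdname write_trace
#' @export
read_trace <- function(csv_path) {
  df <- read.csv(csv_path)
  side <- jsonlite::read_json(paste0(csv_path, ".json"), simplifyVector = TRUE)
  ev <- tibble::as_tibble(as.data.frame(side$events))
  physio_trace(side$channel, side$sample_rate_hz, df$value,
               t0 = side$t0, events = ev)
}
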