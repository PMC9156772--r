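test_that("instantaneous BPM from beat times is exact for regular rhythms", {
  expect_equal(unique(bpm_series(0:10, 50)$samples), 60)
  expect_lt(max(abs(bpm_series(seq(0, 8, by = 0.8), 50)$samples - 75)), 1e-9)
  # jittered beats: series mean tracks 60 / mean IBI
  set.seed(4)
  beats <- cumsum(runif(50, 0.7, 0.9))
  series <- bpm_series(beats, 50)
  expect_equal(mean(series$samples), 60 / mean(diff(beats)), tolerance = 0.5)
  expect_error(bpm_series(1.0), class = "threatsdt_contract_error")
})

test_that("flat or too-short pulse input degrades gracefully", {
  flat <- physio_trace("pulse", 50, rep(0.2, 500))
  b <- detect_beats(flat)
  expect_equal(b$quality, "degenerate")
  expect_length(b$times, 0)
  short <- physio_trace("pulse", 50, rep(0.2, 30))
  expect_error(detect_beats(short), class = "threatsdt_contract_error")
})

test_that("windowed heart-rate change scores programmed signals exactly", {
  # constant trace: no change
  flat <- flat_bpm_trace(70)
  expect_equal(trial_hr_change(flat, 20)$delta_bpm, 0)

  # a -5 BPM step spanning baseline-to-window transition cleanly
  rate <- 50
  x <- rep(70, 60 * rate)
  x[(20 * rate + 1):(40 * rate)] <- 65  # step at exactly t = 20 s
  step_tr <- physio_trace("bpm", rate, x)
  expect_equal(trial_hr_change(step_tr, 20)$delta_bpm, -5, tolerance = 0.01)

  # programmed deceleration kernel: scoring recovers the programmed depth
  s <- build_session(tiny_design(), seed = 2)
  res <- simulate_responses(observer_params(), s$trials, seed = 3)
  fx <- physio_effect_params(decel_threat_bpm = -4, decel_safe_bpm = -4,
                             decel_hit_extra_bpm = 0, decel_trial_sd_bpm = 0,
                             noise_sd_bpm = 0)
  bpm <- generate_bpm_trace(s, res, fx, seed = 4)
  ph <- score_session_physio(s, bpm, NULL)
  expect_equal(mean(ph$delta_bpm_trial, na.rm = TRUE), -4, tolerance = 0.05)

  # baseline-correction property: invariant to a constant offset
  shifted <- physio_trace("bpm", bpm$sample_rate_hz, bpm$samples + 12.3,
                          events = bpm$events)
  ph2 <- score_session_physio(s, shifted, NULL)
  expect_equal(ph$delta_bpm_trial, ph2$delta_bpm_trial, tolerance = 1e-9)

  # insufficient coverage yields a missing value, not an error
  expect_true(is.na(trial_hr_change(flat, 0.2)$delta_bpm))
  expect_true(is.na(trial_hr_change(flat, 59.5)$delta_bpm))
})

test_that("SCR scoring implements the latency/rise-time/largest rules", {
  # single injected SCR at 1.5 s: amplitude and sqrt recovered
  eda <- eda_with_scr(onset_s = 10 + 1.5, amplitude_us = 0.09)
  sc <- score_scr(eda, stimulus_time_s = 10)
  expect_lt(abs(sc$amplitude_us - 0.09), 0.005)
  expect_lt(abs(sc$sqrt_amplitude - 0.3), 0.01)
  expect_lt(abs(sc$onset_latency_s - 1.5), 0.3)

  # two qualifying SCRs: the largest wins
  t2 <- eda_with_scr(onset_s = 11, amplitude_us = 0.04)
  two <- physio_trace("eda", 50, t2$samples +
                        scr_kernel((seq_along(t2$samples) - 1) / 50 - 14,
                                   0.16, 1.5, 3))
  sc2 <- score_scr(two, stimulus_time_s = 10)
  # the larger response wins; its trough sits on the first SCR's decaying
  # tail, so the trough-to-peak amplitude is slightly below the injected peak
  expect_lt(abs(sc2$amplitude_us - 0.16), 0.02)
  expect_gt(sc2$amplitude_us, 2 * 0.04)
  expect_gte(sc2$n_candidates, 2)

  # onset outside the latency window: scored as zero response
  late <- eda_with_scr(onset_s = 10 + 6, amplitude_us = 0.2)
  expect_equal(score_scr(late, stimulus_time_s = 10)$amplitude_us, 0)

  # sub-threshold deflections do not count
  tiny <- eda_with_scr(onset_s = 11.5, amplitude_us = 0.004)
  expect_equal(score_scr(tiny, stimulus_time_s = 10)$amplitude_us, 0)

  # tonic-offset invariance and linearity
  eda_hi <- physio_trace("eda", 50, eda$samples + 3)
  expect_equal(score_scr(eda_hi, 10)$amplitude_us, sc$amplitude_us,
               tolerance = 1e-6)
  eda_2x <- eda_with_scr(onset_s = 11.5, amplitude_us = 0.18)
  expect_lt(abs(score_scr(eda_2x, 10)$amplitude_us - 2 * sc$amplitude_us),
            0.005)

  # insufficient coverage: missing marker
  expect_true(is.na(score_scr(eda, stimulus_time_s = 35)$amplitude_us))
})
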