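test_that("zero effects and zero noise yield flat traces", {
  s <- build_session(tiny_design(), seed = 1)
  res <- simulate_responses(observer_params(), s$trials, seed = 2)
  fx <- physio_effect_params(decel_threat_bpm = 0, decel_safe_bpm = 0,
                             decel_hit_extra_bpm = 0, decel_trial_sd_bpm = 0,
                             noise_sd_bpm = 0)
  bpm <- generate_bpm_trace(s, res, fx, seed = 3)
  expect_equal(range(bpm$samples), c(70, 70))

  fx2 <- physio_effect_params(scr_sqrt_threat = 0, scr_sqrt_safe = 0,
                              scr_prob_threat = 0, scr_prob_safe = 0,
                              noise_sd_eda = 0)
  eda <- generate_eda_trace(s, res, fx2, seed = 4)
  expect_equal(range(eda$samples), c(5, 5))
})

test_that("the SCR kernel is causal, linear, and peaks at its rise time", {
  tt <- seq(-2, 12, by = 0.01)
  k1 <- scr_kernel(tt, amplitude = 0.1, rise_s = 1.5, decay_s = 3)
  expect_true(all(k1[tt < 0] == 0))
  k2 <- scr_kernel(tt, amplitude = 0.2, rise_s = 1.5, decay_s = 3)
  expect_equal(k2, 2 * k1, tolerance = 1e-12)
  peak_t <- tt[which.max(k1)]
  expect_gte(peak_t, 0.9 * 1.5)
  expect_lte(peak_t, 1.1 * 1.5)
  expect_equal(max(k1), 0.1, tolerance = 1e-9)
  expect_error(scr_kernel(tt, 0.1, rise_s = 0, decay_s = 3),
               class = "threatsdt_config_error")
})

test_that("pulse synthesis follows the programmed instantaneous rate", {
  flat60 <- physio_trace("bpm", 50, rep(60, 50 * 10.5))
  pulse <- generate_pulse_trace(flat60, noise_sd = 0, seed = 1)
  beats <- detect_beats(pulse)
  expect_equal(beats$quality, "ok")
  expect_equal(length(beats$times), 10, tolerance = 1)
  expect_equal(mean(beats$ibi_s), 1.0, tolerance = 0.03)

  flat75 <- physio_trace("bpm", 50, rep(75, 50 * 10.5))
  beats75 <- detect_beats(generate_pulse_trace(flat75, noise_sd = 0, seed = 1))
  expect_equal(mean(beats75$ibi_s), 0.8, tolerance = 0.03)

  neg <- physio_trace("bpm", 50, rep(-5, 100))
  expect_error(generate_pulse_trace(neg), class = "threatsdt_config_error")
})

test_that("beat detection round-trips a modulated BPM trace", {
  # slow modulation around 70 BPM, as in event-related deceleration
  rate <- 50
  tt <- (seq_len(rate * 120) - 1) / rate
  bpm_true <- 70 - 5 * sin(2 * pi * tt / 30)
  bpm <- physio_trace("bpm", rate, bpm_true)
  pulse <- generate_pulse_trace(bpm, noise_sd = 0.01, seed = 9)
  beats <- detect_beats(pulse)
  series <- bpm_series(beats, rate_hz = rate)
  # compare on the overlapping interior
  idx <- which(tt >= series$t0 + 1 & tt <= series$t0 + 100)
  est <- series$samples[round((tt[idx] - series$t0) * rate) + 1]
  rmse <- sqrt(mean((est - bpm_true[idx])^2))
  expect_lt(rmse, 1)
})

test_that("traces are reproducible under a fixed seed", {
  s <- build_session(tiny_design(), seed = 5)
  res <- simulate_responses(observer_params(), s$trials, seed = 6)
  fx <- physio_effect_params()
  expect_identical(generate_bpm_trace(s, res, fx, seed = 7)$samples,
                   generate_bpm_trace(s, res, fx, seed = 7)$samples)
  expect_identical(generate_eda_trace(s, res, fx, seed = 8)$samples,
                   generate_eda_trace(s, res, fx, seed = 8)$samples)
  expect_error(generate_bpm_trace(s, res[-1, ], fx),
               class = "threatsdt_contract_error")
})

test_that("traces round-trip through CSV plus JSON sidecar", {
  s <- build_session(tiny_design(n_blocks = 1), seed = 5)
  res <- simulate_responses(observer_params(), s$trials, seed = 6)
  bpm <- generate_bpm_trace(s, res, physio_effect_params(), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(bpm, path)
  back <- read_trace(path)
  expect_equal(back$channel, "bpm")
  expect_equal(back$sample_rate_hz, bpm$sample_rate_hz)
  expect_equal(back$samples, bpm$samples, tolerance = 1e-9)
  expect_equal(nrow(back$events), nrow(bpm$events))
})
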