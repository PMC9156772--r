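test_that("sensitivity decays monotonically with mask contrast", {
  obs <- observer_params()
  grid <- seq(0, 1, by = 0.05)
  d <- dprime_at_contrast(obs, grid)
  expect_true(all(diff(d) < 0))
  expect_equal(which.max(d), 1L)  # unmasked limit is maximal
  expect_equal(dprime_at_contrast(obs, obs$contrast_ref), obs$dprime_safe)
  expect_error(dprime_at_contrast(obs, -0.1), class = "threatsdt_config_error")
  expect_error(dprime_at_contrast(obs, 1.5), class = "threatsdt_config_error")
})

test_that("effective criterion combines base and context shift", {
  obs <- observer_params(criterion_base = 0.365,
                         criterion_shift_rare = 0.165,
                         criterion_shift_frequent = -0.165)
  expect_equal(effective_criterion(obs, "rare", "safe"), 0.53)
  expect_equal(effective_criterion(obs, "frequent", "safe"), 0.20)
  # no threat modulation by default
  expect_equal(effective_criterion(obs, "rare", "threat"),
               effective_criterion(obs, "rare", "safe"))
  flat <- observer_params(criterion_shift_rare = 0,
                          criterion_shift_frequent = 0)
  expect_equal(effective_criterion(flat, "rare", "safe"),
               effective_criterion(flat, "frequent", "safe"))
  expect_error(effective_criterion(obs, "sometimes", "safe"),
               class = "threatsdt_config_error")
})

test_that("response generation matches the equal-variance model", {
  trials <- tibble::tibble(
    condition = "safe", stimulus = rep(c("target", "lure"), 5000),
    prior_context = "none", phase = "experimental", mask_contrast = NA_real_)

  # criterion far below any evidence: always respond present
  always <- clean_observer(criterion_base = -999)
  r <- simulate_responses(always, trials, seed = 1)
  expect_true(all(r$response == "present"))

  # d' = 0: hit rate ~ false-alarm rate
  flat <- clean_observer(dprime_safe = 0, criterion_base = 0.3)
  r <- simulate_responses(flat, trials, seed = 2)
  hit <- mean(r$response[trials$stimulus == "target"] == "present")
  fa <- mean(r$response[trials$stimulus == "lure"] == "present")
  expect_lt(abs(hit - fa), 0.02)

  # closed-form hit/FA rates of the equal-variance model
  obs <- clean_observer(dprime_safe = 1.5, criterion_base = 0.3)
  big <- tibble::tibble(
    condition = "safe", stimulus = rep(c("target", "lure"), 50000),
    prior_context = "none", phase = "experimental", mask_contrast = NA_real_)
  r <- simulate_responses(obs, big, seed = 3)
  hit <- mean(r$response[big$stimulus == "target"] == "present")
  fa <- mean(r$response[big$stimulus == "lure"] == "present")
  expect_equal(hit, pnorm(1.5 / 2 - 0.3), tolerance = 0.01)
  expect_equal(fa, pnorm(-1.5 / 2 - 0.3), tolerance = 0.01)

  # non-response rate is honoured
  nr <- observer_params(nonresponse_rate = 0.0135, lapse_rate = 0)
  r <- simulate_responses(nr, big, seed = 4)
  expect_lt(abs(mean(r$response == "none") - 0.0135), 0.0025)
  expect_true(all(is.na(r$rt_ms[r$response == "none"])))
})

test_that("responses are deterministic given a seed", {
  s <- build_session(seed = 3)
  obs <- observer_params()
  a <- simulate_responses(obs, s$trials, seed = 11)
  b <- simulate_responses(obs, s$trials, seed = 11)
  expect_identical(a, b)
})

test_that("population samples converge to the printed group parameters", {
  pop <- population_params(n_subjects = 5000)
  draw <- sample_population(pop, seed = 21)
  expect_lt(abs(mean(draw$dprime_threat) - 1.66), 0.03)
  expect_lt(abs(mean(draw$dprime_safe) - 1.55), 0.03)
  expect_lt(abs(mean(draw$rt_mean_threat_ms) - 632.4), 4)
  expect_lt(abs(mean(draw$rt_mean_safe_ms) - 616.5), 4)
  expect_lt(abs(mean(draw$nonresponse_rate) - 0.0135), 0.002)
  expect_lt(abs(mean(draw$decel_threat_bpm) - (-4.38)), 0.1)
  expect_lt(abs(mean(draw$decel_safe_bpm) - (-2.99)), 0.1)
  expect_lt(abs(mean(draw$scr_sqrt_threat) - 0.24), 0.015)
  expect_lt(abs(mean(draw$scr_sqrt_safe) - 0.09), 0.01)
  # copula correlations are honoured
  expect_lt(abs(cor(draw$decel_threat_bpm, draw$rt_mean_safe_ms) - 0.32), 0.05)
  shift_mag <- draw$criterion_shift_rare
  expect_lt(abs(cor(draw$dprime_safe, shift_mag) - (-0.29)), 0.05)
  # determinism
  expect_identical(draw, sample_population(pop, seed = 21))
})

test_that("degenerate populations collapse to identical observers", {
  pop <- population_params(n_subjects = 5, dprime_safe_sd = 0,
                           dprime_delta_sd = 0, criterion_base_sd = 0,
                           criterion_shift_sd = 0, rt_safe_sd = 0,
                           rt_delta_sd = 0, nonresponse_shape1 = 1e6,
                           nonresponse_shape2 = 1e6,
                           decel_threat_sd = 0, decel_safe_sd = 0,
                           scr_sqrt_threat_sd = 1e-9, scr_sqrt_safe_sd = 1e-9)
  draw <- sample_population(pop, seed = 5)
  for (col in c("dprime_threat", "dprime_safe", "criterion_base",
                "rt_mean_threat_ms", "decel_threat_bpm")) {
    expect_equal(var(draw[[col]]), 0, tolerance = 1e-12)
  }
  expect_error(population_params(cor_hr_rt = 1.4),
               class = "threatsdt_config_error")
})
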