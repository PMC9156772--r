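test_that("trial classification applies the exclusion rules", {
  trial <- tibble::tibble(stimulus = "target", included_in_analysis = TRUE)
  lure <- tibble::tibble(stimulus = "lure", included_in_analysis = TRUE)
  resp <- function(r, rt = 900) tibble::tibble(response = r, rt_ms = rt)

  expect_equal(classify_trial(trial, resp("present")), "hit")
  expect_equal(classify_trial(trial, resp("absent")), "miss")
  expect_equal(classify_trial(lure, resp("present")), "fa")
  expect_equal(classify_trial(lure, resp("absent")), "cr")
  expect_equal(classify_trial(trial, resp("present", 1600)), "excluded")
  expect_equal(classify_trial(trial, resp("none", NA)), "excluded")
  flagged <- tibble::tibble(stimulus = "target", included_in_analysis = FALSE)
  expect_equal(classify_trial(flagged, resp("present")), "excluded")
})

test_that("the 0.25 correction handles extreme counts", {
  expect_equal(corrected_rates(10, 16, 0, 16),
               list(hit_rate = 0.625, fa_rate = 0.015625))
  expect_equal(corrected_rates(16, 16, 3, 16),
               list(hit_rate = 0.984375, fa_rate = 0.1875))
  expect_equal(corrected_rates(8, 16, 4, 16),
               list(hit_rate = 0.5, fa_rate = 0.25))
  # both cells extreme: both corrected
  both <- corrected_rates(16, 16, 0, 16)
  expect_equal(both$hit_rate, 15.75 / 16)
  expect_equal(both$fa_rate, 0.25 / 16)
  # zero hits corrected upward; full false alarms corrected downward
  expect_equal(corrected_rates(0, 16, 16, 16),
               list(hit_rate = 0.25 / 16, fa_rate = 15.75 / 16))
  expect_error(corrected_rates(1, 0, 0, 16), class = "threatsdt_config_error")
  expect_error(corrected_rates(17, 16, 0, 16), class = "threatsdt_config_error")
})

test_that("d-prime and criterion identities hold", {
  m <- sdt_metrics(0.6915, 0.3085)
  expect_equal(m$dprime, 1.00, tolerance = 1e-3)
  expect_equal(m$criterion, 0.00, tolerance = 1e-3)
  expect_equal(sdt_metrics(0.5, 0.5), list(dprime = 0, criterion = 0))
  expect_equal(sdt_metrics(0.6915, 0.5)$criterion, -0.25, tolerance = 1e-3)
  expect_error(sdt_metrics(1, 0.5), class = "threatsdt_config_error")
  expect_error(sdt_metrics(0.5, 0), class = "threatsdt_config_error")

  # antisymmetry: swapping rates flips d'; reflecting rates flips criterion
  set.seed(8)
  h <- runif(50, 0.05, 0.95); f <- runif(50, 0.05, 0.95)
  expect_equal(sdt_metrics(h, f)$dprime, -sdt_metrics(f, h)$dprime)
  expect_equal(sdt_metrics(h, f)$criterion,
               -sdt_metrics(1 - f, 1 - h)$criterion, tolerance = 1e-12)

  # corrected extreme counts stay finite and monotone in the hit count
  d_seq <- vapply(0:16, function(nh) {
    r <- corrected_rates(nh, 16, 0, 16)
    sdt_metrics(r$hit_rate, r$fa_rate)$dprime
  }, numeric(1))
  expect_true(all(is.finite(d_seq)))
  expect_true(all(diff(d_seq) > 0))
})

test_that("cell aggregation produces the requested partitions", {
  s <- build_session(seed = 9, subject_id = 1)
  res <- simulate_responses(observer_params(), s$trials, seed = 10)
  cells <- aggregate_cells(s$trials, res)
  cond <- cells[cells$prior_context == "pooled", ]
  expect_equal(nrow(cond), 2)
  expect_setequal(cond$condition, c("threat", "safe"))
  expect_true(all(cond$n_signal + cond$n_noise <= 128))
  ctx <- cells[cells$condition == "pooled", ]
  expect_equal(nrow(ctx), 2)
  cc <- cells[cells$condition != "pooled" & cells$prior_context != "pooled", ]
  expect_equal(nrow(cc), 4)
  # per condition: 64 targets and 64 lures minus behavioural exclusions
  expect_true(all(cond$n_signal <= 64 & cond$n_signal >= 55))
  expect_true(all(cond$n_noise <= 64 & cond$n_noise >= 55))
  # metrics match a direct computation on the classified trials
  out <- classify_trials(s$trials, res)
  for (k in 1:2) {
    cnd <- cond$condition[k]
    sel <- s$trials$condition == cnd & out != "excluded"
    nh <- sum(out[sel] == "hit"); ns <- sum(out[sel] %in% c("hit", "miss"))
    nf <- sum(out[sel] == "fa"); nn <- sum(out[sel] %in% c("fa", "cr"))
    r <- corrected_rates(nh, ns, nf, nn)
    expect_equal(cond$dprime[k],
                 sdt_metrics(r$hit_rate, r$fa_rate)$dprime)
  }
})

test_that("aggregation matches hand-computed metrics on a constructed dataset", {
  counts <- tibble::tibble(
    subject_id = 1L, condition = c("threat", "safe"),
    prior_context = "rare", n_sig = 16L, n_hit = c(12L, 10L),
    n_noise = 16L, n_fa = c(2L, 0L))
  hd <- hand_dataset(counts)
  cells <- aggregate_cells(hd$trials, hd$results, cells = "condition")
  threat <- cells[cells$condition == "threat", ]
  expect_equal(threat$dprime, qnorm(12 / 16) - qnorm(2 / 16))
  safe <- cells[cells$condition == "safe", ]
  expect_equal(safe$dprime, qnorm(10 / 16) - qnorm(0.25 / 16))
  expect_equal(safe$criterion, -(qnorm(10 / 16) + qnorm(0.25 / 16)) / 2)
  expect_equal(threat$hit_rate, 0.75)
})
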