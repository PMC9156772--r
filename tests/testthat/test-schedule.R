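test_that("session schedules satisfy the design invariants across seeds", {
  for (seed in 1:5) {
    s <- build_session(seed = seed, subject_id = seed)
    tr <- s$trials

    expect_equal(length(unique(tr$block_index)), 8)
    expect_setequal(unique(tr$phase), c("manipulation", "experimental"))
    expect_equal(sum(s$manipulation_order == "rare"), 4)
    expect_equal(sum(s$manipulation_order == "frequent"), 4)

    exp_tr <- tr[tr$phase == "experimental", ]
    man_tr <- tr[tr$phase == "manipulation", ]
    for (b in 1:8) {
      eb <- exp_tr[exp_tr$block_index == b, ]
      expect_equal(nrow(eb), 38)
      expect_equal(sum(eb$stimulus == "target"), 19)
      expect_equal(sum(eb$included_in_analysis), 32)
      expect_equal(sum(eb$included_in_analysis & eb$condition == "threat"), 16)
      expect_equal(sum(eb$included_in_analysis & eb$condition == "safe"), 16)
      expect_equal(sum(eb$reinforced), 3)
      expect_equal(sum(eb$condition == "threat"), 20)
      expect_equal(sum(eb$extra_trial), 6)
      expect_equal(sum(eb$extra_trial & eb$condition == "threat"), 4)
      expect_equal(sum(eb$shortened_response), 4)

      mb <- man_tr[man_tr$block_index == b, ]
      expect_equal(nrow(mb), 20)
      n_targets <- sum(mb$stimulus == "target")
      expect_equal(n_targets, if (mb$prior_context[1] == "rare") 4 else 16)
    }

    # cross-field invariants
    expect_true(all(exp_tr$condition[exp_tr$reinforced] == "threat"))
    expect_true(all(!exp_tr$included_in_analysis[exp_tr$extra_trial]))
    expect_true(all(exp_tr$shortened_response <= exp_tr$extra_trial))
    expect_true(all(man_tr$condition == "neutral"))
    expect_true(all(exp_tr$fixation_duration_ms >= 1000 &
                      exp_tr$fixation_duration_ms <= 3000))
    expect_true(all(diff(tr$trial_onset_s) > 0))
  }
})

test_that("schedules are bit-reproducible under a fixed seed", {
  a <- build_session(seed = 99, subject_id = 3)
  b <- build_session(seed = 99, subject_id = 3)
  expect_identical(a$trials, b$trials)
  c <- build_session(seed = 100, subject_id = 3)
  expect_false(identical(a$trials, c$trials))
})

test_that("counterbalancing follows subject parity with overrides", {
  odd <- build_session(seed = 1, subject_id = 1)
  even <- build_session(seed = 1, subject_id = 2)
  expect_equal(odd$manipulation_order[1:2], c("rare", "frequent"))
  expect_equal(even$manipulation_order[1:2], c("frequent", "rare"))
  expect_equal(odd$colour_assignment, "orange_threat")
  expect_equal(even$colour_assignment, "blue_threat")
  forced <- build_session(seed = 1, subject_id = 1,
                          manipulation_order = rep("rare", 8),
                          colour_assignment = "blue_threat")
  expect_equal(unique(forced$manipulation_order), "rare")
  expect_equal(forced$colour_assignment, "blue_threat")
})

test_that("a block without extra trials has 32 trials, all analysed", {
  cfg <- design_config(n_extra_threat = 0, n_extra_safe = 0,
                       n_extra_targets = 0, n_reinforced = 0, n_shortened = 0)
  set.seed(5)
  blk <- build_experimental_block(cfg)
  expect_equal(nrow(blk), 32)
  expect_true(all(blk$included_in_analysis))
  expect_true(all(inclusion_flags(blk)))
})

test_that("invalid design parameters raise configuration errors", {
  expect_error(design_config(rate_rare = 1.2), class = "threatsdt_config_error")
  expect_error(design_config(n_threat_core = 16, n_safe_core = 14),
               class = "threatsdt_config_error")
  expect_error(design_config(n_reinforced = 5, n_extra_threat = 4),
               class = "threatsdt_config_error")
  s <- build_session(seed = 1)
  man <- s$trials[s$trials$phase == "manipulation", ]
  expect_error(inclusion_flags(man), class = "threatsdt_contract_error")
})

test_that("schedules round-trip through the CSV serialisation", {
  s <- build_session(seed = 7, subject_id = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(s, path)
  back <- read_schedule_csv(path)
  expect_equal(nrow(back), nrow(s$trials))
  expect_identical(back$included_in_analysis, s$trials$included_in_analysis)
  expect_equal(back$fixation_duration_ms, s$trials$fixation_duration_ms,
               tolerance = 1e-9)
})
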