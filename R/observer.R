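#' Latent signal-detection observer
#'
#' Parameters of the equal-variance Gaussian observer that generates yes/no
#' responses. On a target trial the decision variable is drawn from
#' `N(d', 1)`, on a lure trial from `N(0, 1)`; the observer responds "present"
#' when it exceeds `d'/2 + c`, where the criterion `c` is the base criterion
#' plus the shift induced by the current target-frequency context (positive
#' shift = more conservative). Sensitivities `dprime_threat` / `dprime_safe`
#' are defined at the observer's reference mask contrast `contrast_ref`
#' (normally the staircase-titrated contrast); visibility at other contrasts
#' follows the logistic decay of [dprime_at_contrast()].
#'
#' @param dprime_threat,dprime_safe Sensitivity per threat condition at the
#'   reference contrast.
#' @param criterion_base Criterion common to both contexts.
#' @param criterion_shift_rare,criterion_shift_frequent Additive criterion
#'   shifts after a rare (20% targets) or frequent (80%) manipulation block.
#' @param criterion_threat_delta Additive criterion change under threat
#'   (default 0: no threat modulation of the response bias).
#' @param lapse_rate Probability of a random guess irrespective of evidence.
#' @param nonresponse_rate Probability of giving no response.
#' @param rt_mean_threat_ms,rt_mean_safe_ms Mean response time per condition.
#' @param rt_sd_ms Within-subject trial-to-trial RT standard deviation
#'   (lognormal RT model).
#' @param hr_coupling Latent autonomic trait (standard-normal scale) linking
#'   a subject's heart-rate deceleration depth to their response speed.
#' @param contrast_ref Mask contrast at which the `dprime_*` values apply.
#' @param contrast_k,contrast_mid Slope and midpoint of the logistic
#'   visibility decay over mask contrast.
#' @returns A list of class `observer_params`.
#' @export
observer_params <- function(dprime_threat = 1.66,
                            dprime_safe = 1.55,
                            criterion_base = 0.365,
                            criterion_shift_rare = 0.165,
                            criterion_shift_frequent = -0.165,
                            criterion_threat_delta = 0,
                            lapse_rate = 0.01,
                            nonresponse_rate = 0.0135,
                            rt_mean_threat_ms = 632.4,
                            rt_mean_safe_ms = 616.5,
                            rt_sd_ms = 150,
                            hr_coupling = 0,
                            contrast_ref = 0.5,
                            contrast_k = 6,
                            contrast_mid = 0.5) {
  assert_prob(lapse_rate, "lapse_rate")
  assert_prob(nonresponse_rate, "nonresponse_rate")
  if (rt_sd_ms <= 0) stop_config("rt_sd_ms must be positive")
  structure(list(
    dprime_threat = dprime_threat, dprime_safe = dprime_safe,
    criterion_base = criterion_base,
    criterion_shift_rare = criterion_shift_rare,
    criterion_shift_frequent = criterion_shift_frequent,
    criterion_threat_delta = criterion_threat_delta,
    lapse_rate = lapse_rate, nonresponse_rate = nonresponse_rate,
    rt_mean_threat_ms = rt_mean_threat_ms, rt_mean_safe_ms = rt_mean_safe_ms,
    rt_sd_ms = rt_sd_ms, hr_coupling = hr_coupling,
    contrast_ref = contrast_ref,
    contrast_k = contrast_k, contrast_mid = contrast_mid
  ), class = "observer_params")
}

# Logistic visibility factor, decreasing in mask contrast.
contrast_factor <- function(m, k, mid) 1 / (1 + exp(k * (m - mid)))

#' Sensitivity as a function of backward-mask contrast
#'
#' Maps mask Michelson contrast to d' via a logistic decay normalised so that
#' d' equals `dprime` at the observer's reference contrast. Strictly
#' decreasing in contrast; maximal (unmasked) d' at contrast 0.
#'
#' @param observer An [observer_params()].
#' @param mask_contrast Contrast in `[0, 1]` (vectorised).
#' @param dprime Baseline sensitivity at the reference contrast; defaults to
#'   the observer's safe-condition d' (the staircase runs without threat).
#' @returns Numeric d' values.
#' @export
dprime_at_contrast <- function(observer, mask_contrast,
                               dprime = observer$dprime_safe) {
  if (any(!is.finite(mask_contrast)) ||
      any(mask_contrast < 0 | mask_contrast > 1)) {
    stop_config("mask_contrast must lie in [0, 1]")
  }
  dprime * contrast_factor(mask_contrast, observer$contrast_k, observer$contrast_mid) /
    contrast_factor(observer$contrast_ref, observer$contrast_k, observer$contrast_mid)
}

#' Effective decision criterion in a design cell
#'
#' `criterion_base` plus the context shift (`rare` raises the criterion,
#' `frequent` lowers it) plus the threat modulation (0 by default).
#'
#' @param observer An [observer_params()].
#' @param prior_context `"rare"`, `"frequent"`, or `"none"` (no shift, used in
#'   staircase/familiarisation phases).
#' @param condition `"threat"`, `"safe"`, or `"neutral"`.
#' @returns Numeric criterion (vectorised over the two enum arguments).
#' @export
effective_criterion <- function(observer, prior_context = "none",
                                condition = "safe") {
  bad <- !prior_context %in% c("rare", "frequent", "none")
  if (any(bad)) stop_config("unknown prior_context")
  if (any(!condition %in% c("threat", "safe", "neutral"))) {
    stop_config("unknown condition")
  }
  shift <- ifelse(prior_context == "rare", observer$criterion_shift_rare,
                  ifelse(prior_context == "frequent",
                         observer$criterion_shift_frequent, 0))
  observer$criterion_base + shift +
    ifelse(condition == "threat", observer$criterion_threat_delta, 0)
}

# Lognormal (meanlog, sdlog) matching a target mean and sd.
lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate responses to a set of trials
#'
#' Runs the equal-variance observer over the rows of a trial table. Evidence
#' is `N(d' * 1[target], 1)`; the response is "present" iff evidence exceeds
#' `d'/2 + c` for the trial's condition and context, overridden by a uniform
#' guess with probability `lapse_rate` and by a non-response ("none") with
#' probability `nonresponse_rate`. RTs are lognormal with the condition's
#' mean; neutral (manipulation) trials use the safe parameters.
#'
#' @param observer An [observer_params()].
#' @param trials Trial tibble as produced by [build_session()] (columns
#'   `condition`, `stimulus`, `prior_context`, `phase`, `mask_contrast`).
#' @param mask_contrast Contrast for trials whose `mask_contrast` is `NA`
#'   (the experimental blocks); defaults to the observer's reference contrast.
#' @param seed Optional integer seed.
#' @returns Tibble with columns `response` (`"present"`, `"absent"`,
#'   `"none"`), `rt_ms`, `evidence`.
#' @export
simulate_responses <- function(observer, trials,
                               mask_contrast = NULL, seed = NULL) {
  if (is.null(trials$stimulus) || any(is.na(trials$stimulus))) {
    stop_contract("every trial needs a stimulus assignment")
  }
  n <- nrow(trials)
  m <- trials$mask_contrast
  m[is.na(m)] <- mask_contrast %||% observer$contrast_ref

  base <- ifelse(trials$condition == "threat",
                 observer$dprime_threat, observer$dprime_safe)
  dp <- dprime_at_contrast(observer, m, dprime = base)
  ctx <- trials$prior_context %||% rep("none", n)
  ctx[!ctx %in% c("rare", "frequent")] <- "none"
  crit <- effective_criterion(observer, ctx, trials$condition)

  local_seed(seed, {
    evidence <- rnorm(n, mean = dp * (trials$stimulus == "target"), sd = 1)
    present <- evidence > dp / 2 + crit
    lapse <- runif(n) < observer$lapse_rate
    present[lapse] <- runif(sum(lapse)) < 0.5
    response <- ifelse(present, "present", "absent")
    response[runif(n) < observer$nonresponse_rate] <- "none"

    rt_mean <- ifelse(trials$condition == "threat",
                      observer$rt_mean_threat_ms, observer$rt_mean_safe_ms)
    lp <- lnorm_pars(rt_mean, observer$rt_sd_ms)
    rt <- rlnorm(n, lp$meanlog, lp$sdlog)
    rt[response == "none"] <- NA_real_
    tibble::tibble(response = response, rt_ms = rt, evidence = evidence)
  })
}

#' @rdname simulate_responses
#' @param trial A single-row trial table (or one-row list coercible to it).
#' @export
simulate_response <- function(observer, trial, mask_contrast = NULL,
                              seed = NULL) {
  out <- simulate_responses(observer, tibble::as_tibble(trial),
                            mask_contrast = mask_contrast, seed = seed)
  as.list(out[1L, ])
}

#' Population-level parameters
#'
#' Means, between-subject SDs and the across-subject correlation structure
#' from which whole samples of observers (and their autonomic traits) are
#' drawn. Defaults reproduce the study's printed group means; between-subject
#' SDs are the printed SDs with the per-subject estimation noise of the
#' 64-target/64-lure design removed (see the package vignette for the
#' decomposition). Correlations are induced through a Gaussian copula:
#' `cor_hr_rt` links the bradycardia trait to mean RT (deeper deceleration,
#' faster responses) and `cor_dprime_shift` links sensitivity to the
#' magnitude of the context-induced criterion shift.
#'
#' @param n_subjects Number of observers to draw.
#' @param dprime_safe_mean,dprime_safe_sd Latent safe-condition sensitivity.
#' @param dprime_delta_mean,dprime_delta_sd Threat minus safe sensitivity.
#' @param criterion_base_mean,criterion_base_sd Base criterion.
#' @param criterion_shift_mean,criterion_shift_sd Context shift magnitude
#'   (rare = +shift, frequent = -shift).
#' @param rt_safe_mean,rt_safe_sd,rt_delta_mean,rt_delta_sd RT structure (ms).
#' @param rt_trial_sd Within-subject RT SD (ms).
#' @param lapse_rate Shared lapse rate.
#' @param nonresponse_shape1,nonresponse_shape2 Beta parameters of the
#'   per-subject non-response rate (mean ~1.35%, SD ~2.2%).
#' @param decel_threat_mean,decel_threat_sd,decel_safe_mean,decel_safe_sd
#'   Event-related heart-rate change traits (BPM; negative = deceleration).
#' @param cor_decel_threat_safe Correlation of the two deceleration traits.
#' @param decel_hit_extra_mean,decel_hit_extra_sd Hit-minus-miss
#'   deceleration difference trait (BPM).
#' @param scr_sqrt_threat_mean,scr_sqrt_threat_sd Subject mean square-root
#'   SCR amplitude under threat (lognormal across subjects, sqrt-microsiemens).
#' @param scr_sqrt_safe_mean,scr_sqrt_safe_sd Same for safe.
#' @param cor_scr_threat_safe Copula correlation of the two SCR traits.
#' @param cor_hr_rt,cor_dprime_shift Copula correlations described above.
#' @returns A list of class `population_params`.
#' @export
population_params <- function(n_subjects = 52,
                              dprime_safe_mean = 1.55, dprime_safe_sd = 0.56,
                              dprime_delta_mean = 0.11, dprime_delta_sd = 0.10,
                              criterion_base_mean = 0.365, criterion_base_sd = 0.38,
                              criterion_shift_mean = 0.165, criterion_shift_sd = 0.15,
                              rt_safe_mean = 616.5, rt_safe_sd = 88.4,
                              rt_delta_mean = 15.9, rt_delta_sd = 25.8,
                              rt_trial_sd = 150,
                              lapse_rate = 0.01,
                              nonresponse_shape1 = 0.35, nonresponse_shape2 = 25.24,
                              decel_threat_mean = -4.38, decel_threat_sd = 2.12,
                              decel_safe_mean = -2.99, decel_safe_sd = 1.68,
                              cor_decel_threat_safe = 0.85,
                              decel_hit_extra_mean = 0.4,
                              decel_hit_extra_sd = 1.0,
                              scr_sqrt_threat_mean = 0.24, scr_sqrt_threat_sd = 0.24,
                              scr_sqrt_safe_mean = 0.09, scr_sqrt_safe_sd = 0.07,
                              cor_scr_threat_safe = 0.5,
                              cor_hr_rt = 0.32, cor_dprime_shift = -0.29) {
  if (n_subjects < 2) stop_config("n_subjects must be at least 2")
  for (r in c(cor_decel_threat_safe, cor_scr_threat_safe,
              cor_hr_rt, cor_dprime_shift)) {
    if (!is.finite(r) || abs(r) > 1) stop_config("correlations must lie in [-1, 1]")
  }
  structure(as.list(environment()), class = "population_params")
}

# Correlated standard-normal latents: (hr, rt) and (dprime, shift) pairs.
copula_latents <- function(n, cor_hr_rt, cor_dprime_shift) {
  pair <- function(rho) {
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    list(z1, z2)
  }
  hr_rt <- pair(cor_hr_rt)
  dp_sh <- pair(cor_dprime_shift)
  list(z_hr = hr_rt[[1]], z_rt = hr_rt[[2]],
       z_dp = dp_sh[[1]], z_shift = dp_sh[[2]])
}

#' Draw a sample of observers
#'
#' Samples `n_subjects` observers plus their autonomic traits from a
#' [population_params()]. Deterministic given `seed`; sample moments converge
#' to the population values as n grows.
#'
#' @param pop A [population_params()].
#' @param seed Integer seed.
#' @returns A tibble with one row per subject: every [observer_params()]
#'   field plus the physiological traits (`decel_threat_bpm`,
#'   `decel_safe_bpm`, `scr_sqrt_threat`, `scr_sqrt_safe`). Use
#'   [observer_from_row()] to materialise a single observer.
#' @export
sample_population <- function(pop = population_params(), seed = 1L) {
  n <- pop$n_subjects
  local_seed(seed, {
    z <- copula_latents(n, pop$cor_hr_rt, pop$cor_dprime_shift)

    dprime_safe <- pop$dprime_safe_mean + pop$dprime_safe_sd * z$z_dp
    dprime_threat <- dprime_safe + pop$dprime_delta_mean +
      pop$dprime_delta_sd * rnorm(n)
    criterion_base <- pop$criterion_base_mean + pop$criterion_base_sd * rnorm(n)
    shift <- pop$criterion_shift_mean + pop$criterion_shift_sd * z$z_shift

    rt_safe <- pop$rt_safe_mean + pop$rt_safe_sd * z$z_rt
    rt_threat <- rt_safe + pop$rt_delta_mean + pop$rt_delta_sd * rnorm(n)
    nonresponse <- qbeta(pnorm(rnorm(n)),
                         pop$nonresponse_shape1, pop$nonresponse_shape2)

    rho <- pop$cor_decel_threat_safe
    decel_threat <- pop$decel_threat_mean + pop$decel_threat_sd * z$z_hr
    decel_safe <- pop$decel_safe_mean + pop$decel_safe_sd *
      (rho * z$z_hr + sqrt(1 - rho^2) * rnorm(n))
    decel_hit_extra <- pop$decel_hit_extra_mean +
      pop$decel_hit_extra_sd * rnorm(n)

    lt <- lnorm_pars(pop$scr_sqrt_threat_mean, pop$scr_sqrt_threat_sd)
    ls <- lnorm_pars(pop$scr_sqrt_safe_mean, pop$scr_sqrt_safe_sd)
    z_scr <- rnorm(n)
    rs <- pop$cor_scr_threat_safe
    scr_t <- qlnorm(pnorm(z_scr), lt$meanlog, lt$sdlog)
    scr_s <- qlnorm(pnorm(rs * z_scr + sqrt(1 - rs^2) * rnorm(n)),
                    ls$meanlog, ls$sdlog)

    tibble::tibble(
      subject_id = seq_len(n),
      dprime_threat = dprime_threat, dprime_safe = dprime_safe,
      criterion_base = criterion_base,
      criterion_shift_rare = shift, criterion_shift_frequent = -shift,
      criterion_threat_delta = 0,
      lapse_rate = pop$lapse_rate, nonresponse_rate = nonresponse,
      rt_mean_threat_ms = rt_threat, rt_mean_safe_ms = rt_safe,
      rt_sd_ms = pop$rt_trial_sd,
      hr_coupling = z$z_hr,
      decel_threat_bpm = decel_threat, decel_safe_bpm = decel_safe,
      decel_hit_extra_bpm = decel_hit_extra,
      scr_sqrt_threat = scr_t, scr_sqrt_safe = scr_s
    )
  })
}

#' Materialise one observer from a population row
#' @param row One row of the tibble returned by [sample_population()].
#' @returns An [observer_params()].
#' @export
observer_from_row <- function(row) {
  observer_params(
    dprime_threat = row$dprime_threat, dprime_safe = row$dprime_safe,
    criterion_base = row$criterion_base,
    criterion_shift_rare = row$criterion_shift_rare,
    criterion_shift_frequent = row$criterion_shift_frequent,
    criterion_threat_delta = row$criterion_threat_delta,
    lapse_rate = row$lapse_rate, nonresponse_rate = row$nonresponse_rate,
    rt_mean_threat_ms = row$rt_mean_threat_ms,
    rt_mean_safe_ms = row$rt_mean_safe_ms,
    rt_sd_ms = row$rt_sd_ms, hr_coupling = row$hr_coupling
  )
}
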