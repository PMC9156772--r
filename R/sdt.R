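#' Classify trials into signal-detection outcomes
#'
#' Labels each trial `hit`, `miss`, `fa` (false alarm), `cr` (correct
#' rejection), or `excluded`. A trial is excluded when it is not flagged for
#' analysis (extra / reinforced / shortened-response trials and all
#' manipulation-phase trials), when no response was given, or when the
#' response came later than the RT limit.
#'
#' @param trials Trial tibble ([build_session()]).
#' @param results Response tibble aligned with `trials`
#'   ([simulate_responses()]).
#' @param rt_limit_ms Responses slower than this are excluded.
#' @returns Character vector of outcomes, one per trial.
#' @export
classify_trials <- function(trials, results, rt_limit_ms = 1500) {
  if (nrow(trials) != nrow(results)) {
    stop_contract("trials and results must align")
  }
  excluded <- !trials$included_in_analysis |
    results$response == "none" |
    (!is.na(results$rt_ms) & results$rt_ms > rt_limit_ms)
  target <- trials$stimulus == "target"
  present <- results$response == "present"
  out <- ifelse(target, ifelse(present, "hit", "miss"),
                ifelse(present, "fa", "cr"))
  out[excluded] <- "excluded"
  out
}

#' @rdname classify_trials
#' @param trial,result Single trial / response (one-row data or lists).
#' @export
classify_trial <- function(trial, result, rt_limit_ms = 1500) {
  classify_trials(tibble::as_tibble(trial), tibble::as_tibble(result),
                  rt_limit_ms)[1L]
}

#' Hit and false-alarm rates with the 0.25 extreme-count correction
#'
#' Plain proportions, except that a zero false-alarm count is replaced by
#' 0.25 and a perfect hit count by `n_signal - 0.25` before dividing, so the
#' rates stay strictly inside (0, 1) and d'/criterion remain finite. Both
#' cells are corrected when both are extreme.
#'
#' @param n_hit,n_signal,n_fa,n_noise Outcome and trial counts (vectorised).
#' @returns A list with `hit_rate` and `fa_rate`.
#' @export
corrected_rates <- function(n_hit, n_signal, n_fa, n_noise) {
  if (any(n_signal < 1) || any(n_noise < 1)) {
    stop_config("n_signal and n_noise must be at least 1")
  }
  if (any(n_hit < 0 | n_fa < 0 | n_hit > n_signal | n_fa > n_noise)) {
    stop_config("counts must satisfy 0 <= n_hit <= n_signal, 0 <= n_fa <= n_noise")
  }
  h <- ifelse(n_hit == n_signal, n_signal - 0.25, n_hit)
  h <- ifelse(h == 0, 0.25, h)
  f <- ifelse(n_fa == 0, 0.25, n_fa)
  f <- ifelse(f == n_noise, n_noise - 0.25, f)
  list(hit_rate = h / n_signal, fa_rate = f / n_noise)
}

#' Sensitivity and criterion from rates
#'
#' `d' = z(hit rate) - z(false-alarm rate)` and
#' `c = -(z(hit rate) + z(false-alarm rate)) / 2`, with `z` the
#' standard-normal quantile function. Rates must be strictly inside (0, 1)
#' (apply [corrected_rates()] first).
#'
#' @param hit_rate,fa_rate Rates in (0, 1) (vectorised).
#' @returns A list with `dprime` and `criterion`.
#' @export
sdt_metrics <- function(hit_rate, fa_rate) {
  r <- c(hit_rate, fa_rate)
  if (any(!is.finite(r)) || any(r <= 0 | r >= 1)) {
    stop_config("rates must lie strictly inside (0, 1); correct extreme counts first")
  }
  zh <- qnorm(hit_rate)
  zf <- qnorm(fa_rate)
  list(dprime = zh - zf, criterion = -(zh + zf) / 2)
}

# Match per-trial physiology onto classified trials; physio tables from
# score_session_physio() are per subject, so join on subject too when the
# column is present.
join_physio <- function(df, physio) {
  cols <- c("trial_index", "delta_bpm_trial", "delta_bpm_stim", "sqrt_scr")
  if ("subject_id" %in% names(physio)) {
    dplyr::left_join(df, physio[, c("subject_id", cols)],
                     by = c("subject_id", "trial_index"))
  } else {
    dplyr::left_join(df, physio[, cols], by = "trial_index")
  }
}

sdt_cell <- function(target, present) {
  n_signal <- sum(target)
  n_noise <- sum(!target)
  if (n_signal == 0 || n_noise == 0) {
    return(list(n_signal = n_signal, n_noise = n_noise,
                n_hit = NA_real_, n_fa = NA_real_, hit_rate = NA_real_,
                fa_rate = NA_real_, dprime = NA_real_, criterion = NA_real_))
  }
  n_hit <- sum(target & present)
  n_fa <- sum(!target & present)
  r <- corrected_rates(n_hit, n_signal, n_fa, n_noise)
  m <- sdt_metrics(r$hit_rate, r$fa_rate)
  list(n_signal = n_signal, n_noise = n_noise,
       n_hit = n_hit, n_fa = n_fa,
       hit_rate = n_hit / n_signal, fa_rate = n_fa / n_noise,
       dprime = m$dprime, criterion = m$criterion)
}

#' Aggregate trials into per-subject design-cell metrics
#'
#' Builds the subject-level tables every analysis runs on. Only trials
#' classified as hit/miss/fa/cr (i.e. not excluded) contribute. Three
#' partitions are returned in one tibble, distinguished by the
#' `condition` / `prior_context` columns (either may be `"pooled"`):
#' per condition (threat, safe), per context (rare, frequent), and the
#' full 2 x 2. Each row carries counts, corrected-rate SDT metrics, the raw
#' hit rate, mean RT, and (when per-trial physiology is supplied) mean
#' heart-rate change and mean square-root SCR amplitude.
#'
#' @param trials,results Aligned trial and response tibbles; may contain
#'   several subjects (`subject_id` column).
#' @param physio Optional per-trial physiology ([score_session_physio()]),
#'   matched by `trial_index` within subject.
#' @param cells Which partitions to return.
#' @param rt_limit_ms Passed to [classify_trials()].
#' @returns A tibble, one row per subject x requested cell. Empty cells
#'   yield missing metrics with a warning.
#' @export
aggregate_cells <- function(trials, results, physio = NULL,
                            cells = c("condition", "context", "condition_context"),
                            rt_limit_ms = 1500) {
  outcome <- classify_trials(trials, results, rt_limit_ms)
  df <- tibble::tibble(
    subject_id = trials$subject_id,
    trial_index = trials$trial_index,
    condition = trials$condition,
    prior_context = trials$prior_context,
    target = trials$stimulus == "target",
    present = results$response == "present",
    rt_ms = results$rt_ms,
    outcome = outcome
  )
  df <- df[df$outcome != "excluded", ]
  if (!is.null(physio)) {
    df <- join_physio(df, physio)
  } else {
    df$delta_bpm_trial <- df$delta_bpm_stim <- df$sqrt_scr <- NA_real_
  }

  one_partition <- function(d, by_condition, by_context) {
    d$condition <- if (by_condition) d$condition else "pooled"
    d$prior_context <- if (by_context) d$prior_context else "pooled"
    out <- d |>
      dplyr::group_by(.data$subject_id, .data$condition, .data$prior_context) |>
      dplyr::summarise(
        n_signal = sum(.data$target),
        n_noise = sum(!.data$target),
        n_hit = sum(.data$target & .data$present),
        n_fa = sum(!.data$target & .data$present),
        mean_rt_ms = mean(.data$rt_ms, na.rm = TRUE),
        mean_delta_bpm = mean(.data$delta_bpm_trial, na.rm = TRUE),
        mean_delta_bpm_stim = mean(.data$delta_bpm_stim, na.rm = TRUE),
        mean_sqrt_scr = mean(.data$sqrt_scr, na.rm = TRUE),
        .groups = "drop")
    ok <- out$n_signal > 0 & out$n_noise > 0
    out$hit_rate <- out$fa_rate <- out$dprime <- out$criterion <- NA_real_
    if (any(ok)) {
      r <- corrected_rates(out$n_hit[ok], out$n_signal[ok],
                           out$n_fa[ok], out$n_noise[ok])
      m <- sdt_metrics(r$hit_rate, r$fa_rate)
      out$hit_rate[ok] <- out$n_hit[ok] / out$n_signal[ok]
      out$fa_rate[ok] <- out$n_fa[ok] / out$n_noise[ok]
      out$dprime[ok] <- m$dprime
      out$criterion[ok] <- m$criterion
    }
    out
  }

  res <- list()
  if ("condition" %in% cells) res$condition <- one_partition(df, TRUE, FALSE)
  if ("context" %in% cells) res$context <- one_partition(df, FALSE, TRUE)
  if ("condition_context" %in% cells) {
    res$condition_context <- one_partition(df, TRUE, TRUE)
  }
  out <- dplyr::bind_rows(res)
  if (any(is.na(out$dprime))) {
    warning("empty design cells produced missing SDT metrics")
  }
  dplyr::arrange(out, .data$subject_id, .data$condition, .data$prior_context)
}

#' Per-subject physiology split by detection outcome
#'
#' Means of the physiological measures over hit and miss trials (targets
#' only) per subject and threat condition, for the Threat x Detection
#' repeated-measures analyses.
#'
#' @inheritParams aggregate_cells
#' @returns A tibble: `subject_id`, `condition`, `outcome` (hit/miss),
#'   `n_trials`, `mean_delta_bpm`, `mean_delta_bpm_stim`, `mean_sqrt_scr`.
#' @export
aggregate_hitmiss_physio <- function(trials, results, physio,
                                     rt_limit_ms = 1500) {
  outcome <- classify_trials(trials, results, rt_limit_ms)
  keep <- outcome %in% c("hit", "miss")
  df <- tibble::tibble(
    subject_id = trials$subject_id[keep],
    trial_index = trials$trial_index[keep],
    condition = trials$condition[keep],
    outcome = outcome[keep]
  )
  df <- join_physio(df, physio)
  df |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$outcome) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_delta_bpm = mean(.data$delta_bpm_trial, na.rm = TRUE),
      mean_delta_bpm_stim = mean(.data$delta_bpm_stim, na.rm = TRUE),
      mean_sqrt_scr = mean(.data$sqrt_scr, na.rm = TRUE),
      .groups = "drop")
}
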