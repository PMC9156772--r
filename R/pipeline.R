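#' Full study configuration
#'
#' Bundles everything needed to simulate and analyse one study: the session
#' design, the observer population, the physiological effect parameters, and
#' analysis options. The tail of each hypothesis test is fixed here:
#' one-tailed for the directional threat-vs-safe predictions on heart rate,
#' SCR, hits and d'; two-tailed everywhere else.
#'
#' @param n_subjects Number of simulated participants.
#' @param design A [design_config()].
#' @param population A [population_params()] (its `n_subjects` is overridden
#'   by `n_subjects`).
#' @param physio A [physio_effect_params()] or `NULL` to skip physiology
#'   (behavioural battery only).
#' @param include_physio Simulate and analyse the autonomic channels.
#' @param titrate_contrast Run the staircase calibration per subject (the
#'   titrated contrast becomes the observer's reference contrast). When
#'   `FALSE` the nominal reference contrast is used directly.
#' @param bootstrap_R Bootstrap resamples for effect-size CIs; 0 disables
#'   the CIs (used in large replication sweeps).
#' @param rt_limit_ms Response-time exclusion limit.
#' @param exclude_nonresponse_rate Subjects above this non-response fraction
#'   are excluded.
#' @param exclude_accuracy_sd Subjects whose overall accuracy deviates more
#'   than this many SDs from the (pre-exclusion) sample mean are excluded.
#' @param seed Master seed (mandatory); all per-subject and analysis seeds
#'   derive from it.
#' @returns A list of class `study_config`.
#' @export
study_config <- function(n_subjects = 52,
                         design = design_config(),
                         population = population_params(),
                         physio = physio_effect_params(),
                         include_physio = TRUE,
                         titrate_contrast = TRUE,
                         bootstrap_R = 2000,
                         rt_limit_ms = 1500,
                         exclude_nonresponse_rate = 1 / 3,
                         exclude_accuracy_sd = 2,
                         seed = 1L) {
  if (is.null(seed)) stop_config("a seed is mandatory")
  population$n_subjects <- n_subjects
  structure(list(
    n_subjects = n_subjects, design = design, population = population,
    physio = physio, include_physio = include_physio,
    titrate_contrast = titrate_contrast, bootstrap_R = bootstrap_R,
    rt_limit_ms = rt_limit_ms,
    exclude_nonresponse_rate = exclude_nonresponse_rate,
    exclude_accuracy_sd = exclude_accuracy_sd,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Simulate one complete study and run the full analysis battery
#'
#' Executes, in order: session schedules, staircase contrast titration,
#' observer responses, physiological trace generation and scoring, subject
#' exclusions, cell aggregation, and the hypothesis battery of
#' [run_analysis()].
#'
#' @param config A [study_config()].
#' @returns A list of class `study_results`: `cells` (subject x cell
#'   metrics), `hitmiss` (physiology by detection outcome), `hypotheses`
#'   (results table), `observers`, `excluded_subjects`, `staircase`
#'   (per-subject titrated contrast and flags), `provenance`.
#' @export
run_synthetic_study <- function(config = study_config()) {
  seeds <- derive_seeds(config$seed, 4L)
  observers <- sample_population(config$population, seed = seeds[1])
  n <- nrow(observers)
  subj_seeds <- matrix(derive_seeds(seeds[2], 4L * n), nrow = n)

  trials_list <- vector("list", n)
  results_list <- vector("list", n)
  physio_list <- vector("list", n)
  stair <- tibble::tibble(subject_id = observers$subject_id,
                          contrast = NA_real_, staircase_failure = FALSE)

  for (i in seq_len(n)) {
    obs <- observer_from_row(observers[i, ])
    if (config$titrate_contrast) {
      cal <- calibrate_contrast(obs, seed = subj_seeds[i, 1])
      # the titrated contrast becomes the contrast at which the observer's
      # nominal sensitivities apply (performance there is what the staircase
      # fixed); sensitivity at other contrasts still follows the logistic.
      obs$contrast_ref <- cal$contrast
      stair$contrast[i] <- cal$contrast
      stair$staircase_failure[i] <- cal$failure
    }
    sched <- build_session(config$design, subject_id = observers$subject_id[i],
                           seed = subj_seeds[i, 2])
    res <- simulate_responses(obs, sched$trials, seed = subj_seeds[i, 3])
    if (config$include_physio && !is.null(config$physio)) {
      fx <- config$physio
      fx$decel_threat_bpm <- observers$decel_threat_bpm[i]
      fx$decel_safe_bpm <- observers$decel_safe_bpm[i]
      fx$decel_hit_extra_bpm <- observers$decel_hit_extra_bpm[i]
      fx$scr_sqrt_threat <- observers$scr_sqrt_threat[i]
      fx$scr_sqrt_safe <- observers$scr_sqrt_safe[i]
      ps <- derive_seeds(subj_seeds[i, 4], 2L)
      bpm <- generate_bpm_trace(sched, res, fx, seed = ps[1])
      eda <- generate_eda_trace(sched, res, fx, seed = ps[2])
      physio_list[[i]] <- score_session_physio(sched, bpm, eda)
    }
    trials_list[[i]] <- sched$trials
    results_list[[i]] <- res
  }
  trials <- dplyr::bind_rows(trials_list)
  results <- dplyr::bind_rows(results_list)
  physio <- if (config$include_physio) dplyr::bind_rows(physio_list) else NULL

  out <- run_analysis(trials, results, physio = physio, config = config)
  out$observers <- observers
  out$staircase <- stair
  out
}

# Subject-level exclusion: non-response fraction and overall accuracy beyond
# mean +- k SD, with mean and SD computed on the pre-exclusion sample.
apply_subject_exclusions <- function(trials, results, config) {
  exp_trials <- trials$phase == "experimental"
  per <- tibble::tibble(subject_id = trials$subject_id[exp_trials],
                        stimulus = trials$stimulus[exp_trials],
                        response = results$response[exp_trials]) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      nonresp = mean(.data$response == "none"),
      accuracy = mean((.data$stimulus == "target") ==
                        (.data$response == "present")),
      .groups = "drop")
  mu <- mean(per$accuracy); s <- sd(per$accuracy)
  lim <- config$exclude_accuracy_sd
  bad <- per$nonresp > config$exclude_nonresponse_rate |
    (s > 0 & abs(per$accuracy - mu) > lim * s)
  per$excluded <- bad
  per
}

#' Run the study's hypothesis battery on trial-level data
#'
#' Applies the complete analysis chain to supplied (simulated or loaded)
#' tables: subject exclusions, cell aggregation, then the battery:
#' criterion after rare vs frequent blocks (Wilcoxon, two-tailed, with an
#' ART interaction cross-check); threat vs safe one-tailed tests on
#' heart-rate change (paired t), SCR (paired t), hit rate (paired t) and d'
#' (Wilcoxon); threat vs safe criterion and the Threat x Frequency
#' interaction contrast (Wilcoxon); d' vs criterion-shift association
#' (Spearman); Threat x Detection repeated-measures ANOVAs on heart rate
#' (trial- and stimulus-aligned) and SCR; the safe-trial carryover t test;
#' threat vs safe RT (Wilcoxon); and the RT/heart-rate Spearman
#' correlations. Physiology rows are marked missing when no physiology is
#' supplied.
#'
#' @param trials,results Aligned trial and response tibbles (any number of
#'   subjects).
#' @param physio Optional per-trial physiology table.
#' @param config A [study_config()] carrying the analysis options.
#' @returns A `study_results` list (see [run_synthetic_study()]).
#' @export
run_analysis <- function(trials, results, physio = NULL,
                         config = study_config()) {
  check_analysis_schema(trials, results, physio)
  excl <- apply_subject_exclusions(trials, results, config)
  keep_ids <- excl$subject_id[!excl$excluded]
  keep <- trials$subject_id %in% keep_ids
  trials <- trials[keep, ]; results <- results[keep, ]
  if (!is.null(physio)) physio <- physio[physio$subject_id %in% keep_ids, ]

  cells <- aggregate_cells(trials, results, physio,
                           rt_limit_ms = config$rt_limit_ms)
  hitmiss <- if (!is.null(physio)) {
    aggregate_hitmiss_physio(trials, results, physio,
                             rt_limit_ms = config$rt_limit_ms)
  } else NULL
  carry <- carryover_means(trials, results, physio,
                           rt_limit_ms = config$rt_limit_ms)

  hypotheses <- run_battery(cells, hitmiss, carry,
                            bootstrap_R = config$bootstrap_R,
                            seed = config$seed)
  structure(list(
    cells = cells, hitmiss = hitmiss, hypotheses = hypotheses,
    excluded_subjects = excl$subject_id[excl$excluded],
    provenance = list(seed = config$seed, n_subjects = config$n_subjects,
                      config_hash = rlang::hash(config),
                      package_version = as.character(utils::packageVersion("threatsdt")))
  ), class = "study_results")
}

check_analysis_schema <- function(trials, results, physio) {
  need_t <- c("subject_id", "trial_index", "phase", "condition", "stimulus",
              "prior_context", "included_in_analysis")
  miss <- setdiff(need_t, names(trials))
  if (length(miss)) stop_contract("trials table lacks columns: ",
                                  paste(miss, collapse = ", "))
  need_r <- c("response", "rt_ms")
  miss <- setdiff(need_r, names(results))
  if (length(miss)) stop_contract("results table lacks columns: ",
                                  paste(miss, collapse = ", "))
  if (nrow(trials) != nrow(results)) {
    stop_contract("trials and results must have the same number of rows")
  }
  if (!is.null(physio)) {
    need_p <- c("subject_id", "trial_index", "delta_bpm_trial")
    miss <- setdiff(need_p, names(physio))
    if (length(miss)) stop_contract("physio table lacks columns: ",
                                    paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

# Safe trials split by the condition of the immediately preceding trial
# within the same block (carryover check on heart-rate change).
carryover_means <- function(trials, results, physio, rt_limit_ms = 1500) {
  if (is.null(physio)) return(NULL)
  outcome <- classify_trials(trials, results, rt_limit_ms)
  ord <- order(trials$subject_id, trials$trial_index)
  tr <- trials[ord, ]
  m <- nrow(tr)
  prev_cond <- c(NA, tr$condition[-m])
  same_block <- c(FALSE,
                  tr$subject_id[-1] == tr$subject_id[-m] &
                    tr$block_index[-1] == tr$block_index[-m] &
                    tr$phase[-1] == tr$phase[-m])
  df <- tibble::tibble(subject_id = tr$subject_id,
                       trial_index = tr$trial_index,
                       condition = tr$condition,
                       prev_condition = ifelse(same_block, prev_cond, NA),
                       outcome = outcome[ord])
  df <- df[df$outcome != "excluded" & df$condition == "safe" &
             df$prev_condition %in% c("threat", "safe"), ]
  df <- join_physio(df, physio)
  df |>
    dplyr::group_by(.data$subject_id, .data$prev_condition) |>
    dplyr::summarise(mean_delta_bpm = mean(.data$delta_bpm_trial, na.rm = TRUE),
                     .groups = "drop")
}

# One battery row with its bootstrap effect-size CI attached.
with_ci <- function(row, data, stat_fn, level, R, seed) {
  if (R > 0 && !is.na(row$effect_size)) {
    ci <- tryCatch(bootstrap_ci(data, stat_fn, level = level, R = R,
                                seed = seed),
                   warning = function(w) c(row$effect_size, row$effect_size))
    row$ci_low <- ci[1]; row$ci_high <- ci[2]; row$ci_level <- level
  }
  row
}

run_battery <- function(cells, hitmiss, carry, bootstrap_R = 2000,
                        seed = 1L) {
  seeds <- derive_seeds(seed + 7L, 32L)
  rows <- list()
  k <- 0L
  add <- function(name, row) {
    k <<- k + 1L
    row$hypothesis <- name
    rows[[k]] <<- row
  }

  cond <- cells[cells$prior_context == "pooled" & cells$condition != "pooled", ]
  ctx <- cells[cells$condition == "pooled" & cells$prior_context != "pooled", ]
  cc <- cells[cells$condition != "pooled" & cells$prior_context != "pooled", ]

  wide_cond <- function(metric) {
    tidyr::pivot_wider(cond[, c("subject_id", "condition", metric)],
                       names_from = "condition",
                       values_from = tidyr::all_of(metric))
  }
  wide_ctx <- function(metric) {
    tidyr::pivot_wider(ctx[, c("subject_id", "prior_context", metric)],
                       names_from = "prior_context",
                       values_from = tidyr::all_of(metric))
  }

  boot_wilcoxon_r <- function(w) {
    function(d, idx) {
      r <- suppressWarnings(wilcoxon_signed_rank(d[idx, 1], d[idx, 2]))
      r$effect_size
    }
  }
  boot_d <- function(d, idx) {
    dd <- d[idx, 1] - d[idx, 2]
    if (sd(dd) == 0) return(NA_real_)
    mean(dd) / sd(dd)
  }
  boot_rho <- function(d, idx) {
    if (sd(d[idx, 1]) == 0 || sd(d[idx, 2]) == 0) return(NA_real_)
    cor(rank(d[idx, 1]), rank(d[idx, 2]))
  }

  # --- criterion manipulation check: rare vs frequent (two-tailed) ---
  w <- wide_ctx("criterion")
  m <- as.matrix(w[, c("rare", "frequent")])
  add("criterion_rare_vs_frequent",
      with_ci(wilcoxon_signed_rank(m[, 1], m[, 2]), m, boot_wilcoxon_r(),
              0.95, bootstrap_R, seeds[1]))

  # --- threat vs safe, one-tailed directional tests ---
  has_physio <- !all(is.na(cond$mean_delta_bpm))
  if (has_physio) {
    w <- wide_cond("mean_delta_bpm"); m <- as.matrix(w[, c("threat", "safe")])
    add("hr_deceleration_threat_vs_safe",
        with_ci(paired_t(m[, 1], m[, 2], alternative = "less"), m, boot_d,
                0.90, bootstrap_R, seeds[2]))
    w <- wide_cond("mean_sqrt_scr"); m <- as.matrix(w[, c("threat", "safe")])
    add("scr_threat_vs_safe",
        with_ci(paired_t(m[, 1], m[, 2], alternative = "greater"), m, boot_d,
                0.90, bootstrap_R, seeds[3]))
  } else {
    add("hr_deceleration_threat_vs_safe",
        test_result("paired_t", "t", NA_real_, note = "no physiology supplied"))
    add("scr_threat_vs_safe",
        test_result("paired_t", "t", NA_real_, note = "no physiology supplied"))
  }

  w <- wide_cond("hit_rate"); m <- as.matrix(w[, c("threat", "safe")])
  add("hits_threat_vs_safe",
      with_ci(paired_t(m[, 1], m[, 2], alternative = "greater"), m, boot_d,
              0.90, bootstrap_R, seeds[4]))
  w <- wide_cond("dprime"); m <- as.matrix(w[, c("threat", "safe")])
  add("dprime_threat_vs_safe",
      with_ci(wilcoxon_signed_rank(m[, 1], m[, 2], alternative = "greater"),
              m, boot_wilcoxon_r(), 0.90, bootstrap_R, seeds[5]))

  # --- response bias under threat (two-tailed) ---
  w <- wide_cond("criterion"); m <- as.matrix(w[, c("threat", "safe")])
  add("criterion_threat_vs_safe",
      with_ci(wilcoxon_signed_rank(m[, 1], m[, 2]), m, boot_wilcoxon_r(),
              0.95, bootstrap_R, seeds[6]))

  # Threat x Frequency interaction on the criterion: per-subject contrast
  # (rare - frequent under threat) vs (rare - frequent under safe).
  w4 <- tidyr::pivot_wider(cc[, c("subject_id", "condition", "prior_context",
                                  "criterion")],
                           names_from = c("condition", "prior_context"),
                           values_from = "criterion")
  mi <- cbind(w4$threat_rare - w4$threat_frequent,
              w4$safe_rare - w4$safe_frequent)
  add("criterion_interaction_threat_x_frequency",
      with_ci(wilcoxon_signed_rank(mi[, 1], mi[, 2]), mi, boot_wilcoxon_r(),
              0.95, bootstrap_R, seeds[7]))
  cc_long <- cc[, c("subject_id", "condition", "prior_context", "criterion")]
  art <- art_anova_2x2(cc_long, subject = "subject_id", a = "condition",
                       b = "prior_context", value = "criterion")
  add("criterion_interaction_art_check", art[3, ])

  # --- sensitivity vs criterion-shift association ---
  pooled <- cells[cells$condition == "pooled" & cells$prior_context == "pooled", ]
  if (nrow(pooled) == 0) {
    # pooled-by-both partition is derivable from the context partition
    pooled_d <- ctx |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(dprime = mean(.data$dprime), .groups = "drop")
  } else {
    pooled_d <- pooled[, c("subject_id", "dprime")]
  }
  shift <- wide_ctx("criterion")
  ms <- as.matrix(dplyr::inner_join(pooled_d,
                                    tibble::tibble(subject_id = shift$subject_id,
                                                   shift = shift$rare - shift$frequent),
                                    by = "subject_id")[, c("dprime", "shift")])
  add("dprime_vs_criterion_shift",
      with_ci(spearman_correlation(ms[, 1], ms[, 2]), ms, boot_rho,
              0.95, bootstrap_R, seeds[8]))

  # --- Threat x Detection ANOVAs on physiology ---
  if (!is.null(hitmiss) && nrow(hitmiss) > 0) {
    complete_22 <- function(metric) {
      d <- hitmiss[, c("subject_id", "condition", "outcome", metric)]
      names(d)[4] <- "value"
      counts <- table(d$subject_id[!is.na(d$value)])
      keep <- names(counts)[counts == 4]
      d[d$subject_id %in% keep & !is.na(d$value), ]
    }
    anova_rows <- function(metric, tag, ci_seed) {
      d <- complete_22(metric)
      res <- rm_anova_2x2(d, subject = "subject_id", a = "condition",
                          b = "outcome", value = "value")
      boot_pes <- function(which_contrast) {
        function(dat, idx) {
          ctr <- dat[idx]
          n <- length(ctr)
          se <- sd(ctr) / sqrt(n)
          f <- if (se == 0) 0 else (mean(ctr) / se)^2
          partial_eta_sq(f, 1, n - 1)
        }
      }
      ct <- within_contrasts(d, "subject_id", "condition", "outcome", "value")
      for (j in 1:3) {
        nm <- c("condition", "detection", "condition_x_detection")[j]
        contrast <- list(ct$A, ct$B, ct$AB)[[j]]
        add(paste0(tag, "_", nm),
            with_ci(res[j, ], contrast, boot_pes(j), 0.95, bootstrap_R,
                    ci_seed + j))
      }
    }
    anova_rows("mean_delta_bpm", "hr_anova_trial_aligned", seeds[9])
    anova_rows("mean_delta_bpm_stim", "hr_anova_stimulus_aligned", seeds[13])
    anova_rows("mean_sqrt_scr", "scr_anova", seeds[17])
  }

  # --- carryover: safe after threat vs safe after safe ---
  if (!is.null(carry) && nrow(carry) > 0) {
    wca <- tidyr::pivot_wider(carry, names_from = "prev_condition",
                              values_from = "mean_delta_bpm")
    ok <- !is.na(wca$threat) & !is.na(wca$safe)
    mca <- as.matrix(wca[ok, c("threat", "safe")])
    add("hr_carryover_safe_after_threat_vs_safe",
        with_ci(paired_t(mca[, 1], mca[, 2]), mca, boot_d, 0.95,
                bootstrap_R, seeds[21]))
  }

  # --- reaction times and their autonomic correlates ---
  w <- wide_cond("mean_rt_ms"); mrt <- as.matrix(w[, c("threat", "safe")])
  add("rt_threat_vs_safe",
      with_ci(wilcoxon_signed_rank(mrt[, 1], mrt[, 2]), mrt,
              boot_wilcoxon_r(), 0.95, bootstrap_R, seeds[22]))
  if (has_physio) {
    whr <- wide_cond("mean_delta_bpm")
    mhr <- as.matrix(whr[, c("threat", "safe")])
    d_rt <- mrt[, 1] - mrt[, 2]
    d_hr <- mhr[, 1] - mhr[, 2]
    add("rt_diff_vs_hr_diff",
        with_ci(spearman_correlation(d_rt, d_hr), cbind(d_rt, d_hr),
                boot_rho, 0.95, bootstrap_R, seeds[23]))
    mean_rt <- rowMeans(mrt); mean_hr <- rowMeans(mhr)
    add("mean_rt_vs_mean_hr",
        with_ci(spearman_correlation(mean_rt, mean_hr), cbind(mean_rt, mean_hr),
                boot_rho, 0.95, bootstrap_R, seeds[24]))
  }

  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "hypothesis")
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results>", length(unique(x$cells$subject_id)), "subjects |",
      nrow(x$hypotheses), "hypothesis rows\n")
  print(x$hypotheses[, c("hypothesis", "statistic_label", "statistic",
                         "p_value", "effect_label", "effect_size")], n = 50)
  invisible(x)
}

#' Write the results tables of a study
#'
#' `cells.csv`, `hypotheses.csv` and `manifest.json` (provenance) under
#' `dir`.
#'
#' @param results A `study_results`.
#' @param dir Output directory (created if needed).
#' @returns `dir`, invisibly.
#' @export
write_study_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(results$cells), file.path(dir, "cells.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(results$hypotheses), file.path(dir, "hypotheses.csv"),
            row.names = FALSE)
  jsonlite::write_json(results$provenance, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
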