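#' Fixture specification
#'
#' Named, seeded recipes for ready-made synthetic datasets with the
#' statistical structure the analysis chain assumes. Three effect profiles
#' are registered: `paper_default` (the study's group means: d' 1.66/1.55,
#' criterion 0.53/0.20 after rare/frequent blocks, heart-rate change
#' -4.38/-2.99 BPM, sqrt SCR 0.24/0.09, RT 632.4/616.5 ms, ~1.35%
#' non-responses), `null` (every condition and context effect zeroed, for
#' type-I calibration), and `exaggerated` (condition effects doubled).
#'
#' @param name Fixture name (unique per registry).
#' @param n_subjects Number of subjects.
#' @param profile One of `"paper_default"`, `"null"`, `"exaggerated"`.
#' @param seed Integer seed.
#' @returns A list of class `fixture_spec`.
#' @export
fixture_spec <- function(name = "paper_default_52",
                         n_subjects = 52,
                         profile = c("paper_default", "null", "exaggerated"),
                         seed = 1L) {
  profile <- match.arg(profile)
  structure(list(name = name, n_subjects = n_subjects, profile = profile,
                 seed = as.integer(seed)), class = "fixture_spec")
}

#' Population and physiology parameters of an effect profile
#'
#' @param profile Profile name (see [fixture_spec()]).
#' @param n_subjects Number of subjects.
#' @returns A list with `population` and `physio` parameter objects.
#' @export
profile_params <- function(profile, n_subjects = 52) {
  pop <- population_params(n_subjects = max(n_subjects, 2))
  fx <- physio_effect_params()
  if (profile == "null") {
    pop$dprime_delta_mean <- 0
    pop$criterion_shift_mean <- 0
    pop$criterion_shift_sd <- 0
    pop$rt_delta_mean <- 0
    pop$cor_dprime_shift <- 0
    mid_hr <- mean(c(fx$decel_threat_bpm, fx$decel_safe_bpm))
    pop$decel_threat_mean <- pop$decel_safe_mean <- mid_hr
    pop$decel_hit_extra_mean <- 0
    pop$decel_hit_extra_sd <- 0
    pop$decel_safe_sd <- pop$decel_threat_sd
    pop$cor_decel_threat_safe <- 1
    mid_scr <- mean(c(pop$scr_sqrt_threat_mean, pop$scr_sqrt_safe_mean))
    pop$scr_sqrt_threat_mean <- pop$scr_sqrt_safe_mean <- mid_scr
    pop$scr_sqrt_safe_sd <- pop$scr_sqrt_threat_sd
    pop$cor_scr_threat_safe <- 1
    fx$decel_threat_bpm <- fx$decel_safe_bpm <- mid_hr
    fx$decel_hit_extra_bpm <- 0
    fx$scr_sqrt_threat <- fx$scr_sqrt_safe <- mid_scr
    fx$scr_prob_threat <- fx$scr_prob_safe <-
      mean(c(fx$scr_prob_threat, fx$scr_prob_safe))
  } else if (profile == "exaggerated") {
    pop$dprime_delta_mean <- 2 * pop$dprime_delta_mean
    pop$criterion_shift_mean <- 2 * pop$criterion_shift_mean
    pop$rt_delta_mean <- 2 * pop$rt_delta_mean
    hr_gap <- pop$decel_threat_mean - pop$decel_safe_mean
    pop$decel_threat_mean <- pop$decel_safe_mean + 2 * hr_gap
    fx$decel_threat_bpm <- fx$decel_safe_bpm + 2 * hr_gap
  }
  list(population = pop, physio = fx)
}

#' Materialise a fixture dataset
#'
#' Simulates the dataset a spec describes: schedules, responses, and
#' (optionally) scored physiology for every subject. When `dir` is given the
#' dataset is also written to disk (trials+responses CSV, per-trial physio
#' CSV, manifest JSON with a content hash), so every analysis stage can be
#' exercised from files alone.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory.
#' @param include_physio Simulate the autonomic channels (slower).
#' @param titrate_contrast Run the per-subject staircase first.
#' @returns A list: `trials`, `results`, `physio` (or `NULL`), `observers`,
#'   `spec`, `manifest`.
#' @export
make_fixture <- function(spec = fixture_spec(), dir = NULL,
                         include_physio = TRUE, titrate_contrast = FALSE) {
  pp <- profile_params(spec$profile, spec$n_subjects)
  cfg <- study_config(n_subjects = spec$n_subjects,
                      population = pp$population, physio = pp$physio,
                      include_physio = include_physio,
                      titrate_contrast = titrate_contrast,
                      bootstrap_R = 0, seed = spec$seed)
  seeds <- derive_seeds(spec$seed, 2L)
  observers <- sample_population(cfg$population, seed = seeds[1])
  n <- nrow(observers)
  subj_seeds <- matrix(derive_seeds(seeds[2], 4L * n), nrow = n)

  trials_list <- results_list <- physio_list <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- observer_from_row(observers[i, ])
    if (titrate_contrast) {
      obs$contrast_ref <- calibrate_contrast(obs, seed = subj_seeds[i, 1])$contrast
    }
    sched <- build_session(cfg$design, subject_id = observers$subject_id[i],
                           seed = subj_seeds[i, 2])
    res <- simulate_responses(obs, sched$trials, seed = subj_seeds[i, 3])
    if (include_physio) {
      fx <- cfg$physio
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
  physio <- if (include_physio) dplyr::bind_rows(physio_list) else NULL

  manifest <- list(
    name = spec$name, profile = spec$profile, n_subjects = spec$n_subjects,
    seed = spec$seed, include_physio = include_physio,
    content_hash = rlang::hash(list(trials, results, physio))
  )
  out <- list(trials = trials, results = results, physio = physio,
              observers = observers, spec = spec, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    both <- dplyr::bind_cols(trials, results)
    write_schedule_csv(both, file.path(dir, "trials.csv"))
    if (!is.null(physio)) {
      write.csv(as.data.frame(physio), file.path(dir, "physio.csv"),
                row.names = FALSE)
    }
    manifest$files <- c("trials.csv", if (!is.null(physio)) "physio.csv")
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  out
}

#' Load a fixture dataset from disk
#'
#' @param dir Directory written by [make_fixture()].
#' @returns A list with `trials`, `results`, `physio` (or `NULL`),
#'   `manifest`.
#' @export
read_fixture <- function(dir) {
  both <- read_schedule_csv(file.path(dir, "trials.csv"))
  res_cols <- c("response", "rt_ms", "evidence")
  physio_path <- file.path(dir, "physio.csv")
  list(
    trials = both[, setdiff(names(both), res_cols)],
    results = both[, intersect(res_cols, names(both))],
    physio = if (file.exists(physio_path))
      tibble::as_tibble(read.csv(physio_path)) else NULL,
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}
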