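#' Design parameters for a session
#'
#' Collects the trial counts, rates and timing ranges that define one session
#' of the target-detection task: eight block pairs, each a 20-trial
#' target-frequency manipulation block (target presence 20% or 80%) followed
#' by a 38-trial experimental block (presence 50%). Of the 38 experimental
#' trials, 32 (16 threat, 16 safe) enter the analysis; the remaining 6 "extra"
#' trials (4 threat of which 3 shock-reinforced, 2 safe; 3 targets, 3 lures;
#' 4 with a shortened response window) are excluded from scoring.
#'
#' @param n_blocks Number of manipulation/experimental block pairs.
#' @param trials_per_manipulation Trials per manipulation block.
#' @param rate_rare,rate_frequent Target presence rates of the two
#'   manipulation contexts.
#' @param n_threat_core,n_safe_core Analysed threat/safe trials per
#'   experimental block (each split half target / half lure).
#' @param n_extra_threat,n_extra_safe Extra (non-analysed) trials per
#'   experimental block by condition.
#' @param n_extra_targets Number of targets among the extra trials (the rest
#'   are lures), chosen to keep the overall presence rate at 50%.
#' @param n_reinforced Shock-reinforced trials per experimental block; must
#'   not exceed `n_extra_threat`.
#' @param n_shortened Extra trials with a shortened response window.
#' @param fixation_range_ms Range of the threat/safe fixation-cue duration in
#'   experimental trials (uniform draw).
#' @param response_window_ms Standard response window.
#' @param shortened_response_range_ms Range of the shortened response window
#'   (uniform draw).
#' @param iti_range_ms Inter-trial interval range for experimental trials.
#' @param isi_post_mask_ms Delay between mask offset and response window in
#'   experimental trials.
#' @param manipulation_mask_contrast Backward-mask Michelson contrast used
#'   during manipulation blocks (low, so targets are clearly visible).
#' @param block_break_s Pause inserted between blocks on the session clock.
#' @returns A list of class `design_config`.
#' @export
design_config <- function(n_blocks = 8,
                          trials_per_manipulation = 20,
                          rate_rare = 0.20,
                          rate_frequent = 0.80,
                          n_threat_core = 16,
                          n_safe_core = 16,
                          n_extra_threat = 4,
                          n_extra_safe = 2,
                          n_extra_targets = 3,
                          n_reinforced = 3,
                          n_shortened = 4,
                          fixation_range_ms = c(1000, 3000),
                          response_window_ms = 1500,
                          shortened_response_range_ms = c(800, 3000),
                          iti_range_ms = c(2000, 4000),
                          isi_post_mask_ms = 4000,
                          manipulation_mask_contrast = 0.05,
                          block_break_s = 20) {
  assert_prob(c(rate_rare, rate_frequent), "target presence rates")
  if (n_threat_core %% 2L != 0L || n_safe_core %% 2L != 0L) {
    stop_config("core threat/safe trial counts must be even (half targets, half lures)")
  }
  if (n_threat_core != n_safe_core) {
    stop_config("threat/safe core split must be even: got ",
                n_threat_core, " vs ", n_safe_core)
  }
  n_extra <- n_extra_threat + n_extra_safe
  if (n_reinforced > n_extra_threat) {
    stop_config("reinforcement count (", n_reinforced,
                ") exceeds threat extra-trial capacity (", n_extra_threat, ")")
  }
  if (n_extra_targets > n_extra || n_shortened > n_extra) {
    stop_config("extra-trial composition exceeds the number of extra trials")
  }
  structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_manipulation = as.integer(trials_per_manipulation),
    rate_rare = rate_rare,
    rate_frequent = rate_frequent,
    n_threat_core = as.integer(n_threat_core),
    n_safe_core = as.integer(n_safe_core),
    n_extra_threat = as.integer(n_extra_threat),
    n_extra_safe = as.integer(n_extra_safe),
    n_extra_targets = as.integer(n_extra_targets),
    n_reinforced = as.integer(n_reinforced),
    n_shortened = as.integer(n_shortened),
    fixation_range_ms = fixation_range_ms,
    response_window_ms = response_window_ms,
    shortened_response_range_ms = shortened_response_range_ms,
    iti_range_ms = iti_range_ms,
    isi_post_mask_ms = isi_post_mask_ms,
    manipulation_mask_contrast = manipulation_mask_contrast,
    block_break_s = block_break_s
  ), class = "design_config")
}

# Fixed stimulus timing shared by every trial (ms): target/lure frame, gap,
# backward mask. One 60-Hz frame is 16.7 ms.
STIM_MS <- 16.7
ISI1_MS <- 16.7
MASK_MS <- 100

#' Build one experimental block
#'
#' Draws the 38-trial experimental block: 32 analysed trials (16 threat,
#' 16 safe, each half targets) plus 6 extra trials carrying the shock
#' reinforcements and shortened response windows. Which extra trials are
#' targets, reinforced, or shortened is randomised subject to the stated
#' composition; trial order is fully randomised. Consumes the current RNG
#' stream.
#'
#' @param config A [design_config()].
#' @param prior_context `"rare"` or `"frequent"`: the target-frequency context
#'   of the manipulation block this experimental block follows.
#' @param block_index Integer block label.
#' @returns A `tbl_df` with one row per trial (see [build_session()] for
#'   columns).
#' @export
build_experimental_block <- function(config = design_config(),
                                     prior_context = "rare",
                                     block_index = 1L) {
  n_core <- config$n_threat_core + config$n_safe_core
  n_extra <- config$n_extra_threat + config$n_extra_safe
  n <- n_core + n_extra

  condition <- c(rep("threat", config$n_threat_core),
                 rep("safe", config$n_safe_core),
                 rep("threat", config$n_extra_threat),
                 rep("safe", config$n_extra_safe))
  stimulus <- c(rep(c("target", "lure"), each = config$n_threat_core / 2L),
                rep(c("target", "lure"), each = config$n_safe_core / 2L),
                rep("lure", n_extra))
  extra <- c(rep(FALSE, n_core), rep(TRUE, n_extra))
  reinforced <- rep(FALSE, n)
  shortened <- rep(FALSE, n)

  if (n_extra > 0L) {
    extra_idx <- n_core + seq_len(n_extra)
    stimulus[sample(extra_idx, config$n_extra_targets)] <- "target"
    threat_extras <- extra_idx[condition[extra_idx] == "threat"]
    reinforced[sample(threat_extras, config$n_reinforced)] <- TRUE
    shortened[sample(extra_idx, config$n_shortened)] <- TRUE
  }

  ord <- sample.int(n)
  condition <- condition[ord]; stimulus <- stimulus[ord]
  extra <- extra[ord]; reinforced <- reinforced[ord]; shortened <- shortened[ord]

  fixation <- runif(n, config$fixation_range_ms[1], config$fixation_range_ms[2])
  response <- ifelse(shortened,
                     runif(n, config$shortened_response_range_ms[1],
                           config$shortened_response_range_ms[2]),
                     config$response_window_ms)
  iti <- runif(n, config$iti_range_ms[1], config$iti_range_ms[2])
  orientation <- ifelse(stimulus == "target",
                        sample(c("vertical", "horizontal"), n, replace = TRUE),
                        "none")

  quick_df(list(
    block_index = rep(as.integer(block_index), n),
    phase = rep("experimental", n),
    prior_context = rep(prior_context, n),
    condition = condition,
    stimulus = stimulus,
    target_orientation = orientation,
    fixation_duration_ms = fixation,
    stimulus_onset_ms = fixation,
    isi_post_mask_ms = rep(config$isi_post_mask_ms, n),
    response_window_ms = response,
    iti_ms = iti,
    mask_contrast = rep(NA_real_, n),
    reinforced = reinforced,
    extra_trial = extra,
    shortened_response = shortened,
    included_in_analysis = !extra & !reinforced & !shortened
  ))
}

# Manipulation blocks induce the criterion shift: 20 clearly visible trials
# with target presence 20% (rare) or 80% (frequent), black fixation, no shock
# possible. They are never scored for d'/criterion.
build_manipulation_block <- function(config = design_config(),
                                     kind = c("rare", "frequent"),
                                     block_index = 1L) {
  kind <- match.arg(kind)
  n <- config$trials_per_manipulation
  rate <- if (kind == "rare") config$rate_rare else config$rate_frequent
  n_targets <- as.integer(round(rate * n))
  stimulus <- rep("lure", n)
  stimulus[sample.int(n, n_targets)] <- "target"
  orientation <- ifelse(stimulus == "target",
                        sample(c("vertical", "horizontal"), n, replace = TRUE),
                        "none")
  quick_df(list(
    block_index = rep(as.integer(block_index), n),
    phase = rep("manipulation", n),
    prior_context = rep(kind, n),
    condition = rep("neutral", n),
    stimulus = stimulus,
    target_orientation = orientation,
    fixation_duration_ms = rep(500, n),
    stimulus_onset_ms = rep(500, n),
    isi_post_mask_ms = rep(800, n),
    response_window_ms = rep(config$response_window_ms, n),
    iti_ms = rep(2000, n),
    mask_contrast = rep(config$manipulation_mask_contrast, n),
    reinforced = rep(FALSE, n),
    extra_trial = rep(FALSE, n),
    shortened_response = rep(FALSE, n),
    included_in_analysis = rep(FALSE, n)
  ))
}

#' Analysis-inclusion flags of an experimental block
#'
#' A trial enters the analysis iff it is not an extra trial, not
#' shock-reinforced, and does not have a shortened response window.
#'
#' @param block A tibble of experimental-phase trials.
#' @returns Logical vector, one flag per trial.
#' @export
inclusion_flags <- function(block) {
  if (!all(block$phase == "experimental")) {
    stop_contract("inclusion_flags() applies to experimental blocks only")
  }
  !block$extra_trial & !block$reinforced & !block$shortened_response
}

#' Generate a full session schedule
#'
#' Builds the complete session: `n_blocks` pairs of a manipulation block
#' followed by an experimental block. Half the manipulation blocks are rare
#' (20% targets) and half frequent (80%), in an order counterbalanced by
#' subject parity (alternating, starting with rare for odd subject ids)
#' unless overridden. The threat-cue colour assignment is likewise
#' counterbalanced by parity. Deterministic given `seed`.
#'
#' @param config A [design_config()].
#' @param subject_id Integer subject identifier (drives counterbalancing).
#' @param seed Integer seed; the schedule is bit-reproducible given the seed.
#' @param manipulation_order Optional character vector of `"rare"`/`"frequent"`
#'   labels overriding the parity rule.
#' @param colour_assignment Optional override, `"orange_threat"` or
#'   `"blue_threat"`.
#' @returns A list of class `session_schedule` with elements `subject_id`,
#'   `colour_assignment`, `manipulation_order`, `trials` (tibble, one row per
#'   trial with absolute onset times on the session clock), `seed`, `config`.
#' @export
build_session <- function(config = design_config(),
                          subject_id = 1L,
                          seed = 1L,
                          manipulation_order = NULL,
                          colour_assignment = NULL) {
  if (is.null(manipulation_order)) {
    base <- if (subject_id %% 2L == 1L) c("rare", "frequent") else c("frequent", "rare")
    manipulation_order <- rep(base, length.out = config$n_blocks)
  }
  if (length(manipulation_order) != config$n_blocks ||
      !all(manipulation_order %in% c("rare", "frequent"))) {
    stop_config("manipulation_order must give one rare/frequent label per block")
  }
  if (is.null(colour_assignment)) {
    colour_assignment <- if (subject_id %% 2L == 1L) "orange_threat" else "blue_threat"
  }

  trials <- local_seed(seed, {
    blocks <- vector("list", 2L * config$n_blocks)
    for (b in seq_len(config$n_blocks)) {
      blocks[[2L * b - 1L]] <-
        build_manipulation_block(config, manipulation_order[b], b)
      blocks[[2L * b]] <-
        build_experimental_block(config, manipulation_order[b], b)
    }
    do.call(rbind, blocks)
  })

  trials$subject_id <- subject_id
  trials$trial_index <- seq_len(nrow(trials))
  dur_ms <- trials$fixation_duration_ms + STIM_MS + ISI1_MS + MASK_MS +
    trials$isi_post_mask_ms + trials$response_window_ms + trials$iti_ms
  trials$trial_duration_ms <- dur_ms
  # Session clock: trials run back to back within a block; blocks are
  # separated by a fixed break.
  new_block <- c(TRUE, diff(trials$block_index) != 0 |
                   trials$phase[-1] != trials$phase[-nrow(trials)])
  offset <- cumsum(ifelse(new_block, config$block_break_s, 0))
  trials$trial_onset_s <- offset + cumsum(c(0, dur_ms[-length(dur_ms)] / 1000))
  trials$stimulus_onset_s <- trials$trial_onset_s + trials$stimulus_onset_ms / 1000

  structure(list(
    subject_id = subject_id,
    colour_assignment = colour_assignment,
    manipulation_order = manipulation_order,
    trials = tibble::as_tibble(trials),
    seed = seed,
    config = config
  ), class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("<session_schedule> subject", x$subject_id,
      "|", length(x$manipulation_order), "block pairs",
      "|", nrow(x$trials), "trials",
      "|", x$colour_assignment, "\n")
  invisible(x)
}

#' Write / read a schedule as a flat CSV
#'
#' One row per trial, header row, times in ms (onsets on the session clock in
#' seconds), logical flags as 0/1.
#'
#' @param schedule A `session_schedule` (or its `trials` tibble).
#' @param path Output file.
#' @returns `path`, invisibly; `read_schedule_csv()` returns the trials tibble.
#' @export
write_schedule_csv <- function(schedule, path) {
  trials <- if (inherits(schedule, "session_schedule")) schedule$trials else schedule
  out <- as.data.frame(trials)
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("reinforced", "extra_trial", "shortened_response",
                "included_in_analysis")) {
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  }
  tibble::as_tibble(out)
}
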