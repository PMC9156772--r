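# Shared helpers: small deterministic objects and independent oracles.

tiny_design <- function(n_blocks = 2, ...) design_config(n_blocks = n_blocks, ...)

# An observer with no lapses or non-responses, for clean SDT arithmetic.
clean_observer <- function(...) {
  observer_params(lapse_rate = 0, nonresponse_rate = 0, ...)
}

# Yes/no accuracy of the equal-variance observer at mask contrast m
# (closed form; independent of the simulation path).
observer_accuracy_at <- function(observer, m) {
  d <- dprime_at_contrast(observer, m)
  c0 <- observer$criterion_base
  acc <- 0.5 * pnorm(d / 2 - c0) + 0.5 * pnorm(d / 2 + c0)
  (1 - observer$lapse_rate) * acc + observer$lapse_rate * 0.5
}

# Brute-force exact signed-rank tail probabilities by enumerating all 2^n
# sign assignments of the ranks (oracle for the Wilcoxon implementation).
enumerate_signed_rank <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  list(
    p_greater = mean(w_all >= w_obs),
    p_less = mean(w_all <= w_obs),
    p_two = min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
  )
}

# A flat synthetic BPM trace with a programmed deceleration kernel of known
# windowed score, for scoring oracles.
flat_bpm_trace <- function(value = 70, dur_s = 60, rate = 50) {
  physio_trace("bpm", rate, rep(value, dur_s * rate))
}

# Inject a canonical SCR into a flat EDA trace at a known onset.
eda_with_scr <- function(onset_s, amplitude_us, rise_s = 1.5, decay_s = 3,
                         dur_s = 40, rate = 50, tonic = 5) {
  tt <- (seq_len(dur_s * rate) - 1) / rate
  physio_trace("eda", rate,
               tonic + scr_kernel(tt - onset_s, amplitude_us, rise_s, decay_s))
}

# Small hand-built multi-subject behavioural dataset with known outcome
# counts per cell: each subject x condition x context cell has `n_sig`
# targets and `n_noise` lures with fixed numbers of hits and false alarms.
hand_dataset <- function(counts) {
  # counts: tibble with subject_id, condition, prior_context, n_sig, n_hit,
  # n_noise, n_fa
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    ct <- counts[i, ]
    stim <- c(rep("target", ct$n_sig), rep("lure", ct$n_noise))
    resp <- c(rep("present", ct$n_hit), rep("absent", ct$n_sig - ct$n_hit),
              rep("present", ct$n_fa), rep("absent", ct$n_noise - ct$n_fa))
    rows[[i]] <- tibble::tibble(
      subject_id = ct$subject_id, condition = ct$condition,
      prior_context = ct$prior_context, stimulus = stim, response = resp)
  }
  d <- dplyr::bind_rows(rows)
  n <- nrow(d)
  trials <- tibble::tibble(
    subject_id = d$subject_id, block_index = 1L, phase = "experimental",
    prior_context = d$prior_context, condition = d$condition,
    stimulus = d$stimulus, included_in_analysis = TRUE,
    reinforced = FALSE, extra_trial = FALSE, shortened_response = FALSE)
  trials$trial_index <- stats::ave(seq_len(n), trials$subject_id,
                                   FUN = seq_along)
  results <- tibble::tibble(response = d$response, rt_ms = 700,
                            evidence = 0)
  list(trials = trials, results = results)
}
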