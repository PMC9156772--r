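#' A standard result row for every hypothesis test
#'
#' All inferential functions in the package return one-row (or per-effect)
#' tibbles with this layout, so whole analysis batteries stack into a single
#' results table.
#'
#' @param test Test name.
#' @param statistic_label One of `"Z"`, `"t"`, `"F"`, `"rho"`, `"W"`.
#' @param statistic Test statistic.
#' @param df1,df2 Degrees of freedom (NA where not applicable).
#' @param p_value P value.
#' @param tails `"one"` or `"two"`.
#' @param effect_label `"r"`, `"d"`, `"partial_eta_sq"`, or `"rho"`.
#' @param effect_size Effect-size estimate.
#' @param ci_low,ci_high,ci_level Bootstrap CI of the effect size.
#' @param n Number of subjects.
#' @param note Free-text qualifier (e.g. degenerate-data markers).
#' @returns A one-row tibble.
#' @keywords internal
test_result <- function(test, statistic_label, statistic, df1 = NA_real_,
                        df2 = NA_real_, p_value = NA_real_, tails = "two",
                        effect_label = NA_character_, effect_size = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        ci_level = NA_real_, n = NA_integer_, note = "") {
  tibble::tibble(test = test, statistic_label = statistic_label,
                 statistic = statistic, df1 = df1, df2 = df2,
                 p_value = p_value, tails = tails,
                 effect_label = effect_label, effect_size = effect_size,
                 ci_low = ci_low, ci_high = ci_high, ci_level = ci_level,
                 n = as.integer(n), note = note)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (classic Wilcoxon zero policy). For n <= 12
#' non-zero untied differences the exact signed-rank distribution is used;
#' otherwise the normal approximation with tie correction and continuity
#' correction. The reported statistic is the approximate Z in either case,
#' and the attached effect size is `r = |Z| / sqrt(n)` with n the number of
#' pairs.
#'
#' @param x,y Paired numeric vectors (length >= 5).
#' @param alternative `"two.sided"`, `"greater"` (x tends above y), or
#'   `"less"`.
#' @returns A [test_result()] row (statistic_label `"Z"`).
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop_config("need at least 5 pairs")
  n_pairs <- length(x)
  d <- x - y
  d <- d[d != 0 & !is.na(d)]
  n <- length(d)
  tails <- if (alternative == "two.sided") "two" else "one"
  if (n == 0) {
    return(test_result("wilcoxon_signed_rank", "Z", 0, p_value = 1,
                       tails = tails, effect_label = "r", effect_size = 0,
                       n = n_pairs, note = "degenerate: all differences zero"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- if (W == mu || sigma2 == 0) 0 else
    (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)

  ties <- any(tie_tab > 1)
  if (n <= 12 && !ties) {
    p_geq <- psignrank(W - 1, n, lower.tail = FALSE)
    p_leq <- psignrank(W, n)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_geq, p_leq)),
                greater = p_geq,
                less = p_leq)
  } else {
    p <- switch(alternative,
                two.sided = 2 * pnorm(-abs(z)),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
  }
  test_result("wilcoxon_signed_rank", "Z", z, p_value = p, tails = tails,
              effect_label = "r", effect_size = effect_r_from_z(z, n_pairs),
              n = n_pairs)
}

#' Paired t test with Cohen's d
#'
#' Classical paired t (df = n - 1) via [stats::t.test()], with the
#' paired-design effect size `d = t / sqrt(n)` attached (the mean difference
#' in units of the SD of differences).
#'
#' @inheritParams wilcoxon_signed_rank
#' @returns A [test_result()] row (statistic_label `"t"`).
#' @export
paired_t <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop_config("need at least 3 pairs")
  if (var(x - y, na.rm = TRUE) == 0) {
    stop_config("zero variance of differences")
  }
  tt <- t.test(x, y, paired = TRUE, alternative = alternative)
  n <- sum(!is.na(x - y))
  test_result("paired_t", "t", unname(tt$statistic), df1 = unname(tt$parameter),
              p_value = tt$p.value,
              tails = if (alternative == "two.sided") "two" else "one",
              effect_label = "d",
              effect_size = cohen_d_from_t(unname(tt$statistic), n), n = n)
}

# Per-subject contrast values for a balanced 2x2 within-subject design.
# data: long tibble with columns subject, A, B, value (names passed in).
within_contrasts <- function(data, subject, a, b, value) {
  d <- data.frame(s = data[[subject]], a = data[[a]], b = data[[b]],
                  y = data[[value]])
  if (any(is.na(d$y))) stop_config("missing cell values")
  la <- sort(unique(d$a)); lb <- sort(unique(d$b))
  if (length(la) != 2 || length(lb) != 2) {
    stop_config("both factors must have exactly 2 levels")
  }
  cell <- aggregate(y ~ s + a + b, d, mean)
  wide <- tidyr::pivot_wider(tibble::as_tibble(cell),
                             names_from = c("a", "b"), values_from = "y")
  m <- as.matrix(wide[, -1])
  if (ncol(m) != 4 || any(is.na(m))) {
    stop_config("incomplete 2x2 cells; drop or impute subjects first")
  }
  # column order from pivot: a1_b1, a1_b2, a2_b1, a2_b2
  cols <- paste(rep(la, each = 2), rep(lb, 2), sep = "_")
  m <- m[, cols, drop = FALSE]
  list(
    subjects = wide[[1]],
    A = (m[, 3] + m[, 4] - m[, 1] - m[, 2]) / 2,
    B = (m[, 2] + m[, 4] - m[, 1] - m[, 3]) / 2,
    AB = (m[, 1] - m[, 2] - m[, 3] + m[, 4]) / 2,
    levels = list(a = la, b = lb)
  )
}

#' 2 x 2 repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA for a balanced 2 x 2 design.
#' Because every effect has one numerator degree of freedom, each F(1, n-1)
#' equals the square of the paired t on the corresponding within-subject
#' contrast; partial eta squared `F / (F + df2)` is attached. Subjects with
#' replicated cells are first reduced to cell means; missing cells are an
#' error.
#'
#' @param data Long-format data.
#' @param subject,a,b,value Column names of the subject identifier, the two
#'   factors, and the response.
#' @returns A tibble with one [test_result()] row per effect (`A`, `B`,
#'   `A:B`, labelled with the factor names).
#' @export
rm_anova_2x2 <- function(data, subject = "subject_id", a = "A", b = "B",
                         value = "value") {
  ct <- within_contrasts(data, subject, a, b, value)
  n <- length(ct$subjects)
  one <- function(contrast, name) {
    mu <- mean(contrast)
    se <- sd(contrast) / sqrt(n)
    f <- if (se == 0) 0 else (mu / se)^2
    test_result(paste0("rm_anova[", name, "]"), "F", f, df1 = 1, df2 = n - 1,
                p_value = pf(f, 1, n - 1, lower.tail = FALSE),
                effect_label = "partial_eta_sq",
                effect_size = partial_eta_sq(f, 1, n - 1), n = n)
  }
  dplyr::bind_rows(
    one(ct$A, a), one(ct$B, b),
    one(ct$AB, paste0(a, ":", b)))
}

#' Aligned-rank-transform (ART) 2 x 2 repeated-measures ANOVA
#'
#' Nonparametric factorial ANOVA: for each effect, responses are aligned by
#' removing the estimated cell effects of every other effect (cell-mean
#' estimates; design is balanced), the aligned values are ranked across the
#' whole sample (mid-ranks), and [rm_anova_2x2()] runs on the ranks; only
#' the effect the data were aligned for is interpreted.
#'
#' @inheritParams rm_anova_2x2
#' @returns A tibble with one row per effect, computed from its own
#'   alignment.
#' @export
art_anova_2x2 <- function(data, subject = "subject_id", a = "A", b = "B",
                          value = "value") {
  d <- data.frame(s = data[[subject]], a = data[[a]], b = data[[b]],
                  y = data[[value]], stringsAsFactors = FALSE)
  if (any(is.na(d$y))) stop_config("missing cell values")
  grand <- mean(d$y)
  m_a <- tapply(d$y, d$a, mean)
  m_b <- tapply(d$y, d$b, mean)
  m_ab <- tapply(d$y, list(d$a, d$b), mean)
  cell <- m_ab[cbind(d$a, d$b)]
  eff_a <- m_a[d$a] - grand
  eff_b <- m_b[d$b] - grand
  eff_ab <- cell - m_a[d$a] - m_b[d$b] + grand
  resid <- d$y - cell

  run_one <- function(aligned, which_row, name) {
    d2 <- d
    d2$y <- rank(aligned)
    res <- rm_anova_2x2(d2, subject = "s", a = "a", b = "b", value = "y")
    row <- res[which_row, ]
    row$test <- paste0("art_anova[", name, "]")
    row
  }
  dplyr::bind_rows(
    run_one(resid + eff_a, 1, a),
    run_one(resid + eff_b, 2, b),
    run_one(resid + eff_ab, 3, paste0(a, ":", b)))
}

#' @rdname art_anova_2x2
#' @param effect Which aligned set to return (`"A"`, `"B"`, `"AB"`), for
#'   inspecting the alignment itself.
#' @returns `art_aligned()`: the aligned (pre-rank) responses.
#' @export
art_aligned <- function(data, subject = "subject_id", a = "A", b = "B",
                        value = "value", effect = c("A", "B", "AB")) {
  effect <- match.arg(effect)
  d <- data.frame(a = data[[a]], b = data[[b]], y = data[[value]])
  grand <- mean(d$y)
  m_a <- tapply(d$y, d$a, mean)
  m_b <- tapply(d$y, d$b, mean)
  m_ab <- tapply(d$y, list(d$a, d$b), mean)
  cell <- m_ab[cbind(d$a, d$b)]
  resid <- d$y - cell
  switch(effect,
         A = resid + m_a[d$a] - grand,
         B = resid + m_b[d$b] - grand,
         AB = resid + cell - m_a[d$a] - m_b[d$b] + grand)
}

#' Spearman rank-order correlation
#'
#' Mid-rank Spearman correlation, reported as rho with df = n - 2 and a
#' t-approximation p value.
#'
#' @param x,y Numeric vectors (length >= 4 after NA removal).
#' @param alternative As in [wilcoxon_signed_rank()].
#' @returns A [test_result()] row (statistic_label `"rho"`).
#' @export
spearman_correlation <- function(x, y, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop_config("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(test_result("spearman", "rho", NA_real_, df1 = n - 2,
                       effect_label = "rho", n = n,
                       note = "degenerate: constant input"))
  }
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p2 <- 2 * pt(-abs(tstat), df = n - 2)
  p <- switch(alternative,
              two.sided = p2,
              greater = pt(tstat, df = n - 2, lower.tail = FALSE),
              less = pt(tstat, df = n - 2))
  test_result("spearman", "rho", rho, df1 = n - 2, p_value = p,
              tails = if (alternative == "two.sided") "two" else "one",
              effect_label = "rho", effect_size = rho, n = n)
}

#' Effect sizes from reported statistics
#'
#' Conversions used throughout the analyses: rank-test effect size
#' `r = |Z| / sqrt(n)`, paired-design Cohen's `d = t / sqrt(n)`, and partial
#' eta squared `F df1 / (F df1 + df2)`.
#'
#' @param z,t,F Test statistics.
#' @param n Number of subjects.
#' @param df1,df2 ANOVA degrees of freedom.
#' @returns Numeric effect size.
#' @export
effect_r_from_z <- function(z, n) {
  if (any(n < 1)) stop_config("n must be at least 1")
  abs(z) / sqrt(n)
}

#' @rdname effect_r_from_z
#' @export
cohen_d_from_t <- function(t, n) {
  if (any(n < 2)) stop_config("n must be at least 2")
  t / sqrt(n)
}

#' @rdname effect_r_from_z
#' @export
partial_eta_sq <- function(F, df1, df2) {
  if (any(F < 0) || any(df1 < 1) || any(df2 < 1)) {
    stop_config("F must be non-negative and dfs at least 1")
  }
  (F * df1) / (F * df1 + df2)
}

#' Percentile bootstrap confidence interval over subjects
#'
#' Resamples subjects (rows) with replacement, recomputes the statistic per
#' resample, and returns the percentile interval. Deterministic given
#' `seed`.
#'
#' @param data A vector, matrix or data frame; rows are subjects.
#' @param statistic Function `(data, idx) -> scalar`, as in [boot::boot()].
#' @param level Confidence level (0.90 for the one-tailed analyses, 0.95
#'   otherwise).
#' @param R Number of resamples.
#' @param seed Optional integer seed.
#' @returns Numeric `c(low, high)` with attributes `level` and `R`. A
#'   degenerate statistic yields a zero-width interval with a warning.
#' @export
bootstrap_ci <- function(data, statistic, level = 0.95, R = 2000,
                         seed = NULL) {
  if (level <= 0 || level >= 1) stop_config("level must lie in (0, 1)")
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 5) stop_config("need at least 5 subjects to bootstrap")
  bt <- local_seed(seed, boot::boot(data, statistic, R = R))
  reps <- bt$t[is.finite(bt$t)]
  if (length(reps) == 0 || diff(range(reps)) == 0) {
    warning("degenerate bootstrap distribution; zero-width interval")
    val <- if (length(reps)) reps[1] else unname(bt$t0)
    out <- c(val, val)
  } else {
    alpha <- (1 - level) / 2
    out <- unname(quantile(reps, c(alpha, 1 - alpha)))
  }
  attr(out, "level") <- level
  attr(out, "R") <- R
  out
}
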