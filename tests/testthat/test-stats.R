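test_that("Wilcoxon signed-rank matches exact enumeration and the stats oracle", {
  # exact path vs brute-force enumeration of all 2^n sign assignments
  set.seed(3)
  for (rep in 1:4) {
    d <- round(rnorm(8, 0.3, 1), 3)
    d <- d + (d == 0) * 0.001
    while (any(duplicated(abs(d)))) d <- d + rnorm(8, 0, 1e-4)
    x <- d; y <- rep(0, 8)
    oracle <- enumerate_signed_rank(d)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, oracle$p_two)
    expect_equal(wilcoxon_signed_rank(x, y, "greater")$p_value,
                 oracle$p_greater)
    expect_equal(wilcoxon_signed_rank(x, y, "less")$p_value, oracle$p_less)
  }

  # large-sample normal approximation agrees with stats::wilcox.test
  set.seed(4)
  x <- rnorm(40, 0.2); y <- rnorm(40)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)

  # effect size and degenerate handling
  expect_equal(ours$effect_size, abs(ours$statistic) / sqrt(40))
  same <- wilcoxon_signed_rank(1:10, 1:10)
  expect_equal(same$statistic, 0)
  expect_match(same$note, "degenerate")

  # shift invariance
  shifted <- wilcoxon_signed_rank(x + 5, y + 5)
  expect_equal(ours$statistic, shifted$statistic)
})

test_that("paired t matches a hand computation and carries d = t / sqrt(n)", {
  x <- c(5.1, 4.8, 6.0, 5.6, 5.2)
  y <- c(4.9, 4.4, 5.8, 5.7, 4.6)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  res <- paired_t(x, y)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df1, 4)
  expect_equal(res$effect_size, t_hand / sqrt(5))
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  one <- paired_t(x, y, alternative = "greater")
  expect_equal(one$p_value, pt(t_hand, 4, lower.tail = FALSE))
  expect_equal(one$tails, "one")
  expect_error(paired_t(x, x + 1), class = "threatsdt_config_error")
})

test_that("the 2x2 repeated-measures ANOVA matches its algebraic identities and aov", {
  set.seed(11)
  n <- 16
  long <- expand.grid(subject_id = 1:n, A = c("a1", "a2"), B = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  long$value <- rnorm(nrow(long)) + 0.5 * (long$A == "a2") +
    rnorm(n)[long$subject_id]

  res <- rm_anova_2x2(long, a = "A", b = "B", value = "value")

  # F(1, n-1) for a two-level factor equals the squared paired t on margins
  wide <- tidyr::pivot_wider(tibble::as_tibble(long),
                             names_from = c("A", "B"), values_from = "value")
  mA1 <- (wide$a1_b1 + wide$a1_b2) / 2
  mA2 <- (wide$a2_b1 + wide$a2_b2) / 2
  t_marg <- paired_t(mA2, mA1)$statistic
  expect_equal(res$statistic[1], t_marg^2, tolerance = 1e-8)

  # oracle: full within-subject aov decomposition
  long$s <- factor(long$subject_id)
  fit <- summary(aov(value ~ A * B + Error(s / (A * B)), data = long))
  f_aov <- c(fit[["Error: s:A"]][[1]]["A", "F value"],
             fit[["Error: s:B"]][[1]]["B", "F value"],
             fit[["Error: s:A:B"]][[1]]["A:B", "F value"])
  expect_equal(res$statistic, f_aov, tolerance = 1e-8)
  expect_equal(res$effect_size, res$statistic / (res$statistic + (n - 1)),
               tolerance = 1e-12)

  # purely additive data: interaction F vanishes
  add <- long
  add$value <- (add$A == "a2") * 2 + (add$B == "b2") * 1 +
    rnorm(n)[add$subject_id]
  res_add <- rm_anova_2x2(add, a = "A", b = "B", value = "value")
  expect_lt(res_add$statistic[3], 1e-20)

  # missing cells are an error
  expect_error(rm_anova_2x2(long[-1, ], a = "A", b = "B", value = "value"),
               class = "threatsdt_config_error")
})

test_that("ART alignment zeroes nuisance effects and survives monotone transforms", {
  set.seed(12)
  n <- 20
  long <- expand.grid(subject_id = 1:n, A = c("a1", "a2"), B = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  long$value <- rnorm(nrow(long)) + 1.0 * (long$A == "a2") +
    0.6 * (long$B == "b2")

  # aligned responses for effect A sum to zero within each level of B
  alA <- art_aligned(long, a = "A", b = "B", value = "value", effect = "A")
  for (b in c("b1", "b2")) {
    expect_equal(sum(alA[long$B == b]), 0, tolerance = 1e-9)
  }

  res <- art_anova_2x2(long, a = "A", b = "B", value = "value")
  expect_equal(nrow(res), 3)

  # a monotone transform of the response leaves the main-effect decisions
  # (the interaction alignment uses cell means and is only approximately
  # transform-invariant, as in the published procedure)
  long2 <- long
  long2$value <- exp(long$value)
  res2 <- art_anova_2x2(long2, a = "A", b = "B", value = "value")
  alpha <- 0.05
  expect_equal(res$p_value[1:2] < alpha, res2$p_value[1:2] < alpha)
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_correlation(x, x^3)$statistic, 1)
  expect_equal(spearman_correlation(x, -x^3)$statistic, -1)

  # ties: matches Pearson on mid-ranks (oracle) and cor.test's estimate
  xt <- c(1, 2, 2, 3, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 4)
  ours <- spearman_correlation(xt, yt)
  expect_equal(ours$statistic, cor(rank(xt), rank(yt)))
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman"))
  expect_equal(ours$statistic, unname(ref$estimate))
  expect_equal(ours$df1, 5)

  const <- spearman_correlation(rep(1, 6), x)
  expect_match(const$note, "degenerate")
})

test_that("effect-size conversions are exact at zero and self-consistent", {
  expect_equal(effect_r_from_z(0, 52), 0)
  expect_equal(cohen_d_from_t(0, 52), 0)
  expect_equal(partial_eta_sq(0, 1, 51), 0)
  # self-consistency: partial eta^2 equals t^2/(t^2+df) for F = t^2
  t <- 2.5; n <- 30
  expect_equal(partial_eta_sq(t^2, 1, n - 1), t^2 / (t^2 + n - 1))
  expect_error(partial_eta_sq(-1, 1, 51), class = "threatsdt_config_error")
})

test_that("the bootstrap is deterministic, degenerate-safe, and covers", {
  x <- rnorm(30, 0.5)
  stat <- function(d, i) mean(d[i]) / sd(d[i])
  a <- bootstrap_ci(x, stat, level = 0.95, R = 500, seed = 2)
  b <- bootstrap_ci(x, stat, level = 0.95, R = 500, seed = 2)
  expect_identical(a, b)
  expect_true(a[1] < a[2])

  expect_warning(ci0 <- bootstrap_ci(rep(1, 10), function(d, i) mean(d[i]),
                                     R = 100, seed = 1),
                 "degenerate")
  expect_equal(ci0[1], ci0[2])

  # nominal coverage for a one-sample standardized mean (reduced-scale check)
  set.seed(99)
  true_d <- 0.5
  hits <- 0
  n_rep <- 200
  for (k in seq_len(n_rep)) {
    z <- rnorm(30, true_d, 1)
    ci <- bootstrap_ci(z, stat, level = 0.95, R = 400, seed = k)
    hits <- hits + (ci[1] <= true_d && true_d <= ci[2])
  }
  expect_gt(hits / n_rep, 0.87)
  expect_lt(hits / n_rep, 0.99)
})
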