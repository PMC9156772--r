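Package: threatsdt
Title: Simulation and Signal-Detection Analysis of Visual Target Detection Under Threat of Shock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a within-subject visual target-detection
    experiment in which a coloured fixation cue signals threat of electrical
    stimulation and a preceding block manipulates the prior target frequency.
    Provides a session-schedule generator, an equal-variance signal-detection
    observer with condition-dependent sensitivity and criterion, a 3-down-1-up
    adaptive staircase for mask-contrast titration, generators and scorers for
    event-locked heart-rate deceleration and skin-conductance responses, and
    the study's inferential battery (Wilcoxon signed-rank, paired t,
    repeated-measures and aligned-rank-transform ANOVA, Spearman correlations,
    effect sizes with bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
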