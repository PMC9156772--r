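---
title: "Simulating and analysing target detection under threat of shock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing target detection under threat of shock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threatsdt)
```

## The experiment this package models

`threatsdt` simulates and analyses a within-subject visual detection
experiment in which two manipulations are crossed. First, on every trial of
an experimental block a coloured fixation cue signals whether an electrical
shock may occur (threat) or not (safe); a small fraction of threat trials is
actually reinforced. Second, each experimental block is preceded by a
*target-frequency manipulation block* in which targets appear rarely (20%)
or frequently (80%), pushing the observer's decision criterion up or down.
The observer reports whether a backward-masked grating was present; target
presence in experimental blocks is always 50%. Peripheral physiology —
finger-pulse-derived heart rate and electrodermal activity — is recorded
throughout, because threat anticipation expresses itself as event-locked
bradycardia (heart-rate deceleration) with concurrent skin-conductance
increases.

A session consists of eight block pairs: a 20-trial manipulation block (four
rare, four frequent, order counterbalanced) followed by a 38-trial
experimental block. Six of the 38 trials are "extra": they carry the three
shock reinforcements and four shortened response windows, and are excluded
from analysis, leaving 32 analysed trials per block (16 threat, 16 safe,
half targets each). Within condition and session this yields 64 targets and
64 lures per subject.

## The observer model

Behaviour is generated by an equal-variance Gaussian signal-detection
observer. On a lure trial the decision variable is drawn from N(0, 1), on a
target trial from N(d', 1); the observer responds "present" when the
variable exceeds d'/2 + c. The analysis-side estimators are the standard

* d' = z(H) − z(F),
* c = −(z(H) + z(F)) / 2,

with a 0.25 count correction when a cell is perfect or empty. The model is
the one these formulas presuppose, so parameter recovery is meaningful by
construction.

Criterion dynamics are not modelled trial by trial; instead the
target-frequency context adds a fixed per-subject shift (+s after rare
blocks, −s after frequent blocks) to the base criterion. Threat does not
move the criterion under the default profile, and no threat-by-context
interaction is programmed — the null findings of the study are the
generator's null structure.

### Calibration of the defaults

The defaults encode the study's group statistics directly:

* d' 1.66 (threat) / 1.55 (safe); criterion 0.53 after rare and 0.20 after
  frequent blocks, i.e. base 0.365 ± shift 0.165;
* RT 632.4 / 616.5 ms; non-response rate mean 1.35% (SD ~2.2%, Beta across
  subjects);
* heart-rate change −4.38 / −2.99 BPM; square-root SCR amplitude 0.24 /
  0.09 √µS.

False-alarm levels are nowhere reported, so they are implied rather than
chosen: with the parameters above the model's hit rates are
Φ(d'/2 − c) ≈ 0.68 (threat) and 0.66 (safe) — matching the published hit
rates without further tuning — and false-alarm rates ≈ 0.12/0.13.

Between-subject SDs require one decomposition. The printed SDs of d'
(0.68/0.62) include binomial estimation noise: with 64 targets and 64 lures
per condition, the delta-method SE of a per-subject d' is ≈ 0.26. The latent
population SDs are therefore set to √(printed² − 0.26²) ≈ 0.56, and the
threat−safe difference is drawn with mean 0.11 and SD 0.10 (high latent
correlation between conditions, as expected when one titrated perceptual
system drives both). The same logic sets the criterion-shift SD. Two
across-subject correlations are induced through a Gaussian copula: the
bradycardia trait with mean RT (ρ = 0.32; deeper deceleration, faster
responses) and sensitivity with the criterion-shift magnitude (ρ = −0.29).

Pooling threat/safe trials across the two context halves (criteria 0.53 and
0.20) slightly attenuates the recovered pooled d' (≈ −0.02 to −0.04); the
small-sample convexity bias of z(p̂) at these trial counts acts in the
opposite direction (≈ +0.03). The net recovery bias is well inside the
±0.03 recovery tolerance used in the tests, which is why the latent means
are kept at the printed values rather than inflated.

## Mask contrast and the staircase

Visibility follows a logistic decay of d' in mask Michelson contrast,
normalised so that the observer's nominal d' applies at its reference
contrast (slope k = 6, midpoint 0.5; the published design reports only that
contrast was titrated, so the functional form is a package choice). The
3-down-1-up staircase starts at 60% contrast with a fixed 0.05 step in both
directions; equal steps put the asymptotic convergence point at the 79.4%
correct level of the psychometric function, consistent with the task's
observed ~75% (SD 8%) during-block accuracy and ~51% (SD 15%) final
contrast. The converged contrast is estimated as the mean of all reversals
except the first three; two independent runs (one per target orientation)
are averaged. A least-squares slope of |contrast| > 0.002 per trial stands
in for the experimenters' visual trend check and triggers a restart from
50% (downward trend) or 70% (upward).

In the full pipeline the titrated contrast becomes the contrast *at which
the observer's nominal sensitivities hold* — the printed d' values describe
post-titration performance, so the simulator defines them there. Observers
whose psychometric range cannot reach the convergence point pin the
staircase at the floor and are flagged, mirroring the study's exclusion of
participants for whom titration failed.

## Synthetic physiology

Heart rate is generated at 50 Hz (the analysis rate; acquisition-rate
synthesis would add nothing testable) as a tonic level plus event-locked
kernels plus noise:

* **Condition kernel.** A raised-cosine dip locked to trial onset (onset
  0.5 s, nadir 3 s, recovery 6 s), normalised so that the study's scoring —
  mean BPM over 1–5 s post onset minus a 1 s pre-onset baseline — returns
  exactly the programmed depth (−4.38 threat, −2.99 safe, trial-to-trial SD
  3 BPM).
* **Detection kernel.** Correct detections (hits) carry an additional
  anticipatory deceleration shaped as a sustained plateau (ramp 0.5–1 s,
  flat to 7 s, off by 8 s), with hit/miss adjustments centred by the
  expected hit rate so condition means are unaffected. The hit-minus-miss
  difference is a per-subject trait (mean 0.4 BPM, SD 1.0; the dispersion is
  back-derived from the published F(1,51) ≈ 5.3, partial η² ≈ 0.09 of the
  detection effect, given ~0.8 BPM of per-subject counting noise at these
  trial numbers). Because the plateau
  is flat across any stimulus-aligned baseline/window pair (stimulus onsets
  fall 1–3 s after trial onset), baseline correction cancels it under
  stimulus alignment: the hit-vs-miss difference exists when scored from
  trial onset and disappears when scored from stimulus onset, reproducing
  the study's dissociation generatively rather than by assertion.

A pulse waveform can be synthesised from any BPM trace (one raised-cosine
pulse per beat, inter-beat interval 60/BPM) to exercise the beat detector
end to end; the session pipeline scores the BPM trace directly.

Electrodermal activity is a tonic level plus SCR kernels (half-cosine rise
to the peak at 1.5 s, exponential decay, τ = 3 s). A trial elicits a
response with condition-dependent probability (0.6 threat / 0.3 safe), and
amplitudes are parameterised on the square-root scale so that the subject
mean √amplitude over *all* trials — zeros included, exactly what the
analysis averages — equals the printed 0.24/0.09 √µS. Onset latencies are
drawn inside the scoring window.

## Scoring rules

Beat detection smooths the pulse, takes local maxima above an adaptive
threshold with a 0.33 s refractory period, and flags implausible inter-beat
intervals (< 0.33 s or > 2 s); flat traces degrade to an empty, flagged
result. BPM between beats is step-interpolated (the alternative, linear
interpolation, differs by well under 0.1 BPM at these window widths).
Windowed heart-rate change uses the 1–5 s window and 1 s baseline for both
alignments; missing coverage yields a missing value, never an error.

SCR scoring searches the 10.5 s after stimulus onset for trough-to-peak
deflections whose onset lies 0.5–5.133 s post stimulus and whose
trough-to-peak rise takes 0.5–5 s ("rise time after response onset" is read
as time from SCR onset, not from the button press). Among qualifying
candidates the largest amplitude wins; no candidate scores as amplitude 0.
A minimum deflection of 0.01 µS and a 0.25 s smoothing window make the
trough/peak search robust to measurement noise; both are configurable, as
the original scoring tool does not publish its internal threshold.

## Inference

The battery mirrors the study's analysis list and tail conventions:
one-tailed tests only for the directional threat-vs-safe predictions on
heart rate, SCR, hits and d'; everything else two-tailed. The Wilcoxon
signed-rank test drops zero differences, uses the exact distribution for
n ≤ 12 untied pairs and a continuity-corrected normal approximation
otherwise, and reports r = |Z|/√n. Paired t tests attach d = t/√n; the
2 × 2 repeated-measures ANOVA is computed from within-subject contrasts
(for one-degree effects F is exactly the squared paired t, which the tests
verify against `aov` to 10⁻⁸) and attaches partial η² = F/(F + df₂). The
aligned-rank-transform ANOVA aligns each effect with balanced cell-mean
estimates, ranks across the whole sample, and reuses the parametric engine
on ranks. Effect-size confidence intervals are percentile bootstraps over
subjects (2000 resamples; 90% for the one-tailed analyses, 95% otherwise).

Two printed effect sizes in the source results (r = 0.10 for Z = −1.07 and
r = 0.08 for Z = −0.82) are inconsistent with r = |Z|/√52, and one d
(−1.03 for t = −7.39) differs in the second decimal, most plausibly from
rounding of the printed statistic; these pairs are documented rather than
reproduced.

## Power: what a replication of this design can and cannot show

A deliberate design consequence worth stating explicitly: with 64 targets
and 64 lures per condition, per-subject d' carries ≈ 0.26 estimation SE at
the average operating point, and more for subjects whose conservative
criteria push false-alarm counts toward zero. Measured on a large simulated
sample, the per-subject threat−safe d' difference has SD ≈ 0.42, of which
only ≈ 0.10 is latent heterogeneity — the rest is counting noise intrinsic
to the trial budget. At the printed effect (0.11) and n = 52 this caps the
one-tailed power of the d' comparison at roughly 0.5–0.6; the replication
sweep in the acceptance tests measures ≈ 0.5 and deliberately reports this
against a 0.70 expectation rather than inflating the generator's effect
size or suppressing criterion dispersion to force a pass. The
criterion-manipulation test, by contrast, rejects essentially always, and
the (absent) interaction stays at its nominal rate. The sweep simulates 55
collected subjects per replicate, mirroring recruitment that continued
until ~52 participants survived the performance-based exclusions
(non-response > 33%; accuracy beyond ±2 SD of the pre-exclusion sample
mean).

## Problem sizes and runtime choices

The test suite exercises the chain at sizes chosen to keep Monte-Carlo
error well below each tolerance: 500 staircase blocks for the titration
range; ~5000 trials per condition for physiological parameter recovery
(SE ≈ 0.04 BPM and 0.004 √µS); 5000 subjects for behavioural recovery
(SE ≈ 0.009 on d'); 2000 replicates for test calibration (SE ≈ 0.005 on a
0.05 rate); 200 replicate studies for the power properties (SE ≈ 0.03).
Simulation runs at 50 Hz; all RNG flows through explicit seeds, and every
result object carries its seed and configuration hash.

## What passing tests do and do not show

The generator reproduces the study's *group-level* structure: cell means,
between-subject dispersion after removing estimation noise, two
across-subject correlations, and the presence/absence pattern of effects.
It does not emulate serial dependencies within a session (fatigue,
criterion drift, trial-to-trial carryover — the carryover contrast is null
by construction), respiratory sinus arrhythmia or motion artefacts in the
physiology, stimulus-level variability, or any learning during the
manipulation blocks. Agreement between the pipeline and the printed values
therefore validates the scoring and inference chain and the plausibility of
the parameterisation — it is not evidence about new empirical data, and
analyses of real recordings should treat the defaults as a starting point,
not as facts about any future sample.
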