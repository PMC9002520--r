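---
title: "Validating a contactless sleep tracker against polysomnography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a contactless sleep tracker against polysomnography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sleepagree)
library(dplyr)
```

## The problem

Consumer sleep-tracking devices — here, a bed-embedded ballistocardiographic
sensor — report per-epoch heart rate (HR), breathing rate (BR) and a
sleep/wake decision. Before such a device can be used in research, its output
must be compared against the reference standard, laboratory polysomnography
(PSG), on simultaneously recorded nights. `sleepagree` implements the full
epoch-by-epoch and all-night agreement battery used for such validations:

* clock synchronization of the two recording systems and overnight profile
  concordance;
* simple and repeated-measures Bland–Altman limits of agreement (LOA), with
  gates for proportional bias, heteroscedasticity and non-normality and a
  regression-modeled fallback;
* epoch-by-epoch sleep/wake classification metrics, including the
  prevalence-and-bias-adjusted kappa and a pooled ROC;
* hypnogram summary variables (SOL, WASO, TST, SE) and their cohort-level
  agreement;
* a Fisher-z sample-size calculator for correlation confidence intervals.

Real device/PSG validation datasets are rarely shareable (consent usually
restricts them), so the package ships a synthetic cohort generator whose
defaults reproduce the marginal structure of a typical healthy-adult
laboratory cohort. Every analysis stage is therefore exercisable, and
testable, without any proprietary data.

## Conventions

An *epoch* is a half-open 30 s window `[t, t + 30)`, 0-based and anchored at
lights-off. Differences are always oriented `reference − device`, so a
**positive bias means the device underestimates** the reference. A positive
clock lag means the device stream is delayed relative to the reference.
Sleep is the positive class in all classification metrics.

## The synthetic cohort

`gen_cohort()` simulates subject-nights in four layers.

**Hypnogram.** The night opens with a wake run whose length — the sleep onset
latency — is lognormal with mean 16.4 and SD 13.6 minutes. The remainder is a
first-order Markov chain over the five AASM stages (W, N1, N2, N3, REM) at
30 s resolution; a Markov chain is the minimal generative process that
reproduces bout structure, and nothing in the downstream statistics depends
on longer-range dependence. The default transition matrix is built by
detailed balance from a target stationary distribution
(W 0.123, N1 0.044, N2 0.438, N3 0.175, REM 0.220) with a per-epoch switch
rate of 0.28: from any stage the chain moves to stage *j* with probability
`0.28 π_j`. Time in bed is `round(N(924, 60))` epochs truncated to
[686, 1036] (about 7.7 h, the span observed per subject-night in laboratory
cohorts of this kind). These choices put the expected summary variables at
TST ≈ 389 min, WASO ≈ 54 min, SOL ≈ 16 min and SE ≈ 0.85 — the targets the
generator is calibrated to by construction:

```{r}
set.seed(1)
sv <- bind_rows(lapply(1:50, function(i)
  summary_vars(gen_hypnogram(hypnogram_config())$stage)))
round(colMeans(sv), 1)
```

Two prevalence figures circulate for cohorts like this: a pooled
sleep-epoch prevalence of about 74% in the classification stream and a mean
sleep efficiency near 0.87. They are mutually inconsistent if the
classification stream equals all in-bed epochs; the package does not try to
reconcile them. The chain is calibrated to the summary-variable targets, and
the score model's operating point is a separate knob (`p_sleep`, `p_wake`),
so either figure can be matched when needed.

**Vitals.** Instantaneous HR and BR are stage baseline + a zero-mean linear
overnight decline + AR(1) fluctuation, sampled 60 times per epoch and floored
at 1; epoch values are exactly the within-epoch means, mirroring how
reference rates are built from beat/breath detections. Baselines
(HR: W 70, N1 68, N2 65.7, N3 63.5, REM 67.5 bpm; BR: 15.5/15.0/14.8/14.6/15.0)
are weighted by the chain's stationary stage mix to give overnight means of
66.4 bpm and 14.9 breaths/min. The raw sensor sampling rate of a real device
(hundreds of Hz) is irrelevant downstream — only epoch means enter the
analysis — so 2 Hz instantaneous sampling is used.

**Device error model.** On covered epochs,

```
device = reference − constant_bias − proportional_bias × reference + e,
e ~ N(0, (sd_intercept + sd_slope × reference)²)
```

Coverage dropout is Bernoulli per epoch (defaults 0.936 for HR, 0.994 for
BR). The device clock is shifted by an offset plus drift accumulated to
mid-night, rounded to whole epochs (default 60 s = 2 epochs); sub-epoch
alignment is out of scope. The sleep score is a logistic-noise perturbation
of the state probability, `plogis(qlogis(p_state) + N(0, 1.4))` with
`p_state = 0.90` for sleep epochs and `0.52` for wake, thresholded at 0.5.
Any real device's classifier is proprietary; a monotone score with a tunable
sensitivity/specificity operating point is all that ROC-based testing
requires. The defaults place the operating point at sensitivity ≈ 0.94 and
specificity ≈ 0.48 analytically (`pnorm(qlogis(0.90)/1.4)` and
`pnorm(−qlogis(0.52)/1.4)`), the regime typical of motion/cardiorespiratory
sleep staging, whose specificity for wake is its known weakness.

**Cohort.** Covariates follow a healthy-adult laboratory sample: age
truncated-normal 41.2 (10.5) years on [22, 64], 55.6% female, BMI normal
25.9 (4.4) kg/m², AHI lognormal with mean 6.53 and SD 15.1 events/h (AHI is
a covariate only; apnea events are not simulated). Between-subject
variation enters as random shifts of the vitals baselines (SD 8 bpm HR,
1.8 BR) and of the device constant bias (SD 1.5 / 0.35), which is what makes
the repeated-measures variance decomposition non-trivial. Device HR noise is
coupled to BMI (+0.15 bpm SD per kg/m² above the mean) and female sex
(+0.8 bpm SD), so covariate regressions on concordance have a recoverable
signal. Subject *i*'s series use seed `master + i`; three technician scorers
mislabel each epoch independently with probability 0.15 (typical inter-scorer
agreement for five-stage scoring is 82–85%), and an expert copy of the truth
breaks three-way ties.

What the generator does **not** emulate: raw waveforms, apnea/periodic-limb
events, artifact bursts correlated with movement, scorer biases that are
stage-dependent, or within-night drift re-estimation. Passing tests
therefore demonstrate that the *statistical machinery* is correct and
well-calibrated, not that any physical device meets these numbers on real
recordings.

## Alignment

`estimate_offset()` scans lags in `[−max_lag, +max_lag]` (default 20 epochs)
for the maximum normalized cross-correlation between the two systems'
movement channels — large movements are visible to both systems, which is
what makes them the natural synchronization fiducial. Ties break toward the
smallest `|lag|`, then toward the negative lag. One global lag per night is
estimated; `apply_offset()` shifts the device grid and masks epochs shifted
out of range. Profile smoothing (`smooth_profile()`) is a centered moving
average over a 15 min window (30 epochs); masked entries are ignored and the
mean renormalized — never interpolated, to avoid inventing data inside
coverage gaps — and the window shrinks at the edges. Profile concordance
(`profile_xcorr()`) is fixed at lag zero on the smoothed, aligned profiles,
because alignment has already been applied; the p-value uses the t
distribution on n − 2 df, which ignores the autocorrelation induced by
smoothing — a known approximation, flagged here rather than resolved.

## The agreement decision tree

`analyze_agreement()` reproduces the gated Bland–Altman battery:

1. **Normality.** Shapiro–Wilk on the differences (subsampled to 5000 when
   larger, the test's supported range). If non-normal and both measurements
   are non-negative, the differences are re-tested on a `log(x + 1)` scale
   (the +1 admits zero SOL) and the transform is recorded.
2. **Proportional bias.** OLS of difference on reference; flagged when the
   slope's two-sided p < 0.05.
3. **Heteroscedasticity.** OLS of `|residual|` on reference; flagged when
   that slope's p < 0.05.
4. If neither regression gate fires, a plain result: `simple_ba()` for one
   pair per subject, `rm_ba()` for epoch-by-epoch data. Otherwise a modeled
   result: `bias(ref) = b0 + b1·ref` with limits
   `bias ± 2.46 (c0 + c1·ref)`.

The 2.46 multiplier converts a fitted mean-absolute-deviation line into a
95% normal band: for centered normal residuals `E|e| = σ√(2/π)`, so
`1.96 σ = 1.96 √(π/2) E|e| ≈ 2.46 E|e|`. Coefficient intervals come from the
basic (reflected-percentile) bootstrap, resampling whole subjects in summary
mode and epochs within subject in epoch mode, B = 1000 by default.

Both regression gates run on the **original** measurement scale even when
the log retest fires, and the reported coefficient models are
original-scale, so `b0`, `b1`, `c0`, `c1` stay in the units of the signal
and are directly comparable across channels. On the log scale a purely
multiplicative error collapses to a constant offset, which would hide
exactly the proportional bias the gate exists to find. The regressor is
always the reference measurement (not the device value and not the pair
mean); with an imperfect reference this choice is debatable, but it keeps
every model conditional on the same axis.

The repeated-measures variance decomposition is one-way random-effects
ANOVA: `within = MSW`, `between = max(0, (MSB − MSW)/n0)` with the
unequal-group correction `n0 = (N − Σn_i²/N)/(m − 1)`; total SD is the root
of their sum and LOA are `bias ± 1.96 × SD_total`. Confidence intervals use
the delta method (`Var(bias) = between·Σn_i²/N² + within/N`; `Var(SD)` from
the chi-square variances of the mean squares) with t quantiles on m − 1 df.
A subject contributing a single difference would make MSW undefined, so the
function then falls back to the simple analysis over all differences, with a
warning.

## Classification metrics

Per subject, the 2×2 sleep/wake table yields sensitivity, specificity,
accuracy, balanced accuracy, precision, Cohen's kappa, the
prevalence-and-bias-adjusted kappa and d′. "Adjusted kappa" is implemented
as PABAK = 2·Po − 1, which is the prevalence-and-bias-adjusted kappa for a
2×2 table. d′ is `Φ⁻¹(hit rate) − Φ⁻¹(false-alarm rate)` with rates clamped
to `[1/(2n), 1 − 1/(2n)]` (n the relevant class count) so perfect nights
stay finite; the clamping constant is a convention, not an estimate. The
AUC is pooled over all epochs — one study-level curve, matching how a single
AUC is usually reported — rather than averaged per subject; per-subject
metrics are averaged unweighted, with undefined values excluded and counted.
Epochs without a device HR reading are **not** excluded from the
classification stream (the classifier always emits a state); the opposite
policy can be had by filtering the epoch table before
`cohort_class_summary()`.

## Summary variables

`summary_vars()` defines, in minutes (epochs × 0.5, no rounding): SOL from
lights-off to the first non-wake epoch; WASO as wake strictly between sleep
onset and sleep offset, with sleep offset taken as the *last* non-wake epoch;
TST as all non-wake epochs; and terminal wake reported explicitly so that
`SOL + WASO + TST + terminal wake = time in bed` holds exactly for every
hypnogram (this partition identity is property-tested). Device-side
summaries apply the same definitions to the device's predicted sleep/wake
series with lights-off/on taken from the reference recording — the device's
own bed-entry detection is not modeled, and an unscored (clock-shifted)
device epoch counts as wake.

## Concordance and sample size

Per-subject overnight concordance is the lag-zero correlation of the
15-min-smoothed HR (and BR) profiles after alignment; cohort level, the
per-subject correlations are averaged unweighted and HR vs BR compared by a
two-sided paired t-test (the natural test for per-subject paired
correlations). The covariate regression is OLS of the concordance value on
sex (female = 1), age and BMI; AHI is accepted as an optional extra column
but excluded from the default model, where near-zero AHI variance in healthy
cohorts adds nothing.

`sample_size_correlation()` searches the smallest n ≥ 4 whose
back-transformed Fisher-z interval `tanh(atanh(r) ± z/√(n−3))` has total
width ≤ 2 × half-width. "Interval width 0.1" is interpreted as *half*-width
0.1 (total width 0.2): that is the unique reading under which the
conventional planning example — r = 0.85, 95% level — yields n = 36:

```{r}
sample_size_correlation(r = 0.85, half_width = 0.1, level = 0.95)
```

## Numerical choices and degenerate inputs

* All gates are two-sided at α = 0.05; α, B and the 2.46 multiplier are
  arguments, not constants.
* A channel with identically zero differences (a perfect device) skips the
  gates — every test statistic is degenerate there — and returns the plain
  result with zero-width limits.
* Zero-variance inputs raise typed errors (`sleepagree_degenerate_error`,
  `sleepagree_alignment_error`) rather than NaN propagation; curation with
  nothing left raises `sleepagree_no_epochs_error`.
* Bootstrap resamples that are constant produce a degenerate interval with a
  warning rather than an error, so a pipeline over many channels survives
  one perfect channel.
* `estimate_offset()` tie-breaks deterministically (smallest `|lag|`, then
  negative), making alignment reproducible on symmetric inputs.

## Problem sizes used in the test-suite

The suite validates calibration and coverage at sizes chosen to make the
Monte-Carlo error a small fraction of each tolerance: 45-subject cohorts for
generator calibration, 200 replicates of 30 × 200 epochs for the
repeated-measures variance oracle, 500 replicates for CI coverage
experiments, 60,000 epochs for the null-AUC check, and exhaustive
enumeration wherever the space is finite (all 5³ scorer triples, all lags
|lag| ≤ 20, pair-counting AUC for n ≤ 50).

## Known limitations

* The generator's wake bouts are geometric (memoryless); real WASO bout
  distributions are heavier-tailed. Summary-variable *means* calibrate
  correctly; bout-length statistics would not.
* The t-based p-value for smoothed-profile correlations ignores smoothing
  autocorrelation and is anti-conservative; use it to rank, not to test.
* With few subjects, between-subject level differences can masquerade as
  proportional bias in pooled epoch-level gates (a real phenomenon of the
  pooled-OLS gate, visible on small synthetic cohorts).
* Device summary variables inherit the score model's epoch-independence; a
  real classifier's temporal smoothing would raise device-side SOL. Compare
  SOL/WASO structure, not their absolute synthetic values, against real
  studies.
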