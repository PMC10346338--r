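---
title: "Estimating wearable biometric reliability without a benchmark device"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating wearable biometric reliability without a benchmark device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reliwear)
```

## The problem

Wrist PPG sensors sample heart rate (BPM) and heart-rate variability
(rMSSD, in milliseconds) every few minutes for days on end. Outside the
lab there is no ECG to validate against, so the only measurement-fidelity
question that can still be answered is about *reliability*: does the
sensor agree with itself? `reliwear` answers it in two complementary
senses, both estimable from a single device's stream.

## Between-person reliability: the one-way ICC

A measurement is modelled as

$$x_{ij} = \mu + r_i + v_{ij}, \qquad
  r_i \sim N(0, \sigma_r^2),\; v_{ij} \sim N(0, \sigma_v^2),$$

so the population intraclass correlation is
$\rho = \sigma_r^2 / (\sigma_r^2 + \sigma_v^2)$: the fraction of
measurement variance that is stable between-person signal. The sample
estimator is the one-way random-effects single-measure form,

$$\mathrm{ICC}(1,1) = \frac{MSBS - MSWS}{MSBS + (k-1)\,MSWS},$$

computed by `decompose_oneway()` + `icc_single()`; `icc_average()` gives
the average-measure form $(MSBS - MSWS)/MSBS$, which equals the
Spearman–Brown step-up of the single-measure value. A one-way form is
appropriate because there is no a priori reason to model a systematic
rater-like effect for a single physiological sensor; two-way forms are
deliberately out of scope.

Decisions worth knowing:

* **Unbalanced designs.** The textbook formula requires equal replicate
  counts $k$, but free-living data never cooperate. With unequal $k_i$
  the decomposition substitutes Searle's effective count
  $k_0 = \big(N - \sum k_i^2/N\big)/(n-1)$ and flags the result
  `balanced = FALSE`. Participants with fewer than two replicates are
  dropped with a warning.
* **Intervals and tests.** Confidence bounds use the one-way F bounds
  (Shrout–Fleiss): $F_L = F / F_{1-\alpha/2}(n-1, N-n)$,
  $F_U = F \cdot F_{1-\alpha/2}(N-n, n-1)$, mapped through
  $(F-1)/(F+k-1)$. The p-value is the one-sided F test of
  $H_0\!: \rho = 0$. No resampling is used; on balanced Gaussian data the
  interval is exact, which the test suite confirms by coverage simulation
  (95% interval covers the true $\rho$ in 93–97% of 1000 runs at
  $n = 50$, $k = 5$).
* **Range.** The sample statistic can reach $-1/(k-1)$; it is reported
  unclipped. Strongly negative values are themselves diagnostic of a
  systematic variance source.
* **Qualitative bins.** `classify_icc()` defaults to
  poor < 0.25 ≤ fair < 0.40 ≤ good < 0.75 ≤ excellent, the usage common
  in the wearable-reliability literature (0.65 read as good, 0.38 as
  fair). These differ from Cicchetti's clinical bins and are fully
  configurable.

## Within-person reliability: split-half mixed models

Within-person reliability asks whether repeated samples of the *same
person in the same situation* agree. Each unit's samples (a
participant-day in one sleep/wake state, or a participant-activity cell)
are split into halves, and the half-means are related by

$$y = a + \beta x + (1\,|\,\mathrm{participant})
      \;[+\,(1\,|\,\mathrm{situation})],$$

with random intercepts only — the model contains no random slopes. A
slope near 1 means the halves agree once stable between-unit differences
are absorbed by the intercepts.

* **Time-sensitive split** (`split_time_sensitive()`): samples are
  numbered in acquisition order; odd positions form one half, even the
  other, pairing samples as close in time as possible. Positions start
  at 1 and the odd half takes the extra sample for odd counts. The even
  half is always the predictor and the odd half the criterion — the
  direction is arbitrary but fixed for determinism.
* **Random split** (`split_random()`, `random_split_distribution()`): a
  single random partition can be lucky or unlucky, so the partition is
  redrawn (default 1000×) and the reliability estimate is the mean slope,
  reported with its SD across iterations. Per-iteration seeds are the
  first `n` draws of `sample.int()` under the master seed, so any run is
  reproducible bit for bit and iterations are independent.
* **Inference.** The t test of $\beta$ uses Satterthwaite degrees of
  freedom (via `lmerTest`). Fitting uses `lme4`; boundary ("singular")
  fits are legitimate zero-variance estimates and count as converged,
  while optimizer non-convergence is flagged and excluded from
  random-split summaries (with a warning once more than 10% of
  iterations fail). On exactly noise-free data the residual variance is
  0 and mixed-model standard errors do not exist; the slope is still
  reported, with `NA` test statistics and an explanatory note.

## Cleaning and segmentation

Two artifact filters run, in a fixed order, each exactly once:

1. `remove_zero_samples()` — wearable exports encode failed reads as
   literal zeros (overwhelmingly in rMSSD); all are dropped and logged
   per metric.
2. `remove_outlier_samples()` — per participant and metric, values more
   than 2 sample SDs (strict inequality, divisor $n-1$) from the mean of
   the *whole* retained series are dropped. The statistics are computed
   once; iterating the filter to a fixed point would keep eating the
   distribution's tails, so the pipeline forbids it. Series with fewer
   than 3 samples are left untouched.

Sleep is then segmented from BPM sampling density alone
(`detect_sleep_periods()`): a sleep period is the longest run of
consecutive BPM samples per study day with inter-sample gaps ≤ 15 min and
span ≥ 2 h. Study days run noon to noon in local clock time so a night
crossing midnight is one observation — hence the package-wide insistence
on timestamps with explicit UTC offsets. Ties go to the earliest run;
interval membership is closed on both ends. Two exclusion rules follow
(`apply_study_exclusions()`): participants with fewer than 3 detected
sleep periods are dropped entirely (the weakest rule consistent with
dropping 1–2-period participants while keeping ≥ 5-period ones; the
threshold is configurable), and participant-days with fewer than 2
wakeful rMSSD samples lose those records (one sample cannot be split).

## Daily affect and lagged models

EMA prompts carry eight 1–10 items. Negative affect is the mean of
irritable, afraid, nervous, angry; positive affect the mean of happy,
energetic; pain and discomfort ride along unscored. A scale missing more
than half its items yields `NA` for that prompt (the paper-level sources
of such rules rarely address partial prompts; at least half present is
this package's choice). Prompt scores average into participant-day
scores.

`fit_lagged_models()` fits the six-model family — metric (BPM, rMSSD) ×
timing (concurrent wake, preceding night, following night) — regressing
the daily biometric on both affect scores with a participant random
intercept. Affect is the predictor by convention even where the
scientific reading runs the other way. Wake biometrics are keyed by
calendar date; sleep biometrics by the noon-anchored study day (the
evening the night began), so the preceding night of affect day $D$ is
study day $D-1$ and the following night is $D$. Both raw and
Bonferroni-corrected p-values ($m = 6$, the full family) are reported,
per term.

## The simulator: what it emulates, and what it does not

`simulate_components()` draws the matrix-form variance-components model
exactly: $x = \mu + r_i + s_j + v_{ijk}$, all Gaussian and independent
(the model itself states no distributions; Gaussian is the conventional
reading). `simulate_stream()` adds the wearable's sampling mechanics: a
5-minute grid, every grid point emitted inside the nightly 23:00–07:00
sleep window, wakeful points retained with probability `wake_retention`
(default 0.1 in `simulate_cohort()`, giving the order of 15–20 wakeful
samples a day against ~95 sleep samples, the density asymmetry of real
continuous wear). Each (participant, study-day, state) occasion draws its
own situation effect, with separate sleep and wake SDs, and residual
noise is likewise state-specific — wakeful recordings are far more
variable than sleep recordings, and a single shared variance could not
express that. Artifacts are injected only after the truth is stored:
zeros at `zero_rate` (default 0.1926 for rMSSD in `simulate_cohort()`,
the empirical HRV zero fraction such sensors produce), deterministic
mean + 4 SD spikes at `outlier_rate` (deterministic so the 2-SD filter's
expected behaviour is analyzable), and censoring of negative draws to 0.

`simulate_cohort()` fixes the study conditions used throughout the tests:
10 participants, 7 noon-to-noon days, BPM around 70 (between-person SD 5,
sleep/wake occasion SDs 1/3, noise SDs 2/6) and rMSSD around 45 ms
(between-person SD 12, occasion SDs 4/8, noise SDs 5/25). These are
ordinary resting-physiology magnitudes with the empirically ubiquitous
sleep ≪ wake variability ordering baked in.

What the generator does *not* emulate: circadian heart-rate curves,
respiratory sinus arrhythmia, serial autocorrelation within a night,
activity-dependent artifact bursts, or device clock drift. Passing tests
therefore demonstrate that the estimators recover the statistical
structure they assume — not that any particular commercial device attains
a given reliability on real wrists.

## Numerical choices and degenerate inputs

* All-identical data make the single-measure ICC 0/0: an error, not a
  number. `MSWS = 0` with signal present returns exactly 1 with a
  degenerate CI of [1, 1].
* Zero predictor variance in a split-half fit is a degenerate-design
  error; fewer than 3 pairs is insufficient data.
* Random factors observed at a single level are dropped from the formula
  (with a note); with none left the fit falls back to ordinary least
  squares rather than failing.
* Ties in run length during sleep detection resolve to the earliest run;
  record sorting is total, so every pipeline stage is deterministic under
  a fixed seed.
* Test problem sizes were chosen to make Monte-Carlo noise small relative
  to the asserted tolerances while keeping the default suite in the
  minutes range: 100 oracle tables, 1000 CI-calibration simulations at
  $n = 50$, $k = 5$, 1000 noiseless random splits, 200 random splits per
  condition elsewhere, and 200 null-association EMA replicates.

## Known limitations

* Sleep detection equates "densely sampled" with "asleep"; quiet wakeful
  wear is mislabelled sleep, a bias the segmentation cannot see from
  density alone.
* The one-way ICC folds every situational effect into error; if a
  systematic rater-like factor exists (e.g. device model differences), a
  two-way design would be needed, which this package intentionally does
  not provide.
* Split-half slopes are reported raw, without Spearman–Brown step-up,
  and serial dependence within units is not modelled; for sparsely
  sampled wakeful rMSSD the time-sensitive and random methods can
  legitimately disagree.
* The F-based CI assumes Gaussian components; under heavy-tailed noise
  its coverage degrades, and no robust alternative is implemented.
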