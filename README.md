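# reliwear

Benchmark-free reliability assessment for wearable cardiac biometrics.

Wrist-worn PPG sensors stream heart rate (BPM) and heart-rate variability
(rMSSD, ms) around the clock, but their measurement fidelity in daily life
is usually judged by comparing against an ECG benchmark — something that is
impossible once the device leaves the lab. `reliwear` implements the
complementary view: **reliability**, estimated from a single sensor's own
data stream, with no reference device.

Two quantities are computed:

- **Between-person reliability** — the one-way random-effects intraclass
  correlation. For measurements `x_ij = μ + r_i + v_ij` (participant effect
  `r_i ~ N(0, σ_r²)`, error `v_ij ~ N(0, σ_v²)`), the population value is
  `ρ = σ_r² / (σ_r² + σ_v²)`, estimated by

  ```
  ICC(1,1) = (MSBS − MSWS) / (MSBS + (k − 1) MSWS)
  ```

  with between/within mean squares from the one-way ANOVA decomposition,
  Searle's effective k₀ for unbalanced designs, F-based (Shrout–Fleiss)
  confidence intervals, and a one-sided F test of zero ICC.

- **Within-person reliability** — split-half agreement via the mixed model
  `y = a + β·x + (1|participant) [+ (1|situation)]`, where `x` and `y` are
  the two half-means of each unit's samples. Halves are formed either
  **time-sensitively** (odd/even acquisition positions, as close in time
  as possible) or **randomly**, repeated (default 1000×) to summarize the
  distribution of slopes; β near 1 means the sensor agrees with itself.
  Satterthwaite degrees of freedom are used for the t test.

Around these sit the full pipeline: artifact filters (literal-zero removal,
per-participant 2-SD outlier trimming), sleep-period segmentation from BPM
sampling density (runs ≥ 2 h with gaps ≤ 15 min; longest run per
noon-to-noon study day), the participant/day exclusion rules, daily
positive/negative affect scoring from EMA prompts with six lagged mixed
models (Bonferroni family m = 6), and a seeded variance-components
simulator so everything is testable offline.

## Worked example

```r
library(reliwear)

# one week of simulated continuous wear: BPM + rMSSD, dense sleep sampling,
# sparse noisy wake sampling, ~19% of rMSSD samples zeroed by the vendor
cohort <- simulate_cohort(seed = 505, n_participants = 10, n_days = 7)

prep <- prepare_stream(cohort$stream)   # clean -> segment -> label -> exclude
sleep_hrv <- prep$stream |>
  dplyr::filter(state == "sleep", metric == "rmssd") |>
  as_sample_stream()

sleep_hrv |>
  condition_means("day") |>
  decompose_oneway() |>
  icc_single()
#> ICC(1,1) = 0.858, 95% CI [0.714, 0.955], p = 6.35e-23 (excellent reliability; n = 10, k = 7)

random_split_distribution(sleep_hrv, unit_key = c("study_day", "state"),
                          n_iterations = 200, master_seed = 606)
#> Random-split reliability: mean beta = 0.9928, SD across 200 iterations = 0.0139 (0 failed)
```

The ICC of 0.86 says that 86% of the variance in nightly rMSSD day-means is
stable between-person variance — individuals keep their rank ordering night
after night. The mean split-half slope of 0.995 says the two random halves
of each night agree almost perfectly: within-person measurement noise is
negligible during sleep. Running the same two calls on the wakeful samples
of this cohort gives ICC = 0.77 and mean β = 0.40 — the sleep > wake
reliability ordering that motivates doing biometric inference on nights
rather than days.

`run_report(run_config(samples = "samples.csv", out_dir = "report"))`
executes the whole pipeline and writes tidy CSV tables (between- and
within-person reliability per metric and state, sleep intervals, filter and
exclusion logs) plus a YAML manifest; identical config and seed give
byte-identical output. A thin CLI wrapper lives in `inst/cli/reliwear.R`
(`simulate` and `report` subcommands).

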