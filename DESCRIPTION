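Package: reliwear
Title: Benchmark-Free Reliability Assessment for Wearable Cardiac Biometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies between-person and within-person measurement
    reliability of heart rate (BPM) and heart rate variability (rMSSD)
    recorded by a single wearable photoplethysmography sensor, without a
    benchmark device. Implements one-way random-effects intraclass
    correlations with F-based confidence intervals, split-half
    within-person reliability via mixed-model regression (time-sensitive
    odd/even and repeated random splits), artifact filtering, sleep-period
    segmentation from sampling density, daily affect scoring from
    ecological momentary assessment prompts with lagged mixed models, and
    a variance-components simulator so the entire pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
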