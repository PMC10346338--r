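make_ema <- function(...) {
  rows <- tibble::tibble(...)
  defaults <- tibble::tibble(participant_id = "P01",
    timestamp = ts_utc("2024-03-04 09:00:00"),
    happy = 5L, energetic = 5L, nervous = 5L, afraid = 5L,
    irritable = 5L, angry = 5L, pain = 5L, discomfort = 5L)
  out <- dplyr::bind_rows(rows)
  for (nm in names(defaults)) {
    if (!nm %in% names(out)) out[[nm]] <- defaults[[nm]]
  }
  out <- out[names(defaults)]
  class(out) <- c("ema_records", class(out))
  out
}

test_that("prompt scoring averages the scale items and honours the missing-item rule", {
  ema <- make_ema(happy = 8L, energetic = 6L, nervous = 2L, afraid = 1L,
    irritable = 3L, angry = 2L)
  sc <- score_prompts(ema)
  expect_equal(sc$pos_score, 7)
  expect_equal(sc$neg_score, 2)

  # 3 of 4 negative items present: scored from those 3
  ema2 <- make_ema(irritable = 4L, afraid = 4L, nervous = NA_integer_,
    angry = 4L)
  expect_equal(score_prompts(ema2)$neg_score, 4)

  # more than half of each scale missing: prompt skipped and reported
  ema3 <- make_ema(happy = c(5L, NA), energetic = c(5L, NA),
    nervous = c(5L, NA), afraid = c(5L, NA), irritable = c(5L, NA),
    angry = c(5L, 7L),
    timestamp = ts_utc(c("2024-03-04 09:00:00", "2024-03-04 11:00:00")))
  expect_message(sc3 <- score_prompts(ema3), "skipped")
  expect_equal(nrow(sc3), 1)
  expect_equal(nrow(attr(sc3, "skipped")), 1)
  # pain/discomfort never enter the scores
  ema4 <- make_ema(pain = 10L, discomfort = 10L)
  expect_equal(score_prompts(ema4)$neg_score, 5)
  expect_equal(score_prompts(ema4)$pos_score, 5)
})

test_that("daily affect pools prompts within a participant-day only", {
  ema <- make_ema(
    participant_id = c("P01", "P01", "P01", "P02"),
    timestamp = ts_utc(c("2024-03-04 09:00:00", "2024-03-04 15:00:00",
      "2024-03-05 09:00:00", "2024-03-04 09:00:00")),
    nervous = c(2L, 4L, 8L, 6L), afraid = c(2L, 4L, 8L, 6L),
    irritable = c(2L, 4L, 8L, 6L), angry = c(2L, 4L, 8L, 6L))
  daily <- daily_affect(score_prompts(ema))
  p1d1 <- daily[daily$participant_id == "P01" &
    daily$day == as.Date("2024-03-04"), ]
  expect_equal(p1d1$neg_score, 3) # mean of prompts at 2 and 4
  expect_equal(p1d1$n_prompts, 2L)
  p1d2 <- daily[daily$participant_id == "P01" &
    daily$day == as.Date("2024-03-05"), ]
  expect_equal(p1d2$neg_score, 8)
  expect_equal(p1d2$n_prompts, 1L)
  expect_equal(nrow(daily), 3)
})

test_that("bonferroni multiplies by the family size and caps at one", {
  expect_equal(bonferroni(0.009, 6), 0.054)
  expect_equal(bonferroni(0.3, 6), 1)
  expect_equal(bonferroni(c(0.01, 0.2), 6), c(0.06, 1))
})

test_that("night/day alignment pairs each affect day with the intended nights", {
  # constructed adjacency: sleep biometrics keyed by the evening their
  # night began; wake by calendar day
  bio <- tibble::tibble(
    participant_id = "P01", metric = "bpm",
    state = c("wake", "sleep", "sleep"),
    day = as.Date(c("2024-03-05", "2024-03-04", "2024-03-05")),
    mean_value = c(80, 55, 58), n = 10L)
  affect <- tibble::tibble(participant_id = "P01",
    day = as.Date("2024-03-05"), neg_score = 3, pos_score = 6,
    n_prompts = 4L)
  # exhaustive check through the join logic of each timing
  grid <- list(
    concurrent_wake = 80, # wake of Mar 5
    preceding_night = 55, # night Mar 4 -> Mar 5 morning
    following_night = 58) # night Mar 5 -> Mar 6 morning
  for (timing in names(grid)) {
    sub <- if (timing == "concurrent_wake") {
      dplyr::mutate(bio[bio$state == "wake", ], day_key = day)
    } else if (timing == "preceding_night") {
      dplyr::mutate(bio[bio$state == "sleep", ], day_key = day + 1)
    } else {
      dplyr::mutate(bio[bio$state == "sleep", ], day_key = day)
    }
    paired <- dplyr::inner_join(affect, sub,
      by = c("participant_id", day = "day_key"))
    expect_equal(nrow(paired), 1)
    expect_equal(paired$mean_value, grid[[timing]])
  }
})

test_that("the six lagged models are produced with Bonferroni-corrected p-values", {
  cfg <- sim_config(seed = 77, n_participants = 8, sigma_r = 5, sigma_s = 2,
    sigma_v = 2, sigma_v_wake = 6, wake_retention = 0.2)
  simb <- simulate_stream(cfg, n_days = 7, metric = "bpm")
  cfg2 <- sim_config(seed = 78, n_participants = 8, sigma_r = 12,
    sigma_s = 5, sigma_v = 5, sigma_v_wake = 15, wake_retention = 0.15)
  simh <- simulate_stream(cfg2, n_days = 7, metric = "rmssd")
  stream <- as_sample_stream(dplyr::bind_rows(
    tibble::as_tibble(simb$stream), tibble::as_tibble(simh$stream)))
  lab <- label_state(stream, detect_sleep_periods(stream))
  bio <- daily_biometrics(lab)
  ema <- simulate_ema(cfg, n_days = 7)
  affect <- daily_affect(score_prompts(ema))
  res <- fit_lagged_models(affect, bio)
  expect_equal(sort(unique(res$model_id)),
    sort(paste(rep(c("bpm", "rmssd"), each = 3),
      c("concurrent_wake", "preceding_night", "following_night"), sep = "_")))
  expect_equal(nrow(res), 12) # six models x two affect terms
  ok <- !is.na(res$p_raw)
  expect_true(any(ok))
  expect_equal(res$p_bonferroni[ok], pmin(1, 6 * res$p_raw[ok]))
  expect_true(all(res$p_bonferroni[ok] <= 1))
  expect_true(all(res$n_observations > 0))
})

test_that("a planted next-day association is recovered within two standard errors", {
  cfg <- sim_config(seed = 123, n_participants = 10, sigma_r = 5,
    sigma_s = 2, sigma_v = 2, wake_retention = 0.2)
  sim <- simulate_stream(cfg, n_days = 10, metric = "bpm")
  lab <- label_state(sim$stream, detect_sleep_periods(sim$stream))
  # affect responds to the preceding night: neg items shift by
  # slope * centred night mean; regressing biometric on neg flips the
  # relation, so the fitted slope should be positive for positive `slope`
  ema <- simulate_ema(cfg, n_days = 10, dataset = sim,
    association = list(slope = 0.6))
  affect <- daily_affect(score_prompts(ema))
  res <- fit_lagged_models(affect, daily_biometrics(lab))
  row <- res[res$model_id == "bpm_preceding_night" & res$term == "neg_score", ]
  expect_false(is.na(row$beta))
  se <- abs(row$beta / row$t_stat)
  expect_gt(row$beta + 2 * se, 0)
  expect_gt(row$beta, 0)
  expect_lt(row$p_raw, 0.05)
})
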