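test_that("time-sensitive split averages odd and even positions by hand rule", {
  s <- make_stream(c(70, 72, 74, 76), activity = "rest")
  pairs <- split_time_sensitive(s, unit_key = "activity")
  expect_equal(pairs$criterion_mean, mean(c(70, 74))) # odd positions
  expect_equal(pairs$predictor_mean, mean(c(72, 76))) # even positions
  expect_equal(pairs$n_odd, 2L)
  expect_equal(pairs$n_even, 2L)

  s5 <- make_stream(c(70, 72, 74, 76, 78), activity = "rest")
  p5 <- split_time_sensitive(s5, unit_key = "activity")
  expect_equal(p5$criterion_mean, mean(c(70, 74, 78)))
  expect_equal(p5$predictor_mean, mean(c(72, 76)))
  expect_equal(abs(p5$n_odd - p5$n_even), 1L) # near-equal halves
})

test_that("positions follow acquisition order, not file order", {
  rows <- tibble::as_tibble(make_stream(c(70, 72, 74, 76), activity = "rest"))
  shuffled <- as_sample_stream(rows[c(3, 1, 4, 2), ])
  pairs <- split_time_sensitive(shuffled, unit_key = "activity")
  expect_equal(pairs$criterion_mean, mean(c(70, 74)))
  expect_equal(pairs$predictor_mean, mean(c(72, 76)))
})

test_that("single-sample units are dropped and reported", {
  rows <- dplyr::bind_rows(
    tibble::as_tibble(make_stream(c(70, 72), activity = "rest")),
    tibble::as_tibble(make_stream(90, activity = "walk",
      start = "2024-03-04 11:00:00")))
  pairs <- split_time_sensitive(as_sample_stream(rows), unit_key = "activity")
  expect_equal(nrow(pairs), 1)
  dropped <- attr(pairs, "dropped")
  expect_equal(dropped$activity, "walk")
})

test_that("random splits conserve counts, respect sizes and are seed-deterministic", {
  s <- make_stream(c(70, 71, 72, 73, 74, 75, 76), activity = "rest")
  p1 <- split_random(s, unit_key = "activity", seed = 10)
  expect_equal(p1$n_odd, 4L) # ceiling(7/2)
  expect_equal(p1$n_even, 3L)
  expect_equal(p1$n_odd + p1$n_even, 7L)
  # halves partition the data: total mean is the count-weighted half mean
  expect_equal(
    (p1$criterion_mean * p1$n_odd + p1$predictor_mean * p1$n_even) / 7,
    mean(s$value))
  p2 <- split_random(s, unit_key = "activity", seed = 10)
  expect_identical(p1$criterion_mean, p2$criterion_mean)
  p3 <- split_random(s, unit_key = "activity", seed = 11)
  expect_false(identical(p1$criterion_mean, p3$criterion_mean))

  const <- make_stream(c(5, 5, 5, 5), metric = "rmssd", activity = "rest")
  pc <- split_random(const, unit_key = "activity", seed = 3)
  expect_equal(pc$criterion_mean, 5)
  expect_equal(pc$predictor_mean, 5)
})

noiseless_units_stream <- function(n_participants = 6, n_units = 4,
                                   k = 6, seed = 5) {
  # distinct unit means, zero within-unit noise: both halves equal the
  # unit mean by construction
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(n_participants), function(i) {
      purrr::map_dfr(seq_len(n_units), function(u) {
        mu <- 60 + 5 * i + rnorm(1, 0, 4)
        tibble::tibble(
          participant_id = sprintf("P%02d", i), device_id = "d1",
          timestamp = ts_utc("2024-03-04 08:00:00") +
            (u - 1) * 86400 + (seq_len(k) - 1) * 300,
          metric = "bpm", value = mu,
          activity = paste0("unit", u), state = "unlabeled")
      })
    })
    as_sample_stream(rows)
  })
}

test_that("noiseless units give slope 1; degenerate designs error", {
  s <- noiseless_units_stream()
  pairs <- split_time_sensitive(s, unit_key = "activity")
  expect_equal(pairs$predictor_mean, pairs$criterion_mean)
  fit <- fit_split_model(pairs)
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)

  flat <- pairs
  flat$predictor_mean <- 70
  expect_error(fit_split_model(flat), class = "reliwear_degenerate_error")
  expect_error(fit_split_model(pairs[1:2, ]), class = "reliwear_data_error")
})

test_that("the mixed model recovers slopes with Satterthwaite statistics", {
  withr::with_seed(21, {
    s <- noiseless_units_stream(n_participants = 8, n_units = 6, k = 8)
    df <- tibble::as_tibble(s)
    df$value <- df$value + rnorm(nrow(df), 0, 2)
    pairs <- split_time_sensitive(as_sample_stream(df), unit_key = "activity")
    fit <- fit_split_model(pairs)
    expect_true(fit$converged)
    expect_gt(fit$df, 0)
    expect_lt(fit$p_value, 0.01)
    expect_equal(fit$beta, 1, tolerance = 0.25)
    td <- tidy(fit)
    expect_equal(td$beta, fit$beta)
  })
})

test_that("random-split distributions are reproducible and summarize convergence", {
  s <- noiseless_units_stream()
  d1 <- random_split_distribution(s, unit_key = "activity",
    n_iterations = 25, master_seed = 42)
  d2 <- random_split_distribution(s, unit_key = "activity",
    n_iterations = 25, master_seed = 42)
  expect_identical(d1$betas, d2$betas)
  expect_equal(d1$mean_beta, 1, tolerance = 1e-6)
  expect_equal(d1$sd_beta, 0, tolerance = 1e-8)
  expect_equal(d1$n_failed + length(d1$betas), d1$n_iterations)
})

test_that("mean slope decreases as within-unit noise grows", {
  betas <- purrr::map_dbl(c(0, 4, 12), function(sv) {
    cfg <- sim_config(seed = 31, n_participants = 6, sigma_r = 5,
      sigma_s = 3, sigma_v = sv, wake_retention = 0)
    sim <- simulate_stream(cfg, n_days = 5)
    lab <- label_state(sim$stream, detect_sleep_periods(sim$stream))
    d <- random_split_distribution(lab, unit_key = c("study_day", "state"),
      n_iterations = 40, master_seed = 17)
    d$mean_beta
  })
  expect_true(all(diff(betas) <= 1e-6))
  expect_equal(betas[1], 1, tolerance = 1e-6)
})

test_that("time-sensitive slope sits inside the random-split distribution for iid samples", {
  # no serial structure within units: odd/even is just one more partition
  hits <- 0
  n_rep <- 8
  for (seed in seq_len(n_rep)) {
    cfg <- sim_config(seed = 600 + seed, n_participants = 6, sigma_r = 5,
      sigma_s = 3, sigma_v = 3, wake_retention = 0)
    sim <- simulate_stream(cfg, n_days = 4)
    lab <- label_state(sim$stream, detect_sleep_periods(sim$stream))
    ts_beta <- fit_split_model(
      split_time_sensitive(lab, unit_key = c("study_day", "state")),
      ddf = FALSE)$beta
    d <- random_split_distribution(lab, unit_key = c("study_day", "state"),
      n_iterations = 60, master_seed = 900 + seed)
    q <- quantile(d$betas, c(0.025, 0.975))
    if (ts_beta >= q[1] && ts_beta <= q[2]) hits <- hits + 1
  }
  expect_gte(hits, n_rep - 1)
})
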