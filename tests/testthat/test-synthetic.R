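test_that("matrix-form simulation is deterministic and reconstructs from truth", {
  cfg <- sim_config(seed = 9, n_participants = 5, n_situations = 3,
    k_replicates = 2)
  a <- simulate_components(cfg)
  b <- simulate_components(cfg)
  expect_identical(a$data, b$data)
  expect_equal(a$data$value, cfg$mu + a$data$r + a$data$s + a$data$v)
  # stored truth tables match the per-record components
  pe <- a$truth$participant_effects
  expect_equal(a$data$r, pe$r[match(a$data$participant_id, pe$participant_id)])

  nv <- simulate_components(sim_config(seed = 9, sigma_v = 0, sigma_s = 0,
    n_participants = 4, k_replicates = 3))
  per <- split(nv$data$value, nv$data$participant_id)
  for (v in per) expect_equal(var(v), 0)
})

test_that("realized participant-effect variance approaches sigma_r^2", {
  cfg <- sim_config(seed = 14, sigma_r = 3, n_participants = 2000,
    n_situations = 1, k_replicates = 2)
  r <- simulate_components(cfg)$truth$participant_effects$r
  expect_equal(var(r), 9, tolerance = 0.1 * 9)
})

test_that("timestamped streams honour the sampling schedule and artifact rates", {
  cfg <- sim_config(seed = 25, n_participants = 4, wake_retention = 1,
    zero_rate = 0, outlier_rate = 0)
  sim <- simulate_stream(cfg, n_days = 2)
  # complete artifact-free 5-min grid: 288 points/day/participant
  expect_equal(nrow(sim$stream), 4 * 2 * 288)
  expect_true(all(sim$stream$value > 0))
  expect_identical(tibble::as_tibble(sim$stream),
    tibble::as_tibble(simulate_stream(cfg, n_days = 2)$stream))
  # truth reconstruction on pre-artifact values
  rec <- sim$truth$records
  expect_equal(rec$clean_value, cfg$mu + rec$r + rec$s + rec$v)
  expect_equal(rec$value, rec$clean_value)

  zr <- 0.1926 # the empirical HRV zero fraction the generator emulates
  cfgz <- sim_config(seed = 26, n_participants = 6, wake_retention = 0.3,
    zero_rate = zr, outlier_rate = 0.02)
  simz <- simulate_stream(cfgz, n_days = 5, metric = "rmssd")
  recz <- simz$truth$records
  expect_equal(mean(simz$stream$value == 0), zr, tolerance = 0.01)
  expect_equal(sort(unique(recz$artifact)), c("none", "outlier", "zero"))
  # artifacts overwrite values but never the stored truth
  expect_true(all(recz$clean_value[recz$artifact == "zero"] != 0))
  # spikes are deterministic +4 SD excursions
  out_rows <- recz[recz$artifact == "outlier", ]
  stats <- recz |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(m = mean(clean_value), s = sd(clean_value))
  expected <- stats$m[match(out_rows$participant_id, stats$participant_id)] +
    4 * stats$s[match(out_rows$participant_id, stats$participant_id)]
  expect_equal(out_rows$value, expected)
})

test_that("planted nightly blocks are recoverable by sleep detection", {
  cfg <- sim_config(seed = 33, n_participants = 3, wake_retention = 0.05)
  sim <- simulate_stream(cfg, n_days = 4)
  got <- detect_sleep_periods(sim$stream)
  planted <- sim$truth$sleep_blocks
  joined <- dplyr::inner_join(tibble::as_tibble(got), planted,
    by = c("participant_id", "study_day"))
  expect_equal(nrow(joined), nrow(planted))
  # detected interval always covers the planted dense block
  expect_true(all(joined$start.x <= joined$start.y))
  expect_true(all(joined$end.x >= joined$end.y))
  # and sleep labels recover the true state for the planted samples
  lab <- label_state(sim$stream, got)
  truth <- sim$truth$records
  key <- paste(lab$participant_id, format(lab$timestamp))
  tkey <- paste(truth$participant_id, format(truth$timestamp))
  truth_state <- truth$true_state[match(key, tkey)]
  expect_true(all(lab$state[truth_state == "sleep"] == "sleep"))
})

test_that("simulated EMA has six prompts a day inside the prompt window", {
  cfg <- sim_config(seed = 41, n_participants = 3)
  ema <- simulate_ema(cfg, n_days = 4)
  expect_equal(nrow(ema), 3 * 4 * 6)
  per_day <- ema |>
    dplyr::mutate(day = as.Date(timestamp)) |>
    dplyr::count(participant_id, day)
  expect_true(all(per_day$n == 6))
  hrs <- lubridate::hour(ema$timestamp) + lubridate::minute(ema$timestamp) / 60
  expect_true(all(hrs >= 8 & hrs <= 20))
  items <- as.matrix(tibble::as_tibble(ema)[, ema_items <- c("happy",
    "energetic", "nervous", "afraid", "irritable", "angry", "pain",
    "discomfort")])
  expect_true(all(items >= 1 & items <= 10))
  expect_true(all(items == round(items)))
  expect_identical(tibble::as_tibble(simulate_ema(cfg, n_days = 4)),
    tibble::as_tibble(ema))
})

test_that("truth tables export as plain CSV", {
  cfg <- sim_config(seed = 50, n_participants = 2, wake_retention = 0.2)
  sim <- simulate_stream(cfg, n_days = 2)
  dir <- withr::local_tempdir()
  write_truth(sim, dir)
  expect_true(file.exists(file.path(dir, "participant_effects.csv")))
  expect_true(file.exists(file.path(dir, "record_components.csv")))
  expect_true(file.exists(file.path(dir, "sleep_blocks.csv")))
  pe <- readr::read_csv(file.path(dir, "participant_effects.csv"),
    show_col_types = FALSE)
  expect_equal(pe$r, sim$truth$participant_effects$r)
})
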