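# Fixture builders: small streams constructed in code at test time.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# A quick stream from vectors; timestamps default to a 5-minute grid.
make_stream <- function(values, participant = "P01", metric = "bpm",
                        device = "dev1", activity = "unlabeled",
                        start = "2024-03-04 08:00:00", step_min = 5) {
  n <- length(values)
  as_sample_stream(tibble::tibble(
    participant_id = participant, device_id = device,
    timestamp = ts_utc(start) + (seq_len(n) - 1) * step_min * 60,
    metric = metric, value = values, activity = activity))
}

# Dense 5-min bpm block [from, to] for one participant.
dense_block <- function(participant, from, to, value = 60, step_min = 5) {
  ts <- seq(ts_utc(from), ts_utc(to), by = step_min * 60)
  tibble::tibble(participant_id = participant, device_id = "dev1",
    timestamp = ts, metric = "bpm", value = value,
    activity = "unlabeled", state = "unlabeled")
}

# Sparse wake samples at given clock instants (kept > max_gap apart from
# each other and from any planted block in the fixtures that use them).
sparse_samples <- function(participant, instants, value = 80,
                           metric = "bpm") {
  tibble::tibble(participant_id = participant, device_id = "dev1",
    timestamp = ts_utc(instants), metric = metric, value = value,
    activity = "unlabeled", state = "unlabeled")
}

# Planted-night fixture: one participant, three study days -
#   day 1: clean night 23:00-07:00 plus sparse daytime samples
#   day 2: night split by a 20-min gap at 03:00 into 4 h and 3 h 40 m runs,
#          plus a 1.5-h daytime decoy block (below the 2-h minimum)
#   day 3: dense block of only 1.5 h (no qualifying run that day)
# Expected intervals are derived by hand from the detection rule.
sleep_fixture <- function() {
  rows <- dplyr::bind_rows(
    dense_block("A", "2024-03-04 23:00:00", "2024-03-05 07:00:00"),
    sparse_samples("A", c("2024-03-04 12:00:00", "2024-03-04 14:00:00",
      "2024-03-04 16:30:00")),
    dense_block("A", "2024-03-05 23:00:00", "2024-03-06 03:00:00"),
    dense_block("A", "2024-03-06 03:20:00", "2024-03-06 07:00:00"),
    sparse_samples("A", c("2024-03-06 13:00:00", "2024-03-06 18:00:00")),
    dense_block("A", "2024-03-07 00:30:00", "2024-03-07 02:00:00")
  )
  expected <- tibble::tibble(
    participant_id = "A",
    study_day = as.Date(c("2024-03-04", "2024-03-05")),
    start = ts_utc(c("2024-03-04 23:00:00", "2024-03-05 23:00:00")),
    end = ts_utc(c("2024-03-05 07:00:00", "2024-03-06 03:00:00")))
  list(stream = as_sample_stream(rows), expected = expected)
}

# Exclusion fixture: participants with 1, 2 and 5 detected sleep periods;
# the 5-period participant has one day with exactly one wakeful rMSSD
# sample and another day with three.
exclusion_fixture <- function() {
  nights <- function(participant, days) {
    dplyr::bind_rows(lapply(days, function(d) {
      dense_block(participant,
        paste0("2024-03-0", d, " 23:00:00"),
        paste0("2024-03-0", d + 1, " 05:00:00"))
    }))
  }
  wake_hrv <- function(participant, day, hours) {
    sparse_samples(participant,
      sprintf("2024-03-0%d %02d:00:00", day, hours),
      value = 45, metric = "rmssd")
  }
  rows <- dplyr::bind_rows(
    nights("one_night", 1),
    nights("two_nights", 1:2),
    nights("five_nights", 1:5),
    wake_hrv("five_nights", 2, 14),          # exactly one wake HRV that day
    wake_hrv("five_nights", 3, c(13, 15, 17)) # three wake HRV that day
  )
  stream <- as_sample_stream(rows)
  intervals <- detect_sleep_periods(stream)
  list(stream = label_state(stream, intervals), intervals = intervals)
}

# Balanced random ICC tables for the oracle-equivalence checks.
random_icc_tables <- function(n_tables, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n_tables), function(i) {
      n <- sample(3:6, 1)
      k <- sample(2:4, 1)
      mu <- runif(1, 40, 100)
      r <- rnorm(n, 0, runif(1, 0.5, 10))
      matrix(mu + rep(r, each = k) + rnorm(n * k, 0, runif(1, 0.5, 8)),
        nrow = n, byrow = TRUE)
    })
  })
}

table_to_df <- function(mat) {
  tibble::tibble(
    participant_id = sprintf("P%02d", rep(seq_len(nrow(mat)), ncol(mat))),
    value = as.vector(mat))
}
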