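#' Remove zero-valued samples
#'
#' Wearable PPG exports flag failed reads as literal zeros (this is
#' especially common for rMSSD). This filter drops every record with
#' `value == 0` and logs, per metric, how many records were removed and
#' what fraction of that metric's records they represented. It is
#' idempotent: applying it twice removes nothing further.
#'
#' @param stream A validated `sample_stream`.
#' @return The filtered `sample_stream` with an updated filter log.
#' @seealso [remove_outlier_samples()], which must be applied *after* this
#'   filter; [filter_log()].
#' @export
remove_zero_samples <- function(stream) {
  counts <- dplyr::count(tibble::as_tibble(stream), .data$metric, name = "total")
  zeros <- dplyr::count(
    dplyr::filter(tibble::as_tibble(stream), .data$value == 0),
    .data$metric, name = "removed")
  log_rows <- dplyr::left_join(counts, zeros, by = "metric")
  log_rows$removed <- ifelse(is.na(log_rows$removed), 0L, log_rows$removed)
  log_rows <- tibble::tibble(
    rule = "zero_filter",
    metric = log_rows$metric,
    removed = as.integer(log_rows$removed),
    fraction = ifelse(log_rows$total == 0, 0, log_rows$removed / log_rows$total)
  )
  all_zero <- log_rows$metric[log_rows$fraction == 1 & log_rows$removed > 0]
  if (length(all_zero) > 0) {
    warn(paste0("all samples removed by the zero filter for metric(s): ",
      paste(all_zero, collapse = ", ")))
  }
  kept <- dplyr::filter(tibble::as_tibble(stream), .data$value != 0)
  restream(kept, stream,
    filter_log = dplyr::bind_rows(filter_log(stream), log_rows))
}

#' Remove outlier samples beyond an SD threshold
#'
#' For each participant and metric, computes the mean and sample standard
#' deviation (divisor n - 1) once over that participant's whole retained
#' series, then removes records whose value lies strictly more than
#' `n_sd` standard deviations above or below the mean. The statistics are
#' never recomputed after removal: the filter is a single pass by design,
#' and the pipeline applies it exactly once (iterating it would remove
#' progressively more data).
#'
#' Apply [remove_zero_samples()] first; zeros would otherwise drag the
#' mean down and inflate the SD.
#'
#' @param stream A `sample_stream`, already zero-filtered.
#' @param n_sd Threshold in standard deviations (default 2).
#' @return The filtered `sample_stream` with an updated filter log.
#' @export
remove_outlier_samples <- function(stream, n_sd = 2) {
  stopifnot(is.numeric(n_sd), length(n_sd) == 1, n_sd > 0)
  df <- tibble::as_tibble(stream)
  df$.row <- seq_len(nrow(df))
  stats <- df |>
    dplyr::group_by(.data$participant_id, .data$metric) |>
    dplyr::summarise(
      .n = dplyr::n(), .mean = mean(.data$value), .sd = sd(.data$value),
      .groups = "drop")
  small <- stats[stats$.n < 3, ]
  if (nrow(small) > 0) {
    warn(sprintf(
      "outlier filter skipped %d participant-metric series with < 3 samples (SD unstable): %s",
      nrow(small),
      paste(head(paste(small$participant_id, small$metric, sep = "/"), 5),
        collapse = ", ")))
  }
  df <- dplyr::left_join(df, stats, by = c("participant_id", "metric"))
  drop <- df$.n >= 3 & !is.na(df$.sd) & df$.sd > 0 &
    abs(df$value - df$.mean) > n_sd * df$.sd
  totals <- dplyr::count(df, .data$metric, name = "total")
  removed <- df[drop, ] |> dplyr::count(.data$metric, name = "removed")
  log_rows <- dplyr::left_join(totals, removed, by = "metric")
  log_rows$removed <- ifelse(is.na(log_rows$removed), 0L, log_rows$removed)
  log_rows <- tibble::tibble(
    rule = "outlier_filter",
    metric = log_rows$metric,
    removed = as.integer(log_rows$removed),
    fraction = ifelse(log_rows$total == 0, 0, log_rows$removed / log_rows$total)
  )
  kept <- df[!drop, c("participant_id", "device_id", "timestamp", "metric",
    "value", "activity", "state")]
  restream(kept, stream,
    filter_log = dplyr::bind_rows(filter_log(stream), log_rows))
}

#' Study-day label for timestamps
#'
#' Assigns each instant to a noon-to-noon local-time window, so an
#' overnight sleep period crossing midnight belongs to a single study day
#' (the day on which the night began). A sample at 02:00 on Jan 2 gets
#' study day Jan 1.
#'
#' @param timestamp POSIXct vector.
#' @param tz Time zone in which "noon" is taken (default `"UTC"`).
#' @return A `Date` vector of study-day labels.
#' @export
study_day <- function(timestamp, tz = "UTC") {
  local <- lubridate::with_tz(timestamp, tz)
  as.Date(local - lubridate::dhours(12), tz = tz)
}

#' Per-participant, per-condition means
#'
#' Averages a filtered stream into the participant-by-condition table of
#' cell means that feeds the one-way ICC: one arithmetic mean per
#' (participant, condition) cell, with empty cells marked missing. The
#' condition is chosen by `condition_key`: the activity label, the device
#' id, the sleep/wake state, or the study day.
#'
#' One metric at a time: filter the stream to a single metric first (the
#' function errors on mixed metrics so BPM and rMSSD are never pooled).
#'
#' @param stream A filtered `sample_stream` containing a single metric.
#' @param condition_key One of `"activity"`, `"device"`, `"state"`,
#'   `"day"`.
#' @param tz Time zone used when `condition_key = "day"` (noon-to-noon
#'   study days).
#' @return A tibble of class `condition_means` with columns
#'   `participant_id`, `condition`, `mean`, `n`, one row per cell of the
#'   full participant x condition grid (`mean` is `NA` iff `n` is 0).
#' @export
condition_means <- function(stream,
                            condition_key = c("activity", "device", "state", "day"),
                            tz = "UTC") {
  condition_key <- match.arg(condition_key)
  df <- tibble::as_tibble(stream)
  if (nrow(df) == 0) {
    abort("empty stream", class = "reliwear_data_error")
  }
  if (dplyr::n_distinct(df$metric) > 1) {
    abort(paste0("stream contains multiple metrics (",
      paste(sort(unique(df$metric)), collapse = ", "),
      "); filter to one metric before averaging"),
      class = "reliwear_data_error")
  }
  cond <- switch(condition_key,
    activity = df$activity,
    device = df$device_id,
    state = ifelse(df$state == "unlabeled", NA_character_, df$state),
    day = as.character(study_day(df$timestamp, tz = tz))
  )
  if (condition_key == "activity") {
    cond <- ifelse(cond == "unlabeled", NA_character_, cond)
  }
  if (anyNA(cond)) {
    i <- which(is.na(cond))[1]
    abort(sprintf(
      "condition key '%s' is not populated on all records (first offender: row %d, participant %s, %s)",
      condition_key, i, df$participant_id[i], format_iso8601(df$timestamp[i])),
      class = "reliwear_data_error")
  }
  df$condition <- cond
  out <- df |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(.data$participant_id, .data$condition,
      fill = list(n = 0L)) |>
    dplyr::arrange(.data$participant_id, .data$condition)
  out$n <- as.integer(out$n)
  structure(out,
    class = c("condition_means", class(tibble::tibble())),
    condition_key = condition_key,
    metric = df$metric[1])
}

#' Widen a condition-means table to a participant x condition matrix
#'
#' @param x A `condition_means` tibble.
#' @return A numeric matrix with participants as rows and conditions as
#'   columns; empty cells are `NA`.
#' @export
condition_matrix <- function(x) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x)[c("participant_id", "condition", "mean")],
    names_from = "condition", values_from = "mean")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$participant_id
  m
}

#' Export the filter log as CSV
#'
#' @param stream A `sample_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(stream, path) {
  readr::write_csv(filter_log(stream), path)
  invisible(path)
}
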