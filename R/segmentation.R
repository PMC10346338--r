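#' Detect nightly sleep periods from BPM sampling density
#'
#' Wrist PPG sensors record far more densely during sleep (little motion,
#' good optical contact) than during active wear. Sleep periods are
#' therefore recoverable from the heart-rate sampling pattern alone: a
#' sleep period is a maximal run of consecutive BPM samples whose
#' inter-sample gaps are all at most `max_gap` and whose span (last minus
#' first timestamp) is at least `min_duration`. Per participant and study
#' day (noon-to-noon, see [study_day()]), the longest qualifying run is
#' returned; on a tie the earliest run wins. Days with no qualifying run
#' contribute nothing.
#'
#' Only `bpm` records drive detection; rMSSD density is too sparse and
#' artifact-ridden to define runs.
#'
#' @param stream A `sample_stream` containing bpm records.
#' @param min_duration Minimum span of a qualifying run (default 2 hours;
#'   a lubridate duration or number of seconds).
#' @param max_gap Maximum allowed gap between consecutive samples in a run
#'   (default 15 minutes).
#' @param tz Time zone for the noon-to-noon study-day windows.
#' @return A tibble of class `sleep_intervals` with columns
#'   `participant_id`, `study_day`, `start`, `end`, `n_samples`; at most
#'   one row per (participant, study day), intervals never overlapping.
#' @export
detect_sleep_periods <- function(stream,
                                 min_duration = lubridate::dhours(2),
                                 max_gap = lubridate::dminutes(15),
                                 tz = "UTC") {
  min_duration <- as.numeric(min_duration)
  max_gap <- as.numeric(max_gap)
  stopifnot(min_duration > 0, max_gap > 0)
  df <- tibble::as_tibble(stream)
  df <- df[df$metric == "bpm", ]
  out <- df |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      ts <- sort(unique(d$timestamp))
      if (length(ts) == 0) {
        return(tibble::tibble(study_day = as.Date(character()),
          start = as.POSIXct(character(), tz = "UTC"),
          end = as.POSIXct(character(), tz = "UTC"),
          n_samples = integer()))
      }
      gaps <- as.numeric(difftime(ts[-1], ts[-length(ts)], units = "secs"))
      run_id <- cumsum(c(0, gaps > max_gap))
      runs <- tibble::tibble(ts = ts, run_id = run_id) |>
        dplyr::group_by(.data$run_id) |>
        dplyr::summarise(start = min(.data$ts), end = max(.data$ts),
          n_samples = dplyr::n(), .groups = "drop")
      runs$span <- as.numeric(difftime(runs$end, runs$start, units = "secs"))
      runs <- runs[runs$span >= min_duration, ]
      if (nrow(runs) == 0) {
        return(tibble::tibble(study_day = as.Date(character()),
          start = as.POSIXct(character(), tz = "UTC"),
          end = as.POSIXct(character(), tz = "UTC"),
          n_samples = integer()))
      }
      runs$study_day <- study_day(runs$start, tz = tz)
      runs |>
        dplyr::arrange(.data$study_day, dplyr::desc(.data$span), .data$start) |>
        dplyr::distinct(.data$study_day, .keep_all = TRUE) |>
        dplyr::select("study_day", "start", "end", "n_samples")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$participant_id, .data$study_day)
  out$n_samples <- as.integer(out$n_samples)
  structure(out,
    class = c("sleep_intervals", class(tibble::tibble())),
    min_duration = min_duration, max_gap = max_gap, tz = tz)
}

check_intervals <- function(intervals) {
  bad <- intervals |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      overlap = dplyr::n() > 1 && any(.data$start[-1] < .data$end[-dplyr::n()]),
      .groups = "drop")
  if (any(bad$overlap)) {
    abort(paste0("overlapping sleep intervals for participant(s): ",
      paste(bad$participant_id[bad$overlap], collapse = ", ")),
      class = "reliwear_invariant_error")
  }
  invisible(intervals)
}

#' Label records as sleep or wake from detected intervals
#'
#' Records whose timestamp falls inside any of the participant's sleep
#' intervals (closed on both ends: the samples that define a run belong to
#' it) get `state = "sleep"`; every other record gets `state = "wake"`.
#'
#' @param stream A `sample_stream`.
#' @param intervals A `sleep_intervals` tibble from
#'   [detect_sleep_periods()].
#' @return The stream with its `state` column filled in.
#' @export
label_state <- function(stream, intervals) {
  check_intervals(intervals)
  df <- tibble::as_tibble(stream)
  df$state <- "wake"
  by_part <- split(seq_len(nrow(intervals)), intervals$participant_id)
  for (pid in names(by_part)) {
    iv <- intervals[by_part[[pid]], ]
    iv <- iv[order(iv$start), ]
    rows <- which(df$participant_id == pid)
    if (length(rows) == 0) next
    t <- df$timestamp[rows]
    idx <- findInterval(as.numeric(t), as.numeric(iv$start))
    inside <- idx >= 1 & as.numeric(t) <= as.numeric(iv$end)[pmax(idx, 1)]
    df$state[rows[inside]] <- "sleep"
  }
  restream(df, stream)
}

#' Apply study-level exclusion rules
#'
#' Two exclusion rules guard downstream reliability estimates:
#' participants with fewer than `min_sleep_periods` detected sleep periods
#' are dropped entirely (their sleep/wake partition is too unreliable to
#' use), and participant-days with fewer than `min_wake_hrv_per_day`
#' wakeful rMSSD samples have those wake rMSSD records dropped (a single
#' sample cannot be split-half assessed).
#'
#' @param stream A labelled `sample_stream` (see [label_state()]).
#' @param intervals The `sleep_intervals` used for labelling.
#' @param min_sleep_periods Minimum detected sleep periods to retain a
#'   participant (default 3).
#' @param min_wake_hrv_per_day Minimum wakeful rMSSD samples to retain a
#'   participant-day's wake rMSSD (default 2).
#' @param tz Time zone for study-day labels.
#' @return A list with elements `stream` (the pruned `sample_stream`) and
#'   `exclusions` (a tibble `participant_id`, `study_day`, `rule`,
#'   `n_removed` listing every exclusion).
#' @export
apply_study_exclusions <- function(stream, intervals,
                                   min_sleep_periods = 3,
                                   min_wake_hrv_per_day = 2,
                                   tz = "UTC") {
  df <- tibble::as_tibble(stream)
  exclusions <- list()

  per_part <- dplyr::count(tibble::as_tibble(intervals), .data$participant_id)
  all_parts <- unique(df$participant_id)
  counts <- setNames(rep(0L, length(all_parts)), all_parts)
  counts[per_part$participant_id] <- per_part$n
  dropped_parts <- names(counts)[counts < min_sleep_periods]
  for (pid in dropped_parts) {
    exclusions[[length(exclusions) + 1]] <- tibble::tibble(
      participant_id = pid, study_day = as.Date(NA),
      rule = "insufficient_sleep_periods",
      n_removed = sum(df$participant_id == pid))
  }
  df <- df[!df$participant_id %in% dropped_parts, ]

  if (nrow(df) > 0) {
    df$.study_day <- study_day(df$timestamp, tz = tz)
    wake_hrv <- df |>
      dplyr::filter(.data$metric == "rmssd", .data$state == "wake") |>
      dplyr::count(.data$participant_id, .data$.study_day)
    thin <- wake_hrv[wake_hrv$n < min_wake_hrv_per_day, ]
    if (nrow(thin) > 0) {
      for (i in seq_len(nrow(thin))) {
        exclusions[[length(exclusions) + 1]] <- tibble::tibble(
          participant_id = thin$participant_id[i],
          study_day = thin$.study_day[i],
          rule = "insufficient_wake_hrv",
          n_removed = thin$n[i])
      }
      drop <- df$metric == "rmssd" & df$state == "wake" &
        paste(df$participant_id, df$.study_day) %in%
          paste(thin$participant_id, thin$.study_day)
      df <- df[!drop, ]
    }
    df$.study_day <- NULL
  }

  exclusions <- if (length(exclusions) == 0) {
    tibble::tibble(participant_id = character(), study_day = as.Date(character()),
      rule = character(), n_removed = integer())
  } else {
    dplyr::bind_rows(exclusions)
  }
  exclusions$n_removed <- as.integer(exclusions$n_removed)
  list(stream = restream(df, stream), exclusions = exclusions)
}

#' Write sleep intervals as a BED-like tab-separated table
#'
#' @param intervals A `sleep_intervals` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  out <- tibble::as_tibble(intervals)
  out$start <- format_iso8601(out$start)
  out$end <- format_iso8601(out$end)
  readr::write_tsv(out, path)
  invisible(path)
}
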