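#' Construct a sample stream
#'
#' A sample stream is the universal input of the package: a tibble of
#' timestamped biometric records from one or more participants and devices.
#' Each record carries a participant id, a device id, an absolute timestamp,
#' a metric name (`"bpm"` for heart rate in beats per minute, `"rmssd"` for
#' heart-rate variability in milliseconds), a non-negative value, and
#' optional `activity` and `state` labels. Records are kept sorted by
#' (participant, metric, timestamp) so that acquisition order is always
#' well defined.
#'
#' Missing `activity`/`state` labels are stored as the explicit value
#' `"unlabeled"`, never as `NA` or the empty string, so grouping keys are
#' unambiguous.
#'
#' @param x A data frame with columns `participant_id`, `device_id`,
#'   `timestamp` (POSIXct), `metric`, `value`, and optionally `activity`
#'   and `state`.
#' @param provenance Free-text note recording where the records came from.
#' @param filter_log A tibble with columns `rule`, `metric`, `removed`,
#'   `fraction` accumulating the record counts removed by cleaning rules.
#' @return A `sample_stream`: a tibble with the columns above, sorted, with
#'   `provenance` and `filter_log` attributes.
#' @examples
#' s <- as_sample_stream(tibble::tibble(
#'   participant_id = "P01", device_id = "d1",
#'   timestamp = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
#'   metric = "bpm", value = 72
#' ))
#' s
#' @export
as_sample_stream <- function(x, provenance = "", filter_log = NULL) {
  required <- c("participant_id", "device_id", "timestamp", "metric", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "sample stream is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "reliwear_schema_error")
  }
  x <- tibble::as_tibble(x)
  if (!inherits(x$timestamp, "POSIXct")) {
    abort("`timestamp` must be POSIXct; parse with read_samples() or lubridate",
      class = "reliwear_schema_error")
  }
  bad_metric <- setdiff(unique(x$metric), .metrics)
  if (length(bad_metric) > 0) {
    abort(paste0(
      "unknown metric(s): ", paste(bad_metric, collapse = ", "),
      " (supported: ", paste(.metrics, collapse = ", "), ")"
    ), class = "reliwear_metric_error")
  }
  if (!is.numeric(x$value)) {
    abort("`value` must be numeric", class = "reliwear_schema_error")
  }
  x$participant_id <- as.character(x$participant_id)
  x$device_id <- as.character(x$device_id)
  x$metric <- as.character(x$metric)
  x$value <- as.double(x$value)
  if (!"activity" %in% names(x)) x$activity <- "unlabeled"
  if (!"state" %in% names(x)) x$state <- "unlabeled"
  x$activity <- ifelse(is.na(x$activity) | x$activity == "", "unlabeled",
    as.character(x$activity))
  x$state <- ifelse(is.na(x$state) | x$state == "", "unlabeled",
    as.character(x$state))
  x <- x[c("participant_id", "device_id", "timestamp", "metric", "value",
    "activity", "state")]
  x <- dplyr::arrange(x, .data$participant_id, .data$metric, .data$timestamp,
    .data$device_id)
  new_sample_stream(x, provenance = provenance, filter_log = filter_log)
}

new_sample_stream <- function(x, provenance = "", filter_log = NULL) {
  filter_log <- filter_log %||% empty_filter_log()
  structure(x,
    class = c("sample_stream", class(tibble::tibble())),
    provenance = provenance,
    filter_log = filter_log
  )
}

empty_filter_log <- function() {
  tibble::tibble(rule = character(), metric = character(),
    removed = integer(), fraction = double())
}

#' Stream metadata accessors
#'
#' `filter_log()` returns the tibble of cleaning-rule removals accumulated
#' on a stream; `provenance()` returns its free-text source note.
#'
#' @param stream A `sample_stream`.
#' @return A tibble (`filter_log`) or a character scalar (`provenance`).
#' @export
filter_log <- function(stream) {
  attr(stream, "filter_log") %||% empty_filter_log()
}

#' @rdname filter_log
#' @export
provenance <- function(stream) {
  attr(stream, "provenance") %||% ""
}

# rebuild a sample_stream after dplyr verbs stripped its attributes
restream <- function(x, template, filter_log = NULL) {
  new_sample_stream(tibble::as_tibble(x),
    provenance = provenance(template),
    filter_log = filter_log %||% filter_log(template))
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf("# A sample stream: %d records, %d participant(s), metrics: %s\n",
    nrow(x), dplyr::n_distinct(x$participant_id),
    paste(sort(unique(x$metric)), collapse = ", ")))
  fl <- filter_log(x)
  if (nrow(fl) > 0) {
    cat(sprintf("# Filter log: %d rule application(s), %d record(s) removed\n",
      nrow(fl), sum(fl$removed)))
  }
  NextMethod()
}

# strict ISO 8601 with explicit UTC offset (Z or +-hh:mm); naive rejected
.iso8601_re <- paste0(
  "^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?",
  "(Z|[+-]\\d{2}:?\\d{2})$"
)

parse_iso8601_strict <- function(x, where = "timestamp") {
  ok <- grepl(.iso8601_re, x)
  if (!all(ok)) {
    bad <- which(!ok)
    abort(sprintf(
      "%s not valid ISO 8601 with explicit UTC offset in row(s) %s (e.g. '%s'); naive timestamps are rejected because downstream sleep-window logic depends on local clock time",
      where, paste(head(bad, 5), collapse = ", "), x[bad[1]]
    ), class = "reliwear_parse_error")
  }
  out <- lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
  if (anyNA(out)) {
    bad <- which(is.na(out))
    abort(sprintf("unparseable %s in row(s) %s", where,
      paste(head(bad, 5), collapse = ", ")), class = "reliwear_parse_error")
  }
  out
}

format_iso8601 <- function(x) {
  format(lubridate::with_tz(x, "UTC"), "%Y-%m-%dT%H:%M:%S+00:00")
}

#' Read a biometric samples CSV
#'
#' Reads a CSV of timestamped biometric samples into a validated
#' [sample stream][as_sample_stream]. The expected columns are
#' `participant_id`, `device_id`, `timestamp`, `metric`, `value`, and
#' optionally `activity` and `state`; a `schema` mapping can rename
#' differently-labelled columns on the way in. Timestamps must be ISO 8601
#' with an explicit UTC offset (`2024-01-01T08:00:00+00:00` or `...Z`);
#' naive timestamps are rejected.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(participant_id = "subject", value = "hr")`.
#' @return A validated, sorted `sample_stream`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' s <- as_sample_stream(tibble::tibble(
#'   participant_id = "P01", device_id = "d1",
#'   timestamp = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
#'   metric = "bpm", value = 72
#' ))
#' write_samples(s, path)
#' read_samples(path)
#' @export
read_samples <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "reliwear_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        abort(sprintf("schema column '%s' (for '%s') not found in %s",
          src, canonical, path), class = "reliwear_schema_error")
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  required <- c("participant_id", "device_id", "timestamp", "metric", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s", path,
      paste(missing_cols, collapse = ", ")), class = "reliwear_schema_error")
  }
  if (nrow(raw) > 0) {
    raw$timestamp <- parse_iso8601_strict(raw$timestamp)
    val <- suppressWarnings(as.double(raw$value))
    if (anyNA(val)) {
      bad <- which(is.na(val))
      abort(sprintf("non-numeric value in row(s) %s of %s",
        paste(head(bad, 5), collapse = ", "), path),
        class = "reliwear_parse_error")
    }
    raw$value <- val
  } else {
    raw$timestamp <- as.POSIXct(character(), tz = "UTC")
    raw$value <- double()
  }
  stream <- as_sample_stream(raw, provenance = path)
  report <- validate_stream(stream)
  if (nrow(report) > 0) {
    abort(paste0("invalid stream in ", path, ":\n  ",
      paste(head(report$message, 5), collapse = "\n  ")),
      class = "reliwear_validation_error")
  }
  stream
}

#' Write a sample stream to CSV
#'
#' Writes the stream with a header row, ISO 8601 timestamps carrying an
#' explicit `+00:00` offset, and a stable column order, so that
#' `read_samples(write_samples(s, path))` reproduces `s` field by field.
#'
#' @param stream A `sample_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(stream, path) {
  out <- tibble::as_tibble(stream)
  out$timestamp <- format_iso8601(out$timestamp)
  readr::write_csv(out, path)
  invisible(path)
}

#' Validate a sample stream
#'
#' Checks every record-level and stream-level invariant (finite
#' non-negative values, known metric names, unique
#' (participant, device, metric, timestamp) keys, sorted order, known state
#' labels, filter-log fractions in \[0, 1\]) and reports violations without
#' throwing. A clean stream yields a zero-row report.
#'
#' @param stream A `sample_stream` (or plain data frame with its columns).
#' @return A tibble with columns `rule`, `row`, `message`; one row per
#'   violation.
#' @export
validate_stream <- function(stream) {
  report <- list()
  add <- function(rule, row, message) {
    report[[length(report) + 1]] <<- tibble::tibble(
      rule = rule, row = as.integer(row), message = message)
  }
  if (nrow(stream) > 0) {
    bad <- which(!is.finite(stream$value) | stream$value < 0)
    for (i in bad) {
      add("nonnegative_value", i,
        sprintf("row %d: value %s is not finite and >= 0", i, stream$value[i]))
    }
    bad <- which(!stream$metric %in% .metrics)
    for (i in bad) {
      add("known_metric", i,
        sprintf("row %d: unknown metric '%s'", i, stream$metric[i]))
    }
    bad <- which(!stream$state %in% .states)
    for (i in bad) {
      add("known_state", i,
        sprintf("row %d: unknown state '%s'", i, stream$state[i]))
    }
    key <- paste(stream$participant_id, stream$device_id, stream$metric,
      format_iso8601(stream$timestamp), sep = "|")
    dup <- which(duplicated(key))
    for (i in dup) {
      add("unique_key", i,
        sprintf("row %d: duplicate (participant, device, metric, timestamp) key %s",
          i, key[i]))
    }
    ord <- order(stream$participant_id, stream$metric, stream$timestamp)
    if (!identical(ord, seq_len(nrow(stream)))) {
      add("sorted", NA_integer_,
        "records are not sorted by (participant_id, metric, timestamp)")
    }
  }
  fl <- filter_log(stream)
  bad <- which(fl$fraction < 0 | fl$fraction > 1)
  for (i in bad) {
    add("filter_log_fraction", NA_integer_,
      sprintf("filter_log row %d: fraction %s outside [0, 1]", i, fl$fraction[i]))
  }
  if (length(report) == 0) {
    tibble::tibble(rule = character(), row = integer(), message = character())
  } else {
    dplyr::bind_rows(report)
  }
}

#' Read an EMA (ecological momentary assessment) prompts CSV
#'
#' Each row is one prompt response: a participant id, a timestamp, and
#' eight 1-10 integer ratings named `happy`, `energetic`, `nervous`,
#' `afraid`, `irritable`, `angry`, `pain`, `discomfort`. Missing ratings
#' are allowed (empty cells); non-missing ratings must be integers in
#' \[1, 10\].
#'
#' @param path Path to the EMA CSV.
#' @return A tibble of class `ema_records`.
#' @export
read_ema <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "reliwear_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  required <- c("participant_id", "timestamp", ema_items())
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s", path,
      paste(missing_cols, collapse = ", ")), class = "reliwear_schema_error")
  }
  if (nrow(raw) > 0) {
    raw$timestamp <- parse_iso8601_strict(raw$timestamp)
  } else {
    raw$timestamp <- as.POSIXct(character(), tz = "UTC")
  }
  for (item in ema_items()) {
    v <- suppressWarnings(as.double(raw[[item]]))
    present <- !is.na(raw[[item]]) & raw[[item]] != ""
    bad <- which(present & (is.na(v) | v != round(v) | v < 1 | v > 10))
    if (length(bad) > 0) {
      abort(sprintf("item '%s' has non-integer or out-of-range rating in row(s) %s of %s",
        item, paste(head(bad, 5), collapse = ", "), path),
        class = "reliwear_parse_error")
    }
    raw[[item]] <- as.integer(v)
  }
  raw$participant_id <- as.character(raw$participant_id)
  out <- tibble::as_tibble(raw[required])
  class(out) <- c("ema_records", class(out))
  out
}

#' Write EMA records to CSV
#'
#' @param ema An `ema_records` tibble (see [read_ema()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ema <- function(ema, path) {
  out <- tibble::as_tibble(ema)
  out$timestamp <- format_iso8601(out$timestamp)
  readr::write_csv(out, path)
  invisible(path)
}

ema_items <- function() {
  c("happy", "energetic", "nervous", "afraid", "irritable", "angry",
    "pain", "discomfort")
}

ema_negative_items <- function() c("irritable", "afraid", "nervous", "angry")
ema_positive_items <- function() c("happy", "energetic")
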