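#' Assemble a full-pipeline run configuration
#'
#' Bundles every stage's settings with the defaults of the underlying
#' functions (2 SD outlier threshold, 2 h / 15 min sleep detection, 3
#' minimum sleep periods, 1000 random-split iterations, 95% confidence,
#' Bonferroni family of 6). All preconditions of downstream stages are
#' checkable from the config before any computation starts.
#'
#' @param samples Path to the samples CSV (or a `sample_stream`).
#' @param ema Optional path to an EMA CSV (or an `ema_records` tibble).
#' @param out_dir Output directory for the report bundle.
#' @param n_sd Outlier threshold in SDs.
#' @param zero_filter Apply the zero filter?
#' @param min_duration,max_gap Sleep-detection settings (seconds or
#'   lubridate durations).
#' @param min_sleep_periods,min_wake_hrv_per_day Exclusion-rule settings.
#' @param split_method `"time_sensitive"`, `"random"`, or `"both"`.
#' @param n_iterations Random-split iterations.
#' @param master_seed Master seed for every random stage.
#' @param unit_key Split-half unit columns (see
#'   [split_time_sensitive()]).
#' @param random_factors Random intercepts for the split-half model.
#' @param icc_form `"single"` or `"average"`.
#' @param confidence Confidence level for ICC intervals.
#' @param tz Time zone for study days and sleep windows.
#' @return A list of class `run_config`.
#' @export
run_config <- function(samples, ema = NULL, out_dir = "reliwear-report",
                       n_sd = 2, zero_filter = TRUE,
                       min_duration = lubridate::dhours(2),
                       max_gap = lubridate::dminutes(15),
                       min_sleep_periods = 3, min_wake_hrv_per_day = 2,
                       split_method = c("both", "time_sensitive", "random"),
                       n_iterations = 1000, master_seed = 1L,
                       unit_key = c("study_day", "state"),
                       random_factors = "participant_id",
                       icc_form = c("single", "average"),
                       confidence = 0.95, tz = "UTC") {
  split_method <- match.arg(split_method)
  icc_form <- match.arg(icc_form)
  stopifnot(n_sd > 0, n_iterations >= 1, confidence > 0, confidence < 1,
    min_sleep_periods >= 1, min_wake_hrv_per_day >= 1)
  structure(list(
    samples = samples, ema = ema, out_dir = out_dir,
    n_sd = n_sd, zero_filter = zero_filter,
    min_duration = as.numeric(min_duration), max_gap = as.numeric(max_gap),
    min_sleep_periods = min_sleep_periods,
    min_wake_hrv_per_day = min_wake_hrv_per_day,
    split_method = split_method, n_iterations = n_iterations,
    master_seed = as.integer(master_seed), unit_key = unit_key,
    random_factors = random_factors, icc_form = icc_form,
    confidence = confidence, tz = tz
  ), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      class = "reliwear_stage_error")
  })
}

log_stage <- function(name, stream) {
  message(sprintf("[%s] %d records, %d participant(s)", name, nrow(stream),
    dplyr::n_distinct(stream$participant_id)))
}

#' Run the full reliability pipeline and write a report bundle
#'
#' Executes clean (zero filter, outlier filter), segment (sleep detection,
#' state labelling, exclusions), between-person reliability (ICC per
#' metric and state, with days as measurement instances), within-person
#' reliability (time-sensitive and/or random split-half per metric and
#' state), and — when EMA data are supplied — the six lagged affect
#' models. Writes tidy CSV tables plus filter/exclusion logs and a
#' plain-text manifest recording the configuration and seeds; identical
#' config and seed yield byte-identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the tables written (`between`, `within`,
#'   `intervals`, `exclusions`, `filter_log`, and `ema` when computed).
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stream <- stage("read", {
    if (inherits(config$samples, "sample_stream")) config$samples
    else read_samples(config$samples)
  })
  log_stage("read", stream)

  if (config$zero_filter) {
    stream <- stage("zero_filter", remove_zero_samples(stream))
    log_stage("zero_filter", stream)
  }
  stream <- stage("outlier_filter",
    suppressWarnings(remove_outlier_samples(stream, n_sd = config$n_sd)))
  log_stage("outlier_filter", stream)

  intervals <- stage("segment", detect_sleep_periods(stream,
    min_duration = config$min_duration, max_gap = config$max_gap,
    tz = config$tz))
  stream <- stage("label", label_state(stream, intervals))
  excl <- stage("exclusions", apply_study_exclusions(stream, intervals,
    min_sleep_periods = config$min_sleep_periods,
    min_wake_hrv_per_day = config$min_wake_hrv_per_day, tz = config$tz))
  stream <- excl$stream
  log_stage("exclusions", stream)

  between <- stage("between_reliability", {
    purrr::map_dfr(c("sleep", "wake"), function(st) {
      sub <- restream(
        dplyr::filter(tibble::as_tibble(stream), .data$state == st), stream)
      purrr::map_dfr(sort(unique(sub$metric)), function(m) {
        msub <- restream(
          dplyr::filter(tibble::as_tibble(sub), .data$metric == m), stream)
        res <- tryCatch({
          cm <- condition_means(msub, condition_key = "day", tz = config$tz)
          dec <- decompose_oneway(cm)
          r <- if (config$icc_form == "single")
            icc_single(dec, config$confidence)
          else icc_average(dec, config$confidence)
          dplyr::bind_cols(tibble::tibble(label = paste(m, st)), tidy(r))
        }, error = function(e) NULL)
        res %||% tibble::tibble()
      })
    })
  })

  within <- stage("within_reliability", {
    purrr::map_dfr(c("sleep", "wake"), function(st) {
      sub <- restream(
        dplyr::filter(tibble::as_tibble(stream), .data$state == st), stream)
      purrr::map_dfr(sort(unique(sub$metric)), function(m) {
        msub <- restream(
          dplyr::filter(tibble::as_tibble(sub), .data$metric == m), stream)
        rows <- tibble::tibble()
        if (config$split_method %in% c("both", "time_sensitive")) {
          ts_row <- tryCatch({
            pairs <- split_time_sensitive(msub, unit_key = config$unit_key,
              tz = config$tz)
            fit <- fit_split_model(pairs,
              random_factors = config$random_factors)
            dplyr::bind_cols(
              tibble::tibble(label = paste(m, st), method = "time_sensitive"),
              tidy(fit))
          }, error = function(e) NULL)
          if (!is.null(ts_row)) rows <- dplyr::bind_rows(rows, ts_row)
        }
        if (config$split_method %in% c("both", "random")) {
          rnd_row <- tryCatch({
            d <- random_split_distribution(msub, unit_key = config$unit_key,
              random_factors = config$random_factors,
              n_iterations = config$n_iterations,
              master_seed = config$master_seed, tz = config$tz)
            tibble::tibble(label = paste(m, st), method = "random",
              mean_beta = d$mean_beta, sd_beta = d$sd_beta,
              n_iterations = d$n_iterations, n_failed = d$n_failed)
          }, error = function(e) NULL)
          if (!is.null(rnd_row)) rows <- dplyr::bind_rows(rows, rnd_row)
        }
        rows
      })
    })
  })

  tables <- list(between = between, within = within,
    intervals = tibble::as_tibble(intervals),
    exclusions = excl$exclusions, filter_log = filter_log(stream))

  if (!is.null(config$ema)) {
    tables$ema <- stage("ema", {
      ema <- if (inherits(config$ema, "ema_records")) config$ema
        else read_ema(config$ema)
      affect <- daily_affect(score_prompts(ema), tz = config$tz)
      bio <- daily_biometrics(stream, tz = config$tz)
      tibble::as_tibble(fit_lagged_models(affect, bio))
    })
  }

  readr::write_csv(tables$between, file.path(config$out_dir, "between_reliability.csv"))
  readr::write_csv(tables$within, file.path(config$out_dir, "within_reliability.csv"))
  write_intervals(intervals, file.path(config$out_dir, "sleep_intervals.tsv"))
  readr::write_csv(tables$exclusions, file.path(config$out_dir, "exclusions.csv"))
  readr::write_csv(tables$filter_log, file.path(config$out_dir, "filter_log.csv"))
  if (!is.null(tables$ema)) {
    readr::write_csv(tables$ema, file.path(config$out_dir, "ema_associations.csv"))
  }

  manifest <- config
  manifest$samples <- if (is.character(config$samples)) config$samples
    else "<in-memory stream>"
  manifest$ema <- if (is.null(config$ema)) NULL
    else if (is.character(config$ema)) config$ema else "<in-memory records>"
  writeLines(yaml::as.yaml(list(
    package = "reliwear",
    version = as.character(utils::packageVersion("reliwear")),
    config = unclass(manifest))),
    file.path(config$out_dir, "manifest.yaml"))

  invisible(tables)
}

#' Clean, segment and label a stream in one step
#'
#' The standard front half of the pipeline: zero filter, 2-SD outlier
#' filter, sleep detection from BPM density, sleep/wake labelling, and
#' the participant/day exclusion rules.
#'
#' @param stream A raw `sample_stream`.
#' @inheritParams run_config
#' @return A list: `stream` (cleaned, labelled, pruned), `intervals`,
#'   `exclusions`.
#' @export
prepare_stream <- function(stream, n_sd = 2, zero_filter = TRUE,
                           min_duration = lubridate::dhours(2),
                           max_gap = lubridate::dminutes(15),
                           min_sleep_periods = 3,
                           min_wake_hrv_per_day = 2, tz = "UTC") {
  if (zero_filter) stream <- remove_zero_samples(stream)
  stream <- suppressWarnings(remove_outlier_samples(stream, n_sd = n_sd))
  intervals <- detect_sleep_periods(stream, min_duration = min_duration,
    max_gap = max_gap, tz = tz)
  stream <- label_state(stream, intervals)
  excl <- apply_study_exclusions(stream, intervals,
    min_sleep_periods = min_sleep_periods,
    min_wake_hrv_per_day = min_wake_hrv_per_day, tz = tz)
  list(stream = excl$stream, intervals = intervals,
    exclusions = excl$exclusions)
}

state_metric_stream <- function(stream, st, m) {
  restream(dplyr::filter(tibble::as_tibble(stream),
    .data$state == st, .data$metric == m), stream)
}
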