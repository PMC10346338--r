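#' Simulation configuration
#'
#' Parameters of the variance-components generator. Values are drawn from
#' the additive model
#' \deqn{x_{ijk} = \mu + r_i + s_j + v_{ijk},}
#' with participant effects \eqn{r_i \sim N(0, \sigma_r^2)}, situation
#' effects \eqn{s_j \sim N(0, \sigma_s^2)} and residual noise
#' \eqn{v_{ijk} \sim N(0, \sigma_v^2)}, all independent Gaussians (the
#' conventional reading of a variance-components model). The implied
#' population single-measure ICC is
#' \eqn{\rho = \sigma_r^2 / (\sigma_r^2 + \sigma_v^2)}.
#'
#' The timestamped generator additionally emulates a wearable's sampling
#' schedule: a regular grid every `sampling_period_min` minutes, fully
#' emitted inside the nightly `sleep_window` (dense sleep sampling) and
#' thinned to `wake_retention` outside it, plus two artifact channels —
#' a `zero_rate` fraction of values replaced by literal 0 (the vendor
#' missing-data signature, common for rMSSD) and an `outlier_rate`
#' fraction replaced by deterministic mean + 4 SD spikes (so the 2-SD
#' filter's behaviour on them is analyzable).
#'
#' `sigma_s_wake` and `sigma_v_wake` let wakeful occasion-to-occasion
#' variation and residual noise differ from their sleep counterparts
#' (both default to the sleep values), reproducing the empirical
#' situation where wakeful recordings are far more variable and noisier
#' than sleep recordings.
#'
#' @param mu Grand mean (beats/min for bpm, ms for rmssd).
#' @param sigma_r SD of participant effects.
#' @param sigma_s SD of situation effects (sleep-occasion SD for the
#'   timestamped generator).
#' @param sigma_v SD of residual noise (sleep noise for the timestamped
#'   generator).
#' @param sigma_s_wake SD of wakeful situation effects (timestamped
#'   generator only; default `sigma_s`).
#' @param sigma_v_wake SD of wakeful residual noise (timestamped
#'   generator only; default `sigma_v`).
#' @param n_participants,n_situations,k_replicates Design counts for the
#'   matrix-form generator.
#' @param sampling_period_min Sampling grid step in minutes (default 5,
#'   the enhanced-mode rate of the emulated sensor).
#' @param sleep_start,sleep_end Local clock times "HH:MM" bounding the
#'   nightly dense-sampling window (may cross midnight; default
#'   23:00-07:00).
#' @param wake_retention Probability that a wakeful grid point is emitted.
#' @param zero_rate Fraction of emitted values replaced by 0.
#' @param outlier_rate Fraction of emitted values replaced by +4 SD
#'   spikes.
#' @param seed Integer seed; every generator draw is reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(mu = 70, sigma_r = 5, sigma_s = 2, sigma_v = 3,
                       sigma_s_wake = sigma_s, sigma_v_wake = sigma_v,
                       n_participants = 10, n_situations = 4,
                       k_replicates = 4,
                       sampling_period_min = 5,
                       sleep_start = "23:00", sleep_end = "07:00",
                       wake_retention = 0.2, zero_rate = 0,
                       outlier_rate = 0, seed = 1L) {
  stopifnot(
    sigma_r >= 0, sigma_s >= 0, sigma_v >= 0, sigma_v_wake >= 0,
    sigma_s_wake >= 0,
    n_participants >= 1, n_situations >= 1, k_replicates >= 1,
    sampling_period_min > 0,
    wake_retention >= 0, wake_retention <= 1,
    zero_rate >= 0, zero_rate <= 1,
    outlier_rate >= 0, outlier_rate <= 1)
  for (t in c(sleep_start, sleep_end)) {
    if (!grepl("^\\d{2}:\\d{2}$", t)) {
      abort("sleep window bounds must be 'HH:MM'",
        class = "reliwear_config_error")
    }
  }
  structure(list(
    mu = mu, sigma_r = sigma_r, sigma_s = sigma_s, sigma_v = sigma_v,
    sigma_s_wake = sigma_s_wake, sigma_v_wake = sigma_v_wake,
    n_participants = as.integer(n_participants),
    n_situations = as.integer(n_situations),
    k_replicates = as.integer(k_replicates),
    sampling_period_min = sampling_period_min,
    sleep_start = sleep_start, sleep_end = sleep_end,
    wake_retention = wake_retention, zero_rate = zero_rate,
    outlier_rate = outlier_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Population ICC implied by a simulation configuration
#'
#' \eqn{\rho = \sigma_r^2 / (\sigma_r^2 + \sigma_v^2)}; the value the
#' sample ICC should recover.
#'
#' @param config A [sim_config()].
#' @param state For the timestamped generator, which state's noise to use
#'   (`"sleep"` uses `sigma_v`, `"wake"` uses `sigma_v_wake`).
#' @return The population intraclass correlation.
#' @export
population_icc <- function(config, state = c("sleep", "wake")) {
  state <- match.arg(state)
  sv <- if (state == "wake") config$sigma_v_wake else config$sigma_v
  if (config$sigma_r == 0 && sv == 0) {
    abort("population ICC undefined when sigma_r = sigma_v = 0",
      class = "reliwear_degenerate_error")
  }
  config$sigma_r^2 / (config$sigma_r^2 + sv^2)
}

participant_ids <- function(n) sprintf("P%02d", seq_len(n))

#' Simulate matrix-form variance-components data
#'
#' Draws a participants x situations x replicates array from the additive
#' Gaussian model (see [sim_config()]), keeping the realized effect
#' components so tests can score estimators against the truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `data` (tibble
#'   `participant_id`, `situation`, `replicate`, `value`, plus the
#'   realized components `r`, `s`, `v`), `truth` (participant and
#'   situation effect tables), `config`.
#' @export
simulate_components <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    pid <- participant_ids(config$n_participants)
    sid <- sprintf("S%02d", seq_len(config$n_situations))
    r <- rnorm(config$n_participants, 0, config$sigma_r)
    s <- rnorm(config$n_situations, 0, config$sigma_s)
    grid <- tidyr::expand_grid(participant_id = pid, situation = sid,
      replicate = seq_len(config$k_replicates))
    grid$r <- r[match(grid$participant_id, pid)]
    grid$s <- s[match(grid$situation, sid)]
    grid$v <- rnorm(nrow(grid), 0, config$sigma_v)
    grid$value <- config$mu + grid$r + grid$s + grid$v
    structure(list(
      data = grid[c("participant_id", "situation", "replicate", "value",
        "r", "s", "v")],
      truth = list(
        participant_effects = tibble::tibble(participant_id = pid, r = r),
        situation_effects = tibble::tibble(situation = sid, s = s)),
      config = config
    ), class = "sim_dataset")
  })
}

parse_hm <- function(x) {
  p <- as.integer(strsplit(x, ":")[[1]])
  p[1] * 3600 + p[2] * 60
}

in_sleep_window <- function(seconds_of_day, start_s, end_s) {
  if (start_s <= end_s) {
    seconds_of_day >= start_s & seconds_of_day < end_s
  } else {
    seconds_of_day >= start_s | seconds_of_day < end_s
  }
}

#' Simulate a timestamped wearable sample stream
#'
#' Generates `n_days` noon-to-noon study days of a single metric for each
#' participant on the sensor's sampling grid. All grid points inside the
#' nightly sleep window are emitted (the dense block that sleep detection
#' recovers); wakeful grid points are emitted independently with
#' probability `wake_retention`. Every (participant, study day, state)
#' occasion draws its own situation effect — sleep occasions from
#' \eqn{N(0, \sigma_s^2)}, wake occasions from
#' \eqn{N(0, \sigma_{s,wake}^2)} — and the two states have their own
#' residual-noise SDs. Zero and spike artifacts are injected last,
#' after the truth is stored, so filters can be scored for exact recall;
#' any negative Gaussian draw (physically impossible for these metrics)
#' is likewise censored to the failed-sample value 0 and flagged.
#'
#' @param config A [sim_config()].
#' @param n_days Number of study days per participant.
#' @param metric `"bpm"` or `"rmssd"`.
#' @param start_date Date of the first study day.
#' @param tz Time zone of the local sampling clock.
#' @return A `sim_dataset` whose `stream` element is a `sample_stream`
#'   (with `state = "unlabeled"`: labelling is the pipeline's job) and
#'   whose `truth` element holds the per-record components, the true
#'   state, the pre-artifact values and artifact flags, plus
#'   `sleep_blocks` (first/last emitted sleep instant per participant and
#'   study day) and the state-level situation effects.
#' @export
simulate_stream <- function(config, n_days = 7, metric = "bpm",
                            start_date = as.Date("2024-03-04"),
                            tz = "UTC") {
  stopifnot(inherits(config, "sim_config"))
  metric <- match.arg(metric, .metrics)
  start_s <- parse_hm(config$sleep_start)
  end_s <- parse_hm(config$sleep_end)
  step <- config$sampling_period_min * 60
  withr::with_seed(config$seed, {
    pid <- participant_ids(config$n_participants)
    r <- rnorm(config$n_participants, 0, config$sigma_r)
    noon0 <- as.POSIXct(paste(start_date, "12:00:00"), tz = tz)
    grid <- seq(0, 86400 - step, by = step)
    day_offsets <- rep(seq_len(n_days) - 1, each = length(grid))
    within_day <- rep(grid, times = n_days)
    recs <- purrr::map_dfr(seq_along(pid), function(i) {
      ts <- noon0 + day_offsets * 86400 + within_day
      day_idx <- day_offsets + 1
      sod <- (as.numeric(ts) - as.numeric(lubridate::floor_date(ts, "day"))) %% 86400
      asleep <- in_sleep_window(sod, start_s, end_s)
      keep <- asleep | (stats::runif(length(ts)) < config$wake_retention)
      ts <- ts[keep]; asleep <- asleep[keep]; day_idx <- day_idx[keep]
      # one situation effect per (participant, study day, state) occasion
      s_occ <- cbind(rnorm(n_days, 0, config$sigma_s),
        rnorm(n_days, 0, config$sigma_s_wake))
      sv <- ifelse(asleep, config$sigma_v, config$sigma_v_wake)
      v <- rnorm(length(ts), 0, sv)
      s <- s_occ[cbind(day_idx, ifelse(asleep, 1L, 2L))]
      tibble::tibble(
        participant_id = pid[i], timestamp = ts,
        study_day = start_date + day_idx - 1,
        true_state = ifelse(asleep, "sleep", "wake"),
        r = r[i], s = s, v = v,
        clean_value = config$mu + r[i] + s + v)
    })
    # artifacts injected after truth storage
    recs$artifact <- "none"
    n <- nrow(recs)
    n_zero <- round(config$zero_rate * n)
    n_out <- round(config$outlier_rate * n)
    idx <- sample.int(n, min(n, n_zero + n_out))
    zero_idx <- idx[seq_len(n_zero)]
    out_idx <- setdiff(idx, zero_idx)
    recs$value <- recs$clean_value
    recs$artifact[zero_idx] <- "zero"
    recs$value[zero_idx] <- 0
    if (length(out_idx) > 0) {
      stats_p <- recs |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::summarise(m = mean(.data$clean_value),
          s = sd(.data$clean_value), .groups = "drop")
      pm <- setNames(stats_p$m, stats_p$participant_id)
      ps <- setNames(stats_p$s, stats_p$participant_id)
      recs$artifact[out_idx] <- "outlier"
      recs$value[out_idx] <- pm[recs$participant_id[out_idx]] +
        4 * ps[recs$participant_id[out_idx]]
    }
    # negative draws are physically impossible reads: censor to the
    # sensor's failed-sample signature (0), truth keeps the clean value
    censored <- recs$value < 0
    recs$artifact[censored] <- "censored"
    recs$value[censored] <- 0
    sleep_blocks <- recs |>
      dplyr::filter(.data$true_state == "sleep") |>
      dplyr::group_by(.data$participant_id, .data$study_day) |>
      dplyr::summarise(start = min(.data$timestamp), end = max(.data$timestamp),
        n_samples = dplyr::n(), .groups = "drop")
    stream <- as_sample_stream(tibble::tibble(
      participant_id = recs$participant_id,
      device_id = "sim01",
      timestamp = recs$timestamp,
      metric = metric,
      value = recs$value,
      activity = "unlabeled", state = "unlabeled"
    ), provenance = sprintf("simulate_stream(seed = %d)", config$seed))
    structure(list(
      stream = stream,
      truth = list(
        records = recs,
        participant_effects = tibble::tibble(participant_id = pid, r = r),
        situation_effects = dplyr::distinct(
          recs[c("participant_id", "study_day", "true_state", "s")]),
        sleep_blocks = sleep_blocks),
      config = config
    ), class = "sim_dataset")
  })
}

#' Simulate EMA prompt responses
#'
#' Generates six prompts per participant-day at seeded random times
#' between 08:00 and 20:00 local time, each with the eight 1-10 integer
#' items. Items are drawn around fixed scale anchors (positive items
#' around 6, negative around 3, pain/discomfort around 2) with a
#' participant-level random intercept and item-level Gaussian noise, then
#' rounded and clipped to \[1, 10\].
#'
#' When `association` is supplied, the negative-item means on day D are
#' shifted by `slope * (b - mean(b))` before rounding, where `b` is the
#' participant's mean *clean* sleep value of the preceding night (study
#' day D - 1) in the coupled `dataset` — a ground-truth next-day
#' association for recovery tests.
#'
#' @param config A [sim_config()] (supplies the seed and participant
#'   count).
#' @param n_days Number of days of prompts.
#' @param start_date Date of the first day.
#' @param n_prompts_per_day Prompts per day (default 6).
#' @param association Optional `list(slope = )`: linear coupling of
#'   next-day negative affect to the preceding night's sleep biometric.
#' @param dataset The `sim_dataset` (from [simulate_stream()]) to couple
#'   to; required when `association` is given.
#' @param tz Time zone of prompt clock times.
#' @return An `ema_records` tibble (see [read_ema()]).
#' @export
simulate_ema <- function(config, n_days = 7,
                         start_date = as.Date("2024-03-04"),
                         n_prompts_per_day = 6,
                         association = NULL, dataset = NULL,
                         tz = "UTC") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(association) && is.null(dataset)) {
    abort("`dataset` is required when `association` is given",
      class = "reliwear_config_error")
  }
  anchors <- c(happy = 6, energetic = 6, nervous = 3, afraid = 3,
    irritable = 3, angry = 3, pain = 2, discomfort = 2)
  night_shift <- NULL
  if (!is.null(association)) {
    night <- dataset$truth$records |>
      dplyr::filter(.data$true_state == "sleep") |>
      dplyr::mutate(study_day = study_day(.data$timestamp, tz = tz)) |>
      dplyr::group_by(.data$participant_id, .data$study_day) |>
      dplyr::summarise(b = mean(.data$clean_value), .groups = "drop")
    night$shift <- association$slope * (night$b - mean(night$b))
    night_shift <- setNames(night$shift,
      paste(night$participant_id, night$study_day))
  }
  withr::with_seed(config$seed + 1L, {
    pid <- participant_ids(config$n_participants)
    intercept <- rnorm(length(pid), 0, 0.5)
    purrr::map_dfr(seq_along(pid), function(i) {
      purrr::map_dfr(seq_len(n_days), function(d) {
        day <- start_date + d - 1
        secs <- sort(stats::runif(n_prompts_per_day, 8 * 3600, 20 * 3600))
        ts <- as.POSIXct(paste(day, "00:00:00"), tz = tz) + round(secs)
        shift <- 0
        if (!is.null(night_shift)) {
          key <- paste(pid[i], day - 1) # preceding night began on day - 1
          if (key %in% names(night_shift)) shift <- night_shift[[key]]
        }
        items <- purrr::map(names(anchors), function(item) {
          mu_item <- anchors[[item]] + intercept[i] +
            if (item %in% ema_negative_items()) shift else 0
          raw <- round(rnorm(n_prompts_per_day, mu_item, 1.5))
          as.integer(pmin(10, pmax(1, raw)))
        })
        names(items) <- names(anchors)
        dplyr::bind_cols(
          tibble::tibble(participant_id = pid[i], timestamp = ts),
          tibble::as_tibble(items))
      })
    }) -> out
    class(out) <- c("ema_records", class(out))
    out
  })
}

#' Export a simulated dataset's truth tables as CSV
#'
#' Writes the realized effect components to plain CSV files so tests and
#' reports never need to reach inside generator objects.
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- sim$truth
  if (!is.null(tr$participant_effects)) {
    readr::write_csv(tr$participant_effects,
      file.path(dir, "participant_effects.csv"))
  }
  if (!is.null(tr$situation_effects)) {
    readr::write_csv(tr$situation_effects,
      file.path(dir, "situation_effects.csv"))
  }
  if (!is.null(tr$records)) {
    rec <- tr$records
    rec$timestamp <- format_iso8601(rec$timestamp)
    readr::write_csv(rec, file.path(dir, "record_components.csv"))
  }
  if (!is.null(tr$sleep_blocks)) {
    sb <- tr$sleep_blocks
    sb$start <- format_iso8601(sb$start)
    sb$end <- format_iso8601(sb$end)
    readr::write_csv(sb, file.path(dir, "sleep_blocks.csv"))
  }
  invisible(dir)
}

#' Simulate a two-metric wearable cohort
#'
#' Convenience generator for a realistic continuous-wear cohort: one BPM
#' stream and one rMSSD stream per participant on a shared study
#' calendar, each from its own [sim_config()] drawn off a single master
#' seed. Defaults emulate a week of free-living wear: resting-range heart
#' rate (mean 70 beats/min, between-person SD 5) and rMSSD around 45 ms
#' (between-person SD 12), dense nightly sampling, roughly one wakeful
#' sample in ten retained, wakeful noise several times larger than sleep
#' noise for both metrics, and about a fifth of rMSSD samples zeroed by
#' the vendor missing-data signature.
#'
#' @param seed Master seed; the two metric configs derive their seeds
#'   from it.
#' @param n_participants,n_days Cohort size and study length.
#' @param bpm,rmssd Named lists overriding the per-metric value model:
#'   `mu`, `sigma_r`, `sigma_s`, `sigma_v` (sleep noise), `sigma_v_wake`,
#'   `zero_rate`, `outlier_rate`.
#' @param wake_retention Probability a wakeful grid point is emitted
#'   (shared by both metrics).
#' @param start_date,tz Study calendar.
#' @return A list: `stream` (combined two-metric `sample_stream`),
#'   `bpm_sim` and `rmssd_sim` (the per-metric `sim_dataset`s with their
#'   truth tables), `seed`.
#' @export
simulate_cohort <- function(seed, n_participants = 10, n_days = 7,
                            bpm = list(), rmssd = list(),
                            wake_retention = 0.1,
                            start_date = as.Date("2024-03-04"),
                            tz = "UTC") {
  bpm_par <- utils::modifyList(list(mu = 70, sigma_r = 5, sigma_s = 1,
    sigma_s_wake = 3, sigma_v = 2, sigma_v_wake = 6, zero_rate = 0,
    outlier_rate = 0), bpm)
  hrv_par <- utils::modifyList(list(mu = 45, sigma_r = 12, sigma_s = 4,
    sigma_s_wake = 8, sigma_v = 5, sigma_v_wake = 25, zero_rate = 0.1926,
    outlier_rate = 0.01), rmssd)
  seeds <- derive_seeds(seed, 2)
  make_cfg <- function(par, s) {
    sim_config(mu = par$mu, sigma_r = par$sigma_r, sigma_s = par$sigma_s,
      sigma_s_wake = par$sigma_s_wake, sigma_v = par$sigma_v,
      sigma_v_wake = par$sigma_v_wake,
      n_participants = n_participants, wake_retention = wake_retention,
      zero_rate = par$zero_rate, outlier_rate = par$outlier_rate, seed = s)
  }
  bpm_sim <- simulate_stream(make_cfg(bpm_par, seeds[1]), n_days = n_days,
    metric = "bpm", start_date = start_date, tz = tz)
  hrv_sim <- simulate_stream(make_cfg(hrv_par, seeds[2]), n_days = n_days,
    metric = "rmssd", start_date = start_date, tz = tz)
  stream <- as_sample_stream(dplyr::bind_rows(
    tibble::as_tibble(bpm_sim$stream), tibble::as_tibble(hrv_sim$stream)),
    provenance = sprintf("simulate_cohort(seed = %d)", as.integer(seed)))
  list(stream = stream, bpm_sim = bpm_sim, rmssd_sim = hrv_sim,
    seed = as.integer(seed))
}
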