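#' Score EMA prompts into negative and positive affect
#'
#' Each prompt's negative-affect score is the mean of the four negative
#' emotion items (irritable, afraid, nervous, angry) and its
#' positive-affect score the mean of the two positive items (happy,
#' energetic). Pain and discomfort are carried in the data model but not
#' scored. A scale with more than half of its items missing yields `NA`
#' for that prompt; prompts with both scales missing are dropped and
#' reported in the `skipped` attribute.
#'
#' @param ema An `ema_records` tibble from [read_ema()] or
#'   [simulate_ema()].
#' @return A tibble `participant_id`, `timestamp`, `neg_score`,
#'   `pos_score` with attribute `skipped`.
#' @export
score_prompts <- function(ema) {
  df <- tibble::as_tibble(ema)
  neg_m <- as.matrix(df[ema_negative_items()])
  pos_m <- as.matrix(df[ema_positive_items()])
  neg_present <- rowSums(!is.na(neg_m))
  pos_present <- rowSums(!is.na(pos_m))
  neg <- ifelse(neg_present >= length(ema_negative_items()) / 2,
    rowMeans(neg_m, na.rm = TRUE), NA_real_)
  pos <- ifelse(pos_present >= length(ema_positive_items()) / 2,
    rowMeans(pos_m, na.rm = TRUE), NA_real_)
  out <- tibble::tibble(
    participant_id = df$participant_id, timestamp = df$timestamp,
    neg_score = neg, pos_score = pos)
  skip <- is.na(neg) & is.na(pos)
  skipped <- out[skip, c("participant_id", "timestamp")]
  if (nrow(skipped) > 0) {
    inform(sprintf("%d prompt(s) skipped: more than half of each scale missing",
      nrow(skipped)))
  }
  structure(out[!skip, ], skipped = skipped)
}

#' Daily affect scores
#'
#' Averages prompt-level negative and positive affect within each
#' participant and calendar day. Days without prompts are simply absent.
#'
#' @param scores Output of [score_prompts()].
#' @param tz Time zone defining the calendar day.
#' @return A tibble `participant_id`, `day`, `neg_score`, `pos_score`,
#'   `n_prompts`.
#' @export
daily_affect <- function(scores, tz = "UTC") {
  df <- tibble::as_tibble(scores)
  df$day <- as.Date(lubridate::with_tz(df$timestamp, tz))
  df |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(
      neg_score = mean(.data$neg_score, na.rm = TRUE),
      pos_score = mean(.data$pos_score, na.rm = TRUE),
      n_prompts = dplyr::n(), .groups = "drop")
}

#' Daily biometric means by sleep/wake state
#'
#' Summarises a labelled stream into one mean per participant, metric,
#' state and day — the biometric side of the affect models. Wake records
#' are keyed by calendar date (the day the samples were taken); sleep
#' records are keyed by the noon-to-noon [study_day()], i.e. the evening
#' date on which the night began, so that "the night following day D" has
#' day label D and "the night preceding day D" has label D - 1.
#'
#' @param stream A labelled, filtered `sample_stream`.
#' @param tz Time zone for day labels.
#' @return A tibble `participant_id`, `metric`, `state`, `day`,
#'   `mean_value`, `n`.
#' @export
daily_biometrics <- function(stream, tz = "UTC") {
  df <- tibble::as_tibble(stream)
  df <- df[df$state %in% c("sleep", "wake"), ]
  df$day <- dplyr::if_else(df$state == "sleep",
    study_day(df$timestamp, tz = tz),
    as.Date(lubridate::with_tz(df$timestamp, tz)))
  df |>
    dplyr::group_by(.data$participant_id, .data$metric, .data$state,
      .data$day) |>
    dplyr::summarise(mean_value = mean(.data$value), n = dplyr::n(),
      .groups = "drop")
}

model_grid <- function() {
  tidyr::expand_grid(
    metric = c("bpm", "rmssd"),
    timing = c("concurrent_wake", "preceding_night", "following_night"))
}

#' Lagged mixed models linking daily affect to biometrics
#'
#' Fits the six-model family relating daily affect to sleep/wake
#' biometrics: for each metric (BPM, rMSSD), the daily biometric mean is
#' regressed on that day's negative and positive affect scores with a
#' participant random intercept, at three timings — concurrent wakeful
#' biometrics (same day), the preceding night's sleep biometrics (the
#' night ending on the morning of the affect day), and the following
#' night's (the night starting on the evening of the affect day).
#' Affect is the predictor and the biometric the outcome in every model.
#' P-values use Satterthwaite degrees of freedom; the Bonferroni-corrected
#' p-value is `min(1, m * p_raw)` with the family size `m = 6`.
#'
#' @param affect A [daily_affect()] table.
#' @param biometrics A [daily_biometrics()] table.
#' @param m Bonferroni family size (default 6, the number of models).
#' @return A tibble of class `association_results` with one row per model
#'   and affect term: `model_id`, `metric`, `timing`, `term`, `beta`,
#'   `t_stat`, `df`, `p_raw`, `p_bonferroni`, `n_observations`. Models
#'   with no paired observations are flagged by `n_observations = 0` and
#'   `NA` statistics, not fitted.
#' @export
fit_lagged_models <- function(affect, biometrics, m = 6) {
  affect <- tibble::as_tibble(affect)
  biometrics <- tibble::as_tibble(biometrics)
  grid <- model_grid()
  rows <- purrr::pmap_dfr(grid, function(metric, timing) {
    bio <- biometrics[biometrics$metric == metric, ]
    bio <- if (timing == "concurrent_wake") {
      dplyr::mutate(bio[bio$state == "wake", ], day_key = .data$day)
    } else if (timing == "preceding_night") {
      # sleep keyed by the evening it began: night before affect day D is D-1
      dplyr::mutate(bio[bio$state == "sleep", ], day_key = .data$day + 1L)
    } else {
      dplyr::mutate(bio[bio$state == "sleep", ], day_key = .data$day)
    }
    paired <- dplyr::inner_join(affect, bio,
      by = c(participant_id = "participant_id", day = "day_key"))
    model_id <- paste(metric, timing, sep = "_")
    empty <- tibble::tibble(
      model_id = model_id, metric = metric, timing = timing,
      term = c("neg_score", "pos_score"),
      beta = NA_real_, t_stat = NA_real_, df = NA_real_,
      p_raw = NA_real_, p_bonferroni = NA_real_,
      n_observations = nrow(paired))
    if (nrow(paired) < 3 || dplyr::n_distinct(paired$participant_id) < 2) {
      return(empty)
    }
    fit <- tryCatch(withCallingHandlers(
      lmerTest::lmer(mean_value ~ neg_score + pos_score + (1 | participant_id),
        data = paired),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(mm) invokeRestart("muffleMessage")),
      error = function(e) NULL)
    if (is.null(fit)) return(empty)
    ct <- suppressWarnings(summary(fit)$coefficients)
    purrr::map_dfr(c("neg_score", "pos_score"), function(term) {
      tibble::tibble(
        model_id = model_id, metric = metric, timing = timing, term = term,
        beta = unname(ct[term, "Estimate"]),
        t_stat = unname(ct[term, "t value"]),
        df = unname(ct[term, "df"]),
        p_raw = unname(ct[term, "Pr(>|t|)"]),
        p_bonferroni = bonferroni(unname(ct[term, "Pr(>|t|)"]), m),
        n_observations = nrow(paired))
    })
  })
  structure(rows,
    class = c("association_results", class(tibble::tibble())), m = m)
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the family size `m`, capped at 1.
#'
#' @param p Raw p-value(s).
#' @param m Number of tests in the family.
#' @return Corrected p-value(s).
#' @examples
#' bonferroni(0.009, 6) # 0.054
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}
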