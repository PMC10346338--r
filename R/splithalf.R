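#' Time-sensitive odd/even split
#'
#' Within each unit (e.g. a participant's samples during one activity, or
#' one participant-day in one sleep/wake state), samples are numbered
#' 1..m in acquisition order; odd positions are averaged into one half and
#' even positions into the other. Because consecutive samples alternate
#' between halves, the two halves are as close in time as a split can
#' make them, so their agreement reflects short-timescale measurement
#' consistency rather than slow drift.
#'
#' Direction is fixed and documented: the even-position half is the
#' predictor, the odd-position half the criterion. Units are always
#' (participant, metric) crossed with the columns in `unit_key`.
#'
#' @param stream A `sample_stream`.
#' @param unit_key Character vector of extra unit columns: any of
#'   `"activity"`, `"device_id"`, `"state"`, `"study_day"` (computed from
#'   timestamps if absent as a column).
#' @param tz Time zone for `"study_day"`.
#' @return A tibble of class `split_pairs`: `participant_id`, `metric`,
#'   the unit columns, `predictor_mean` (even half), `criterion_mean`
#'   (odd half), `n_odd`, `n_even`. Units with fewer than 2 samples are
#'   dropped and reported in the `dropped` attribute.
#' @examples
#' # four samples 70, 72, 74, 76 in time order -> odd half 72, even half 74
#' @export
split_time_sensitive <- function(stream, unit_key = "activity", tz = "UTC") {
  grouped <- unit_groups(stream, unit_key, tz)
  halves <- grouped |>
    dplyr::summarise(
      predictor_mean = mean(.data$value[seq_along(.data$value) %% 2 == 0]),
      criterion_mean = mean(.data$value[seq_along(.data$value) %% 2 == 1]),
      n_odd = sum(seq_along(.data$value) %% 2 == 1),
      n_even = sum(seq_along(.data$value) %% 2 == 0),
      .groups = "drop")
  finish_split(halves, unit_key)
}

#' Random split into halves
#'
#' Within each unit, samples are partitioned uniformly at random into two
#' halves of sizes ceiling(m/2) and floor(m/2) (the larger half is the
#' criterion, mirroring the odd half of the time-sensitive split). The
#' partition is fully determined by `seed`: the same seed reproduces the
#' same partition for every unit.
#'
#' @inheritParams split_time_sensitive
#' @param seed Integer seed controlling the partition.
#' @return A `split_pairs` tibble as in [split_time_sensitive()].
#' @export
split_random <- function(stream, unit_key = "activity", seed, tz = "UTC") {
  stopifnot(is.numeric(seed), length(seed) == 1)
  grouped <- unit_groups(stream, unit_key, tz)
  halves <- withr::with_seed(as.integer(seed), {
    grouped |>
      dplyr::summarise(.half = {
        m <- dplyr::n()
        crit <- sample.int(m, ceiling(m / 2))
        list(c(
          predictor_mean = mean(.data$value[-crit]),
          criterion_mean = mean(.data$value[crit]),
          n_odd = length(crit), n_even = m - length(crit)))
      }, .groups = "drop") |>
      tidyr::unnest_wider(".half")
  })
  halves$n_odd <- as.integer(halves$n_odd)
  halves$n_even <- as.integer(halves$n_even)
  finish_split(halves, unit_key)
}

unit_groups <- function(stream, unit_key, tz) {
  allowed <- c("activity", "device_id", "state", "study_day")
  bad <- setdiff(unit_key, allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown unit_key column(s): ", paste(bad, collapse = ", "),
      " (allowed: ", paste(allowed, collapse = ", "), ")"),
      class = "reliwear_config_error")
  }
  df <- tibble::as_tibble(stream)
  if ("study_day" %in% unit_key && !"study_day" %in% names(df)) {
    df$study_day <- study_day(df$timestamp, tz = tz)
  }
  df |>
    dplyr::arrange(.data$participant_id, .data$metric, .data$timestamp) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("participant_id", "metric", unit_key))))
}

finish_split <- function(halves, unit_key) {
  dropped <- halves[halves$n_odd < 1 | halves$n_even < 1, ]
  kept <- halves[halves$n_odd >= 1 & halves$n_even >= 1, ]
  structure(kept,
    class = c("split_pairs", class(tibble::tibble())),
    unit_key = unit_key,
    dropped = dropped[c("participant_id", "metric", unit_key)])
}

#' Fit the split-half mixed-model regression
#'
#' Fits the mixed model
#' \deqn{y = a + \beta x + (1\,|\,\mathrm{factor}_1) + \dots}
#' where \eqn{x} is the predictor half mean and \eqn{y} the criterion half
#' mean of each unit, with a random intercept for each requested grouping
#' factor. The slope \eqn{\beta} is the within-person reliability
#' estimate: \eqn{\beta} near 1 means the two halves agree after removing
#' the between-unit variance absorbed by the random intercepts. The t test
#' of \eqn{\beta} uses Satterthwaite-approximated degrees of freedom.
#'
#' Random-intercept variances estimated at zero (singular fits) are
#' legitimate boundary estimates and count as converged; optimizer
#' convergence failures set `converged = FALSE`. If the residual variance
#' collapses to exactly zero (noise-free data) the mixed-model machinery
#' for standard errors is unavailable and the slope is reported with `NA`
#' test statistics and a note.
#'
#' @param pairs A `split_pairs` tibble.
#' @param random_factors Character vector of grouping columns to receive
#'   random intercepts, e.g. `"participant_id"` or
#'   `c("participant_id", "activity")`.
#' @param ddf If `TRUE` (default) compute Satterthwaite degrees of
#'   freedom; `FALSE` skips the (comparatively slow) computation, leaving
#'   `t_stat`/`df`/`p_value` as `NA` — used by
#'   [random_split_distribution()] where only the slope is needed.
#' @return An object of class `split_half_fit`: `beta`, `intercept`,
#'   `se`, `t_stat`, `df`, `p_value`, `random_factors`, `converged`,
#'   `n_units`, `note`, and the underlying `model`.
#' @export
fit_split_model <- function(pairs, random_factors = "participant_id",
                            ddf = TRUE) {
  df <- tibble::as_tibble(pairs)
  if (nrow(df) < 3) {
    abort("need at least 3 split pairs to fit", class = "reliwear_data_error")
  }
  missing_f <- setdiff(random_factors, names(df))
  if (length(missing_f) > 0) {
    abort(paste0("random factor column(s) not in pairs: ",
      paste(missing_f, collapse = ", ")), class = "reliwear_config_error")
  }
  if (var(df$predictor_mean) == 0) {
    abort("predictor half has zero variance: degenerate design",
      class = "reliwear_degenerate_error")
  }
  usable <- random_factors[vapply(random_factors,
    function(f) dplyr::n_distinct(df[[f]]) >= 2, logical(1))]
  note <- character()
  if (length(usable) < length(random_factors)) {
    note <- c(note, paste0("random factor(s) with a single level dropped: ",
      paste(setdiff(random_factors, usable), collapse = ", ")))
  }

  if (length(usable) == 0) {
    fit <- stats::lm(criterion_mean ~ predictor_mean, data = df)
    ct <- summary(fit)$coefficients
    return(structure(list(
      beta = unname(ct["predictor_mean", "Estimate"]),
      intercept = unname(ct["(Intercept)", "Estimate"]),
      se = unname(ct["predictor_mean", "Std. Error"]),
      t_stat = unname(ct["predictor_mean", "t value"]),
      df = fit$df.residual,
      p_value = unname(ct["predictor_mean", "Pr(>|t|)"]),
      random_factors = character(), converged = TRUE, n_units = nrow(df),
      note = c(note, "no usable random factors; ordinary least squares"),
      model = fit), class = "split_half_fit"))
  }

  fml <- as.formula(paste("criterion_mean ~ predictor_mean +",
    paste(sprintf("(1 | %s)", usable), collapse = " + ")))
  converged <- TRUE
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore",
    calc.derivs = ddf)
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(fml, data = df, REML = TRUE, control = ctrl),
      error = function(e) e),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    abort(paste0("mixed-model fit failed: ", conditionMessage(fit)),
      class = "reliwear_fit_error")
  }
  fe <- lme4::fixef(fit)
  beta <- unname(fe["predictor_mean"])
  intercept <- unname(fe["(Intercept)"])
  se <- t_stat <- dfree <- p_value <- NA_real_
  if (ddf) {
    sat <- tryCatch({
      lt <- suppressWarnings(lmerTest::as_lmerModLmerTest(fit))
      ct <- suppressWarnings(summary(lt)$coefficients)
      list(se = ct["predictor_mean", "Std. Error"],
        t = ct["predictor_mean", "t value"],
        df = ct["predictor_mean", "df"],
        p = ct["predictor_mean", "Pr(>|t|)"])
    }, error = function(e) NULL)
    if (is.null(sat)) {
      note <- c(note,
        "Satterthwaite statistics unavailable (residual variance ~ 0)")
    } else {
      se <- unname(sat$se); t_stat <- unname(sat$t)
      dfree <- unname(sat$df); p_value <- unname(sat$p)
    }
  }
  structure(list(
    beta = beta, intercept = intercept, se = se, t_stat = t_stat,
    df = dfree, p_value = p_value, random_factors = usable,
    converged = converged, n_units = nrow(df), note = note, model = fit
  ), class = "split_half_fit")
}

#' @export
print.split_half_fit <- function(x, ...) {
  cat(sprintf("Split-half mixed model: beta = %.4f", x$beta))
  if (!is.na(x$t_stat)) {
    cat(sprintf(", t(%.2f) = %.3f, p = %.3g", x$df, x$t_stat, x$p_value))
  }
  cat(sprintf("\n  random intercepts: %s; units: %d; converged: %s\n",
    if (length(x$random_factors)) paste(x$random_factors, collapse = ", ")
      else "(none)",
    x$n_units, x$converged))
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

# per-iteration seeds derived from one master seed by a counter scheme:
# seed_i is the i-th draw from sample.int seeded with the master seed
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
    sample.int(.Machine$integer.max, n))
}

#' Distribution of split-half slopes over repeated random splits
#'
#' A single random split can be uncharacteristically (dis)similar by
#' chance, so the random-split reliability estimate is the mean slope over
#' many independent random partitions. Each iteration draws a fresh
#' partition (seeded deterministically from `master_seed` by a counter
#' scheme) and fits [fit_split_model()]; the summary is taken over the
#' converged fits.
#'
#' @inheritParams split_random
#' @param random_factors Passed to [fit_split_model()].
#' @param n_iterations Number of random splits (default 1000).
#' @param master_seed Integer master seed; the same master seed reproduces
#'   the summary bit for bit.
#' @param probs Quantiles of the beta distribution to report.
#' @return An object of class `beta_distribution`: `mean_beta`,
#'   `sd_beta`, `quantiles`, `betas` (converged slopes), `n_iterations`,
#'   `n_failed`, `master_seed`.
#' @export
random_split_distribution <- function(stream, unit_key = "activity",
                                      random_factors = "participant_id",
                                      n_iterations = 1000, master_seed,
                                      probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                                      tz = "UTC") {
  stopifnot(n_iterations >= 1)
  seeds <- derive_seeds(master_seed, n_iterations)
  betas <- rep(NA_real_, n_iterations)
  for (i in seq_len(n_iterations)) {
    pairs <- split_random(stream, unit_key = unit_key, seed = seeds[i],
      tz = tz)
    fit <- tryCatch(
      fit_split_model(pairs, random_factors = random_factors, ddf = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) betas[i] <- fit$beta
  }
  ok <- betas[!is.na(betas)]
  n_failed <- n_iterations - length(ok)
  if (length(ok) == 0) {
    abort("no random-split iteration produced a converged fit",
      class = "reliwear_fit_error")
  }
  if (n_failed > 0.1 * n_iterations) {
    warn(sprintf(
      "%d of %d random-split iterations failed to converge; summary may be unrepresentative",
      n_failed, n_iterations))
  }
  structure(list(
    mean_beta = mean(ok),
    sd_beta = if (length(ok) > 1) sd(ok) else 0,
    quantiles = quantile(ok, probs = probs, names = TRUE),
    betas = ok,
    n_iterations = n_iterations, n_failed = n_failed,
    master_seed = as.integer(master_seed)
  ), class = "beta_distribution")
}

#' @export
print.beta_distribution <- function(x, ...) {
  cat(sprintf(
    "Random-split reliability: mean beta = %.4f, SD across %d iterations = %.4f (%d failed)\n",
    x$mean_beta, x$n_iterations, x$sd_beta, x$n_failed))
  invisible(x)
}
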