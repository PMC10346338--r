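#' One-way random-effects ANOVA decomposition
#'
#' Decomposes repeated measurements into between-participant and
#' within-participant mean squares, the raw material of the one-way
#' intraclass correlation. Under the model
#' \deqn{x_{ij} = \mu + r_i + v_{ij},}
#' where \eqn{r_i} is participant \eqn{i}'s stable deviation from the
#' population mean \eqn{\mu} and \eqn{v_{ij}} is measurement error, the
#' between mean square (MSBS) estimates \eqn{k\sigma_r^2 + \sigma_v^2} and
#' the within mean square (MSWS) estimates \eqn{\sigma_v^2}.
#'
#' With unequal replicate counts the common \eqn{k} does not exist; the
#' decomposition then substitutes Searle's effective replicate count
#' \deqn{k_0 = \frac{1}{n-1}\left(N - \sum_i k_i^2 / N\right)}
#' and flags the result as unbalanced.
#'
#' @param data A [condition_means()] table, or any data frame with one row
#'   per measurement.
#' @param participant Name of the column identifying participants.
#' @param value Name of the measurement column. Defaults to `"mean"` when
#'   present (the `condition_means` layout), else `"value"`.
#' @return An object of class `anova_decomp`: a list with elements `msbs`,
#'   `msws`, `n` (participants), `k` (common or effective replicate
#'   count), `balanced`, `df_between`, `df_within`, `n_total`.
#' @examples
#' d <- tibble::tibble(participant_id = c("A", "A", "B", "B"),
#'                     value = c(1, 2, 3, 4))
#' decompose_oneway(d)
#' @export
decompose_oneway <- function(data, participant = "participant_id",
                             value = NULL) {
  df <- tibble::as_tibble(data)
  if (is.null(value)) {
    value <- if ("mean" %in% names(df)) "mean" else "value"
  }
  for (col in c(participant, value)) {
    if (!col %in% names(df)) {
      abort(paste0("column '", col, "' not found"),
        class = "reliwear_schema_error")
    }
  }
  df <- tibble::tibble(g = as.character(df[[participant]]),
    y = as.double(df[[value]]))
  df <- df[!is.na(df$y), ]
  ki <- table(df$g)
  few <- names(ki)[ki < 2]
  if (length(few) > 0) {
    warn(sprintf("dropping %d participant(s) with fewer than 2 replicates: %s",
      length(few), paste(head(few, 5), collapse = ", ")))
    df <- df[!df$g %in% few, ]
    ki <- table(df$g)
  }
  n <- length(ki)
  if (n < 2) {
    abort("need at least 2 participants with >= 2 replicates each",
      class = "reliwear_data_error")
  }
  N <- nrow(df)
  grand <- mean(df$y)
  means <- tapply(df$y, df$g, mean)
  ki <- as.numeric(ki[names(means)])
  ss_between <- sum(ki * (means - grand)^2)
  ss_within <- sum((df$y - means[df$g])^2)
  df_between <- n - 1
  df_within <- N - n
  balanced <- length(unique(ki)) == 1
  k <- if (balanced) ki[1] else (N - sum(ki^2) / N) / (n - 1)
  structure(list(
    msbs = ss_between / df_between,
    msws = ss_within / df_within,
    n = n, k = k, balanced = balanced,
    df_between = df_between, df_within = df_within, n_total = N
  ), class = "anova_decomp")
}

#' @export
print.anova_decomp <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA decomposition: MSBS = %.4g, MSWS = %.4g, n = %d, k = %.4g%s\n",
    x$msbs, x$msws, x$n, x$k,
    if (x$balanced) "" else " (unbalanced, Searle effective k0)"))
  invisible(x)
}

icc_ci_f <- function(f_obs, k, df1, df2, confidence, average) {
  alpha <- 1 - confidence
  fl <- f_obs / qf(1 - alpha / 2, df1, df2)
  fu <- f_obs * qf(1 - alpha / 2, df2, df1)
  if (average) {
    c(low = 1 - 1 / fl, high = 1 - 1 / fu)
  } else {
    c(low = (fl - 1) / (fl + k - 1), high = (fu - 1) / (fu + k - 1))
  }
}

new_icc_result <- function(estimate, ci, confidence, f_obs, df1, df2,
                           form, decomp) {
  p_value <- pf(f_obs, df1, df2, lower.tail = FALSE)
  structure(list(
    estimate = estimate,
    ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
    confidence = confidence, p_value = p_value,
    f_stat = f_obs, df1 = df1, df2 = df2,
    form = form, n = decomp$n, k = decomp$k, balanced = decomp$balanced,
    label = classify_icc(max(min(estimate, 1), -1))
  ), class = "icc_result")
}

#' Single-measure intraclass correlation, ICC(1,1)
#'
#' The one-way random single-measure ICC estimates the reliability of one
#' measurement occasion for distinguishing between people:
#' \deqn{ICC(1,1) = \frac{MSBS - MSWS}{MSBS + (k-1)\,MSWS},}
#' a consistent estimator of \eqn{\rho = \sigma_r^2/(\sigma_r^2 +
#' \sigma_v^2)}. The confidence interval uses the one-way F bounds
#' (Shrout & Fleiss): with \eqn{F = MSBS/MSWS},
#' \eqn{F_L = F / F_{1-\alpha/2}(n-1, N-n)} and
#' \eqn{F_U = F \cdot F_{1-\alpha/2}(N-n, n-1)}, mapped through
#' \eqn{(F-1)/(F+k-1)}. The p-value is the one-sided F test of zero ICC.
#'
#' The sample statistic can range down to \eqn{-1/(k-1)}; it is reported
#' unclipped.
#'
#' @param decomp An [decompose_oneway()] result.
#' @param confidence Confidence level for the interval (default 0.95).
#' @return An object of class `icc_result` with fields `estimate`,
#'   `ci_low`, `ci_high`, `confidence`, `p_value`, `form`, `n`, `k`,
#'   `balanced`, `label`.
#' @examples
#' d <- tibble::tibble(participant_id = c("A", "A", "B", "B"),
#'                     value = c(1, 2, 3, 4))
#' icc_single(decompose_oneway(d))
#' @export
icc_single <- function(decomp, confidence = 0.95) {
  stopifnot(inherits(decomp, "anova_decomp"),
    confidence > 0, confidence < 1)
  if (decomp$msbs == 0 && decomp$msws == 0) {
    abort("all measurements identical: ICC is undefined (0/0)",
      class = "reliwear_degenerate_error")
  }
  k <- decomp$k
  est <- (decomp$msbs - decomp$msws) / (decomp$msbs + (k - 1) * decomp$msws)
  f_obs <- if (decomp$msws == 0) Inf else decomp$msbs / decomp$msws
  ci <- icc_ci_f(f_obs, k, decomp$df_between, decomp$df_within, confidence,
    average = FALSE)
  if (is.infinite(f_obs)) ci <- c(low = 1, high = 1)
  new_icc_result(est, ci, confidence, f_obs, decomp$df_between,
    decomp$df_within, "single", decomp)
}

#' Average-measure intraclass correlation, ICC(1,k)
#'
#' Reliability of the *average* across all k measurement occasions:
#' \deqn{ICC(1,k) = \frac{MSBS - MSWS}{MSBS},}
#' related to the single-measure form by the Spearman-Brown step-up
#' \eqn{k\rho_1 / (1 + (k-1)\rho_1)}. Confidence bounds use the same F
#' bounds as [icc_single()] mapped through \eqn{1 - 1/F}.
#'
#' @inheritParams icc_single
#' @return An `icc_result` with `form = "average"`.
#' @export
icc_average <- function(decomp, confidence = 0.95) {
  stopifnot(inherits(decomp, "anova_decomp"),
    confidence > 0, confidence < 1)
  if (decomp$msbs == 0) {
    abort("MSBS = 0: average-measure ICC is undefined",
      class = "reliwear_degenerate_error")
  }
  est <- (decomp$msbs - decomp$msws) / decomp$msbs
  f_obs <- if (decomp$msws == 0) Inf else decomp$msbs / decomp$msws
  ci <- icc_ci_f(f_obs, decomp$k, decomp$df_between, decomp$df_within,
    confidence, average = TRUE)
  if (is.infinite(f_obs)) ci <- c(low = 1, high = 1)
  new_icc_result(est, ci, confidence, f_obs, decomp$df_between,
    decomp$df_within, "average", decomp)
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(1,%s) = %.3f, %g%% CI [%.3f, %.3f], p = %.3g (%s reliability; n = %d, k = %.3g%s)\n",
    if (x$form == "single") "1" else "k", x$estimate, 100 * x$confidence,
    x$ci_low, x$ci_high, x$p_value, x$label, x$n, x$k,
    if (x$balanced) "" else ", unbalanced"))
  invisible(x)
}

#' Qualitative reliability label for an ICC estimate
#'
#' Maps an ICC estimate into ordered qualitative bins. The default bins —
#' at least 0.75 excellent, 0.40 to 0.75 good, 0.25 to 0.40 fair, below
#' 0.25 poor — follow common usage in the wearable-reliability literature
#' (where, e.g., 0.65 is called good and 0.38 fair); they are stricter at
#' the top and looser at the bottom than Cicchetti's clinical bins, and
#' fully configurable.
#'
#' @param estimate ICC estimate(s) in \[-1, 1\].
#' @param bins Named numeric vector of strictly increasing lower bin
#'   edges; the first edge should be `-Inf`.
#' @return Character vector of labels.
#' @examples
#' classify_icc(c(0.8, 0.65, 0.38, 0.1))
#' @export
classify_icc <- function(estimate,
                         bins = c(poor = -Inf, fair = 0.25, good = 0.40,
                                  excellent = 0.75)) {
  if (is.null(names(bins)) || any(names(bins) == "") ||
      is.unsorted(bins, strictly = TRUE)) {
    abort("`bins` must be a named vector of strictly increasing lower edges",
      class = "reliwear_config_error")
  }
  if (any(estimate < -1 | estimate > 1, na.rm = TRUE)) {
    abort("ICC estimates must lie in [-1, 1]", class = "reliwear_config_error")
  }
  names(bins)[findInterval(estimate, bins)]
}

#' ICC for each condition of a stream
#'
#' Convenience wrapper chaining [condition_means()],
#' [decompose_oneway()] and [icc_single()]/[icc_average()] for each metric
#' of a stream: participants are the random "targets" and the chosen
#' condition's levels the repeated measurement instances.
#'
#' @param stream A filtered `sample_stream`.
#' @param condition_key Grouping passed to [condition_means()].
#' @param form `"single"` or `"average"`.
#' @param confidence Confidence level.
#' @param tz Time zone for `condition_key = "day"`.
#' @return A tibble with one row per metric: `metric`, `icc`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `k`, `balanced`, `label`.
#' @export
icc_by_metric <- function(stream, condition_key, form = c("single", "average"),
                          confidence = 0.95, tz = "UTC") {
  form <- match.arg(form)
  df <- tibble::as_tibble(stream)
  purrr::map_dfr(sort(unique(df$metric)), function(m) {
    sub <- restream(df[df$metric == m, ], stream)
    cm <- condition_means(sub, condition_key = condition_key, tz = tz)
    dec <- decompose_oneway(cm)
    res <- if (form == "single") icc_single(dec, confidence)
      else icc_average(dec, confidence)
    dplyr::bind_cols(tibble::tibble(metric = m), tidy(res))
  })
}
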