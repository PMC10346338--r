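#' Tidy an ICC result
#'
#' @param x An `icc_result`.
#' @param ... Unused.
#' @return A one-row tibble: `icc`, `ci_low`, `ci_high`, `p_value`, `n`,
#'   `k`, `balanced`, `reliability` (the qualitative bin).
#' @exportS3Method generics::tidy
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    icc = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, n = x$n, k = x$k, balanced = x$balanced,
    reliability = x$label)
}

#' @rdname tidy.icc_result
#' @exportS3Method generics::glance
glance.icc_result <- function(x, ...) {
  tibble::tibble(
    form = x$form, confidence = x$confidence, f_stat = x$f_stat,
    df1 = x$df1, df2 = x$df2, n = x$n, k = x$k, balanced = x$balanced)
}

#' Tidy an ANOVA decomposition
#'
#' @param x An `anova_decomp`.
#' @param ... Unused.
#' @return A one-row tibble with the mean squares and design counts.
#' @exportS3Method generics::tidy
tidy.anova_decomp <- function(x, ...) {
  tibble::tibble(
    msbs = x$msbs, msws = x$msws, n = x$n, k = x$k,
    balanced = x$balanced, df_between = x$df_between,
    df_within = x$df_within, n_total = x$n_total)
}

#' Tidy a split-half mixed-model fit
#'
#' @param x A `split_half_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `beta`, `intercept`, `se`, `t_stat`, `df`,
#'   `p_value`, `converged`.
#' @exportS3Method generics::tidy
tidy.split_half_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, intercept = x$intercept, se = x$se,
    t_stat = x$t_stat, df = x$df, p_value = x$p_value,
    converged = x$converged)
}

#' @rdname tidy.split_half_fit
#' @exportS3Method generics::glance
glance.split_half_fit <- function(x, ...) {
  tibble::tibble(
    n_units = x$n_units,
    random_factors = paste(x$random_factors, collapse = "+"),
    converged = x$converged,
    note = paste(x$note, collapse = "; "))
}

#' Tidy a random-split beta distribution
#'
#' @param x A `beta_distribution`.
#' @param ... Unused.
#' @return A one-row tibble: `mean_beta`, `sd_beta`, the requested
#'   quantiles, `n_iterations`, `n_failed`.
#' @exportS3Method generics::tidy
tidy.beta_distribution <- function(x, ...) {
  q <- tibble::as_tibble(as.list(setNames(x$quantiles,
    paste0("q", sub("%", "", names(x$quantiles))))))
  dplyr::bind_cols(
    tibble::tibble(mean_beta = x$mean_beta, sd_beta = x$sd_beta), q,
    tibble::tibble(n_iterations = x$n_iterations, n_failed = x$n_failed))
}

#' @rdname tidy.beta_distribution
#' @exportS3Method generics::glance
glance.beta_distribution <- function(x, ...) {
  tibble::tibble(n_iterations = x$n_iterations, n_failed = x$n_failed,
    master_seed = x$master_seed)
}
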