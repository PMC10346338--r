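#' Plot the distribution of random-split slopes
#'
#' Histogram of the converged split-half slopes across random-split
#' iterations, with the mean slope (the reliability estimate) marked.
#'
#' @param object A `beta_distribution`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.beta_distribution <- function(object, bins = 40, ...) {
  df <- tibble::tibble(beta = object$betas)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_beta, colour = "firebrick",
      linewidth = 0.8) +
    ggplot2::labs(
      x = "split-half slope (beta)", y = "iterations",
      title = sprintf("Random-split reliability: mean beta = %.3f (SD %.3f)",
        object$mean_beta, object$sd_beta)) +
    ggplot2::theme_minimal()
}

#' Plot per-participant condition means
#'
#' One line per participant across conditions; parallel, well-separated
#' lines are the visual signature of high between-person reliability.
#'
#' @param object A `condition_means` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.condition_means <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$mean), ],
    ggplot2::aes(x = .data$condition, y = .data$mean,
      group = .data$participant_id, colour = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = attr(object, "condition_key"),
      y = paste("mean", attr(object, "metric") %||% "value"),
      colour = "participant") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of ICC estimates
#'
#' Point estimates with confidence intervals for a table of tidied ICC
#' results (e.g. the output of [icc_by_metric()] or a row-bound set of
#' `tidy()` results with a `label`-bearing grouping column).
#'
#' @param data A tibble with columns `icc`, `ci_low`, `ci_high` and a
#'   grouping column named by `group`.
#' @param group Name of the column labelling each row.
#' @return A ggplot object.
#' @export
plot_icc <- function(data, group = "metric") {
  df <- tibble::as_tibble(data)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data[[group]])) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
      xmax = .data$ci_high)) +
    ggplot2::geom_vline(xintercept = 0.75, linetype = "dashed",
      colour = "grey50") +
    ggplot2::labs(x = "ICC(1,1) with CI", y = NULL) +
    ggplot2::coord_cartesian(xlim = c(-0.1, 1)) +
    ggplot2::theme_minimal()
}
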