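# ggplot2 visualisations -------------------------------------------------------

#' @describeIn lorenz_curve Plot the Lorenz curve against the equality
#'   diagonal.
#' @param object A `lorenz_curve`.
#' @param ... Unused.
#' @export
autoplot.lorenz_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$L)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::geom_point(size = 0.8, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Cumulative share of units",
                  y = "Cumulative share of sampled population",
                  title = "Lorenz curve of sampling concentration") +
    ggplot2::theme_minimal()
}

#' @describeIn gini_permutation_test Histogram of the permutation null with
#'   the observed statistic marked.
#' @param object A `perm_test`.
#' @param ... Unused.
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey75", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#B2182B",
                        linewidth = 0.9) +
    ggplot2::labs(x = sprintf("%s under the null (%s)", object$statistic,
                              object$null_model),
                  y = "Replicates",
                  title = sprintf("Permutation test: observed = %.3f, p = %.3g",
                                  object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @describeIn score_table Mean quality score per publication year.
#' @param object A `quality_summary`.
#' @param ... Unused.
#' @export
autoplot.quality_summary <- function(object, ...) {
  if (is.null(object$by_year)) abort("no per-year summary available.")
  ggplot2::ggplot(object$by_year,
                  ggplot2::aes(x = .data$year, y = .data$mean_total)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7,
                        colour = "#2166AC") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "#B2182B", linewidth = 0.7) +
    ggplot2::labs(x = "Publication year", y = "Mean quality score (0-10)",
                  size = "Studies",
                  title = "Study quality over time") +
    ggplot2::theme_minimal()
}

#' @describeIn spline_gam_fit Observed points with the fitted semi-parametric
#'   curve.
#' @param object A `spline_gam`.
#' @param ... Unused.
#' @export
autoplot.spline_gam <- function(object, ...) {
  mf <- object$gam$model
  df <- tibble(x = mf$x %||% seq_along(object$fitted), y = mf$y,
               fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#B2182B",
                       linewidth = 0.9) +
    ggplot2::labs(x = "x", y = "y",
                  title = sprintf("Penalized-spline fit (edf = %.1f)",
                                  object$smooth_edf)) +
    ggplot2::theme_minimal()
}
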