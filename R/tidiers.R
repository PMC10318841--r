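# broom-style tidiers for the package's result objects ------------------------

#' @describeIn dagum_decomposition Pairwise module terms as a tibble.
#' @param x A `dagum_gini` object.
#' @param ... Unused.
#' @export
tidy.dagum_gini <- function(x, ...) x$pairwise

#' @describeIn dagum_decomposition One-row component summary.
#' @export
glance.dagum_gini <- function(x, ...) {
  tibble(G_total = x$G_total, G_within = x$G_within,
         G_between_net = x$G_between_net,
         G_transvariation = x$G_transvariation,
         n_units = x$n, n_modules = nrow(x$shares))
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed, p_value = x$p_value,
         alternative = x$alternative, B = x$null_samples,
         null_model = x$null_model, seed = x$seed)
}

#' @export
glance.perm_test <- function(x, ...) tidy(x)

#' @export
tidy.correlation_result <- function(x, ...) {
  tibble(estimate = x$rho, p_value = x$p_value,
         conf_low = x$ci95[1], conf_high = x$ci95[2],
         n = x$n, bf10 = x$bf10)
}

#' @export
glance.correlation_result <- function(x, ...) tidy(x)

#' @export
tidy.mk_trend <- function(x, ...) {
  tibble(S = x$S, var_S = x$var_S, statistic = x$Z, p_value = x$p_value,
         trend = x$trend, n = x$n)
}

#' @export
glance.mk_trend <- function(x, ...) tidy(x)

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("scale", "b"),
         estimate = c(x$scale, x$b),
         conf_low = c(NA, x$b_ci95[1]),
         conf_high = c(NA, x$b_ci95[2]))
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(b = x$b, conf_low = x$b_ci95[1], conf_high = x$b_ci95[2],
         r_squared = x$r2, n = x$n)
}

#' @export
tidy.spline_gam <- function(x, ...) {
  tibble(term = "x", estimate = x$linear_beta, std_error = x$linear_se,
         statistic = x$t_value, p_value = x$p_value)
}

#' @export
glance.spline_gam <- function(x, ...) {
  tibble(r_squared = x$r2, adj_r_squared = x$r2_adj,
         smooth_edf = x$smooth_edf, knots = x$knots, lambda = x$lambda)
}

#' @export
tidy.precision_weighted <- function(x, ...) x$details

#' @export
glance.precision_weighted <- function(x, ...) {
  tibble(weighted_mean = x$weighted_mean, unweighted_mean = x$unweighted_mean,
         conf_low = x$ci95[1], conf_high = x$ci95[2],
         n_studies = x$n_studies, weights_sum = x$weights_sum)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(statistic = x$stat_W, p_value = x$p_value, cohens_d = x$cohens_d,
         weighted_mean_A = unname(x$means["A"]),
         weighted_mean_B = unname(x$means["B"]),
         bf10 = x$bf10, n_A = unname(x$n["A"]), n_B = unname(x$n["B"]))
}

#' @export
glance.group_comparison <- function(x, ...) tidy(x)

#' @export
tidy.quality_summary <- function(x, ...) x$scores

#' @export
glance.quality_summary <- function(x, ...) {
  tibble(n_studies = nrow(x$scores), mean_total = x$mean_total,
         mean_stars = x$mean_stars, low_quality_share = x$low_quality_share)
}
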