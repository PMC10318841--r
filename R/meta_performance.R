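# Precision-weighted performance synthesis, case-control skewness, group
# contrasts between methodological strata -------------------------------------

#' Case-control skewness ratio
#'
#' Ratio of the larger to the smaller of the patient and control counts:
#' `max(n_patients, n_controls) / min(n_patients, n_controls)`. Always >= 1,
#' symmetric in its arguments; 1 means a perfectly balanced design.
#'
#' @param n_patients,n_controls Positive counts (vectorized).
#' @return Numeric vector of skewness ratios.
#' @export
#' @examples
#' case_control_skewness(60, 40)  # 1.5
case_control_skewness <- function(n_patients, n_controls) {
  if (any(is.na(n_patients)) || any(is.na(n_controls)) ||
      any(n_patients <= 0) || any(n_controls <= 0)) {
    abort("`n_patients` and `n_controls` must be positive counts.")
  }
  pmax(n_patients, n_controls) / pmin(n_patients, n_controls)
}

# Per-record precision weights: inverse variance of a binomial proportion at
# the study's evaluation-set size (n_test when coded, else n_total), with the
# proportion clipped to [0.5/n, 1 - 0.5/n] to avoid infinite weight at 0 or 1.
precision_weights <- function(p, n) {
  p_tilde <- pmin(pmax(p, 0.5 / n), 1 - 0.5 / n)
  list(weight = n / (p_tilde * (1 - p_tilde)), p_tilde = p_tilde)
}

weighting_n <- function(records) {
  n <- if ("n_test" %in% names(records)) records$n_test else rep(NA_real_, nrow(records))
  use_test <- !is.na(n) & n > 0
  n[!use_test] <- records$n_total[!use_test]
  list(n = as.numeric(n), basis = ifelse(use_test, "n_test", "n_total"))
}

#' Precision-weighted mean of a reported performance metric
#'
#' Inverse-variance synthesis of study-level proportions: each study is
#' weighted by \eqn{w_i = 1/\mathrm{SE}_i^2} with
#' \eqn{\mathrm{SE}_i = \sqrt{\tilde p_i (1-\tilde p_i)/n_i}}, where
#' \eqn{n_i} is the held-out test size when coded and the total sample size
#' otherwise. The 95% interval is a percentile bootstrap over studies.
#'
#' @param records Evidence-table subset (tibble) with the metric column and
#'   `n_total` (and optionally `n_test`).
#' @param metric Name of the proportion column to synthesize (default
#'   `"accuracy"`).
#' @param n_boot Bootstrap replicates for the CI (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `precision_weighted`: `n_studies`,
#'   `weighted_mean`, `unweighted_mean`, `weights_sum`, `ci95`, `metric`,
#'   plus a `details` tibble (per-study weight and weighting basis).
#' @export
precision_weighted_mean <- function(records, metric = "accuracy",
                                    n_boot = 1000, seed = 1) {
  records <- as_tibble(records)
  if (!metric %in% names(records)) {
    abort(sprintf("metric column `%s` not found.", metric))
  }
  keep <- !is.na(records[[metric]]) & !is.na(records$n_total)
  records <- records[keep, , drop = FALSE]
  if (!nrow(records)) abort("no usable records for precision weighting.")
  p <- records[[metric]]
  wn <- weighting_n(records)
  pw <- precision_weights(p, wn$n)
  w <- pw$weight
  wm <- sum(w * p) / sum(w)

  seed <- check_seed(seed)
  ci <- c(NA_real_, NA_real_)
  if (nrow(records) > 1L && n_boot >= 1) {
    idx <- with_seed(seed,
                     matrix(sample.int(length(p), length(p) * n_boot,
                                       replace = TRUE), ncol = n_boot))
    boots <- apply(idx, 2, function(i) sum(w[i] * p[i]) / sum(w[i]))
    ci <- unname(quantile(boots, c(0.025, 0.975), names = FALSE))
  } else if (nrow(records) == 1L) {
    ci <- c(wm, wm)
  }

  structure(list(
    n_studies = nrow(records),
    weighted_mean = wm,
    unweighted_mean = mean(p),
    weights_sum = sum(w),
    ci95 = ci,
    metric = metric,
    seed = seed,
    details = tibble(study_id = records$study_id %||% as.character(seq_along(p)),
                     value = p, n = wn$n, basis = wn$basis, weight = w)
  ), class = "precision_weighted")
}

#' @export
print.precision_weighted <- function(x, ...) {
  cat(sprintf(
    "Precision-weighted %s over %d studies: %.4f (unweighted %.4f; 95%% CI %.4f-%.4f)\n",
    x$metric, x$n_studies, x$weighted_mean, x$unweighted_mean,
    x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Contrast a performance metric between two methodological strata
#'
#' Wilcoxon rank-sum test on the raw metric values (exact null for small
#' untied samples, tie-corrected normal approximation otherwise), Cohen's d
#' on the unweighted values, precision-weighted means of both groups, and
#' (optionally) a two-sample JZS Bayes factor.
#'
#' @param groupA,groupB Evidence-table subsets (tibbles) to contrast.
#' @param metric Proportion column to compare (default `"accuracy"`).
#' @param seed Integer seed (bootstrap CIs of the weighted means).
#' @param bayes Compute a JZS two-sample Bayes factor (default `TRUE`)?
#' @param prior_scale Cauchy prior scale for the Bayes factor (default 0.34).
#' @return An object of class `group_comparison`: `stat_W`, `p_value`,
#'   `cohens_d`, `means` (precision-weighted means A then B), `bf10`,
#'   `n` (records used per group), `n_excluded` (records without the metric).
#' @export
compare_groups <- function(groupA, groupB, metric = "accuracy", seed = 1,
                           bayes = TRUE, prior_scale = 0.34) {
  groupA <- as_tibble(groupA); groupB <- as_tibble(groupB)
  if (!nrow(groupA) || !nrow(groupB)) abort("both groups must be nonempty.")
  xa <- groupA[[metric]]; xb <- groupB[[metric]]
  excluded <- sum(is.na(xa)) + sum(is.na(xb))
  if (excluded > 0) {
    message(sprintf("compare_groups: excluded %d record(s) without `%s`.",
                    excluded, metric))
  }
  a <- groupA[!is.na(xa), , drop = FALSE]; b <- groupB[!is.na(xb), , drop = FALSE]
  xa <- a[[metric]]; xb <- b[[metric]]
  if (!length(xa) || !length(xb)) abort("a group has no usable metric values.")

  # exact null for small untied samples, tie-corrected normal approx otherwise
  wt <- suppressWarnings(wilcox.test(xa, xb, correct = TRUE))
  pooled_sd <- sqrt(((length(xa) - 1) * var_or_zero(xa) +
                       (length(xb) - 1) * var_or_zero(xb)) /
                      (length(xa) + length(xb) - 2))
  d <- if (pooled_sd > 0) (mean(xa) - mean(xb)) / pooled_sd else 0

  pw_a <- precision_weighted_mean(a, metric, seed = seed)
  pw_b <- precision_weighted_mean(b, metric, seed = seed + 1L)

  bf <- NA_real_
  if (bayes && length(xa) > 1L && length(xb) > 1L && pooled_sd > 0) {
    tstat <- (mean(xa) - mean(xb)) /
      (pooled_sd * sqrt(1 / length(xa) + 1 / length(xb)))
    bf <- jzs_bayes_factor("two_sample", t = tstat, n1 = length(xa),
                           n2 = length(xb), prior_scale = prior_scale)
  }

  structure(list(
    stat_W = unname(wt$statistic),
    p_value = wt$p.value,
    cohens_d = d,
    means = c(A = pw_a$weighted_mean, B = pw_b$weighted_mean),
    precision_weighted = list(A = pw_a, B = pw_b),
    bf10 = bf,
    metric = metric,
    n = c(A = length(xa), B = length(xb)),
    n_excluded = excluded
  ), class = "group_comparison")
}

var_or_zero <- function(x) if (length(x) > 1L) var(x) else 0

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Rank-sum contrast on %s: W = %s, p = %.3g, d = %.3f\n  weighted means: A = %.4f, B = %.4f%s\n",
    x$metric, format(x$stat_W, big.mark = ","), x$p_value, x$cohens_d,
    x$means[["A"]], x$means[["B"]],
    if (is.finite(x$bf10)) sprintf(", BF10 = %.3g", x$bf10) else ""))
  invisible(x)
}
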