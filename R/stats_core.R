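# Shared inferential machinery: Spearman + bootstrap, permutation correlation,
# Mann-Kendall trend, exponential growth fits, JZS Bayes factors, penalized
# spline regression ------------------------------------------------------------

#' Spearman correlation with bootstrap confidence interval
#'
#' Rank correlation (mid-ranks for ties) with the asymptotic two-sided
#' p-value and a percentile bootstrap CI over paired resamples. Optionally
#' attaches a JZS Bayes factor for the correlation.
#'
#' @param x,y Numeric vectors of equal length (>= 4).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param bayes Attach a JZS correlation Bayes factor (default `TRUE`)?
#' @param prior_scale Cauchy prior width for the Bayes factor (default 0.34).
#' @return An object of class `correlation_result`: `rho`, `p_value`, `ci95`,
#'   `n`, `n_boot`, `seed`, `bf10`.
#' @export
#' @examples
#' spearman_bootstrap(1:4, c(1, 3, 2, 4), n_boot = 200, seed = 1)$rho  # 0.8
spearman_bootstrap <- function(x, y, n_boot = 1000, seed = 1, bayes = TRUE,
                               prior_scale = 0.34) {
  check_paired(x, y)
  seed <- check_seed(seed)
  rho <- cor(x, y, method = "spearman")
  p <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE)$p.value)

  n <- length(x)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(cor(x[idx], y[idx], method = "spearman"))
  }, 1))
  boots <- boots[is.finite(boots)]
  ci <- if (length(boots) >= 2) {
    unname(quantile(boots, c(0.025, 0.975), names = FALSE))
  } else c(NA_real_, NA_real_)

  bf <- if (bayes) jzs_bayes_factor("correlation", r = rho, n = n,
                                    prior_scale = prior_scale) else NA_real_

  structure(list(rho = rho, p_value = p, ci95 = ci, n = n,
                 n_boot = n_boot, seed = seed, bf10 = bf),
            class = "correlation_result")
}

check_paired <- function(x, y, min_n = 4L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < min_n) abort(sprintf("need at least %d paired observations.", min_n))
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must not contain missing values.")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for a constant vector.")
  invisible(NULL)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d), p = %.3g, 95%% CI %.3f to %.3f%s\n",
              x$rho, x$n, x$p_value, x$ci95[1], x$ci95[2],
              if (is.finite(x$bf10)) sprintf(", BF10 = %.3g", x$bf10) else ""))
  invisible(x)
}

#' Permutation test for a rank correlation
#'
#' Builds the null by permuting `y`, recomputing the Spearman correlation for
#' each of `B` permutations; the p-value uses the add-one correction. The
#' two-sided alternative counts `|rho*| >= |rho|`, which doubles the
#' one-tailed p (capped at 1) for symmetric nulls.
#'
#' @inheritParams spearman_bootstrap
#' @param B Number of permutations (default 10000).
#' @param alternative `"greater"`, `"less"`, or `"two_sided"` (default).
#' @return An object of class `perm_test`.
#' @export
permutation_correlation <- function(x, y, B = 10000, seed = 1,
                                    alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_paired(x, y)
  if (!is.numeric(B) || length(B) != 1L || B < 1) abort("`B` must be >= 1.")
  B <- as.integer(B)
  seed <- check_seed(seed)

  rx <- rank(x); ry <- rank(y)
  observed <- cor(rx, ry)
  null_stats <- with_seed(seed,
                          vapply(seq_len(B), function(i) cor(rx, sample(ry)), 1))

  p <- switch(alternative,
    greater   = (1 + sum(null_stats >= observed)) / (B + 1),
    less      = (1 + sum(null_stats <= observed)) / (B + 1),
    two_sided = (1 + sum(abs(null_stats) >= abs(observed))) / (B + 1))

  structure(list(observed = observed, p_value = p, null_samples = B,
                 null = null_stats, alternative = alternative,
                 null_model = "permute_y", seed = seed,
                 statistic = "spearman_rho"),
            class = "perm_test")
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotonic-trend test for a time-ordered series:
#' \eqn{S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)}, tie-corrected variance
#' \eqn{\mathrm{var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18} over tie
#' groups of size t, and a continuity-corrected normal deviate Z with a
#' two-sided p-value.
#'
#' @param series Numeric vector in time order (length >= 3).
#' @param alpha Significance level used to label the trend (default 0.05).
#' @return An object of class `mk_trend`: `S`, `var_S`, `Z`, `p_value`,
#'   `trend` (`"increasing"`, `"decreasing"`, `"none"`), `n`.
#' @export
#' @examples
#' mann_kendall(c(1, 2, 3, 4, 5))$S  # 10
mann_kendall <- function(series, alpha = 0.05) {
  if (anyNA(series) || !is.numeric(series)) abort("`series` must be numeric without NA.")
  n <- length(series)
  if (n < 3L) abort("`series` must have length >= 3.")
  S <- 0L
  for (i in seq_len(n - 1L)) {
    S <- S + sum(sign(series[(i + 1L):n] - series[i]))
  }
  ties <- table(series)
  ties <- ties[ties > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- 2 * pnorm(-abs(Z))
  trend <- if (p < alpha && S > 0) "increasing"
           else if (p < alpha && S < 0) "decreasing" else "none"
  structure(list(S = as.integer(S), var_S = var_S, Z = Z, p_value = p,
                 trend = trend, n = n),
            class = "mk_trend")
}

#' @export
print.mk_trend <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %d, Z = %.2f, p = %.3g (%s trend, n = %d)\n",
              x$S, x$Z, x$p_value, x$trend, x$n))
  invisible(x)
}

#' Exponential growth fit for yearly counts
#'
#' Fits \eqn{k = a\,e^{b\tilde t}} on centered time by nonlinear least
#' squares, started from the log-linear regression on the positive counts.
#' Returns the rate `b` with a Wald 95% CI.
#'
#' @param t Numeric vector of years.
#' @param k Nonnegative counts per year (same length, >= 3 points).
#' @return An object of class `growth_fit`: `b`, `b_ci95`, `scale` (the
#'   amplitude `a`), `r2`, `fitted`, `n`.
#' @export
exp_growth_fit <- function(t, k) {
  if (length(t) != length(k)) abort("`t` and `k` must have equal length.")
  if (length(t) < 3L) abort("need at least 3 points.")
  if (anyNA(t) || anyNA(k)) abort("`t` and `k` must not contain NA.")
  if (any(k < 0)) abort("counts must be nonnegative.")
  if (all(k == 0)) abort("all counts are zero; growth rate undefined.")
  tt <- t - mean(t)
  pos <- k > 0
  start <- if (sum(pos) >= 2 && sd(tt[pos]) > 0) {
    cf <- coef(lm(log(k[pos]) ~ tt[pos]))
    list(a = exp(cf[[1]]), b = cf[[2]])
  } else list(a = mean(k), b = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(k ~ a * exp(b * tt), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- coef(fit)
    se_b <- sqrt(diag(vcov(fit)))[["b"]]
    fitted_k <- as.numeric(stats::fitted(fit))
  } else {
    # degenerate (e.g. exact-fit) data: the log-linear start is the optimum;
    # use it with a linearized (Gauss-Newton) covariance
    est <- c(a = start$a, b = start$b)
    fitted_k <- est[["a"]] * exp(est[["b"]] * tt)
    J <- cbind(exp(est[["b"]] * tt), est[["a"]] * tt * exp(est[["b"]] * tt))
    sigma2 <- sum((k - fitted_k)^2) / max(1, length(k) - 2)
    se_b <- sqrt(pmax(0, sigma2 * diag(solve(crossprod(J)))))[2]
  }
  ss_res <- sum((k - fitted_k)^2)
  ss_tot <- sum((k - mean(k))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(b = est[["b"]],
                 b_ci95 = est[["b"]] + c(-1, 1) * qnorm(0.975) * se_b,
                 scale = est[["a"]], r2 = r2,
                 fitted = fitted_k, n = length(k)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth: b = %.3f (95%% CI %.3f to %.3f), R2 = %.3f\n",
              x$b, x$b_ci95[1], x$b_ci95[2], x$r2))
  invisible(x)
}

#' Jeffreys-Zellner-Siow Bayes factor
#'
#' Default Bayes factor with a Cauchy prior on the standardized effect,
#' computed by numerical integration of the JZS marginal likelihood ratio.
#' For `kind = "two_sample"` this is the Rouder et al. two-sample t form with
#' effective sample size \eqn{N = n_1 n_2/(n_1+n_2)}; for
#' `kind = "correlation"` the one-regressor g-prior form evaluated at the
#' observed Pearson/Spearman coefficient, generalized to an arbitrary prior
#' scale. `BF10 > 1` favors the presence of an effect; `BF01 = 1/BF10`.
#'
#' @param kind `"correlation"` or `"two_sample"`.
#' @param r Observed correlation (for `kind = "correlation"`).
#' @param n Sample size of the correlation (>= 4).
#' @param t Observed t statistic (for `kind = "two_sample"`; alternatively
#'   supply raw samples `x` and `y`).
#' @param n1,n2 Group sizes for the two-sample case.
#' @param x,y Optional raw group samples (pooled-variance t is computed).
#' @param prior_scale Cauchy prior scale (default 0.34).
#' @return A single number, BF10.
#' @export
#' @examples
#' jzs_bayes_factor("correlation", r = 0.5, n = 40)
jzs_bayes_factor <- function(kind = c("correlation", "two_sample"),
                             r = NULL, n = NULL, t = NULL, n1 = NULL, n2 = NULL,
                             x = NULL, y = NULL, prior_scale = 0.34) {
  kind <- match.arg(kind)
  if (!is.numeric(prior_scale) || prior_scale <= 0) {
    abort("`prior_scale` must be positive.")
  }
  if (kind == "correlation") {
    if (is.null(r) || is.null(n)) abort("correlation BF needs `r` and `n`.")
    if (n < 4) abort("`n` must be >= 4.")
    if (abs(r) >= 1) r <- sign(r) * (1 - 1e-12)
    return(jzs_bf_correlation(r, n, prior_scale))
  }
  if (!is.null(x) && !is.null(y)) {
    n1 <- length(x); n2 <- length(y)
    sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
    t <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
  }
  if (is.null(t) || is.null(n1) || is.null(n2)) {
    abort("two-sample BF needs `t`, `n1`, `n2` (or raw `x`, `y`).")
  }
  jzs_bf_two_sample(t, n1, n2, prior_scale)
}

# Liang et al. one-regressor g-prior marginal, Cauchy(0, s) on the
# standardized slope via g ~ InvGamma(1/2, n s^2 / 2):
# BF10 = int (1+g)^((n-2)/2) (1+(1-r^2) g)^(-(n-1)/2) pi(g) dg
jzs_bf_correlation <- function(r, n, s) {
  b <- n * s^2 / 2
  log_dens <- function(g) {
    0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g
  }
  integrand <- function(g) {
    exp(((n - 2) / 2) * log1p(g) - ((n - 1) / 2) * log1p((1 - r^2) * g) +
          log_dens(g))
  }
  quad_0_inf(integrand)
}

# Rouder et al. (2009) JZS two-sample BF with Cauchy(0, s) prior on delta:
# g ~ InvGamma(1/2, s^2/2), effective N = n1 n2 / (n1 + n2).
jzs_bf_two_sample <- function(t, n1, n2, s) {
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  b <- s^2 / 2
  log_dens <- function(g) 0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g
  log_h0 <- -((nu + 1) / 2) * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(N * g) -
          ((nu + 1) / 2) * log1p(t^2 / ((1 + N * g) * nu)) +
          log_dens(g) - log_h0)
  }
  quad_0_inf(integrand)
}

quad_0_inf <- function(f) {
  out <- tryCatch(
    integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 2000L),
    error = function(e) NULL)
  if (is.null(out) || out$message != "OK") {
    # fall back to a transformed grid u = g/(1+g)
    u <- seq(1e-8, 1 - 1e-8, length.out = 100000L)
    g <- u / (1 - u)
    vals <- f(g) / (1 - u)^2
    if (any(!is.finite(vals))) {
      abort("JZS Bayes factor integration failed to converge.")
    }
    return(sum((vals[-1] + vals[-length(vals)]) / 2) * diff(u[1:2]))
  }
  out$value
}

#' Semi-parametric spline regression (linear term + penalized smooth)
#'
#' Fits \eqn{y = \alpha + \beta x + f(x) + \varepsilon} where `f` is a
#' penalized cubic B-spline (P-spline, second-order difference penalty) whose
#' basis is constrained orthogonal to \eqn{\{1, x\}}, so the linear slope
#' \eqn{\beta} is estimable next to the smooth. Smoothing is chosen by GCV
#' via [mgcv::gam()]. `mode = "smooth_only"` drops the separate linear term
#' and centers the smooth only.
#'
#' @param x,y Numeric vectors (>= 8 points).
#' @param k Number of B-spline basis functions before constraint (default 10).
#' @param mode `"linear_plus_smooth"` (default) or `"smooth_only"`.
#' @return An object of class `spline_gam`: `linear_beta`, `linear_se`,
#'   `t_value`, `p_value`, `r2`, `r2_adj`, `smooth_edf`, `knots`, `lambda`,
#'   `fitted`, and the underlying `gam` fit.
#' @export
spline_gam_fit <- function(x, y, k = 10,
                           mode = c("linear_plus_smooth", "smooth_only")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must not contain NA.")
  if (length(x) < 8L) abort("need at least 8 points.")
  if (k < 5L) abort("basis dimension `k` must be >= 5.")
  if (length(x) < k + 2L) {
    abort(sprintf(
      "too few points (%d) for a %d-function basis; reduce `k`.", length(x), k))
  }

  B <- pspline_basis(x, k)
  D <- diff(diag(k), differences = 2L)
  S <- crossprod(D)

  Cmat <- if (mode == "linear_plus_smooth") cbind(1, x) else cbind(rep(1, length(x)))
  Ct <- crossprod(Cmat, B)                       # constraints Ct %*% beta = 0
  qrC <- qr(t(Ct))
  Znull <- qr.Q(qrC, complete = TRUE)[, (nrow(Ct) + 1L):k, drop = FALSE]
  BZ <- B %*% Znull
  SZ <- crossprod(Znull, S %*% Znull)

  dat <- data.frame(y = y, x = x)
  dat$BZ <- BZ
  fit <- if (mode == "linear_plus_smooth") {
    mgcv::gam(y ~ x + BZ, data = dat, paraPen = list(BZ = list(SZ)),
              method = "GCV.Cp")
  } else {
    mgcv::gam(y ~ BZ, data = dat, paraPen = list(BZ = list(SZ)),
              method = "GCV.Cp")
  }

  smry <- summary(fit)
  idx <- grep("^BZ", names(coef(fit)))
  smooth_edf <- sum(fit$edf[idx])
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)

  beta <- se <- tval <- pval <- NA_real_
  if (mode == "linear_plus_smooth") {
    pt <- smry$p.table
    beta <- pt["x", "Estimate"]; se <- pt["x", "Std. Error"]
    tval <- pt["x", "t value"]; pval <- pt["x", "Pr(>|t|)"]
  }

  structure(list(
    linear_beta = beta, linear_se = se, t_value = tval, p_value = pval,
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    r2_adj = smry$r.sq,
    smooth_edf = smooth_edf,
    knots = k,
    lambda = if (length(fit$sp)) unname(fit$sp[1]) else NA_real_,
    fitted = as.numeric(stats::fitted(fit)),
    mode = mode,
    gam = fit
  ), class = "spline_gam")
}

pspline_basis <- function(x, k, degree = 3L) {
  rng <- range(x)
  if (diff(rng) == 0) abort("`x` is constant; no spline basis possible.")
  n_inner <- k - degree - 1L
  dx <- diff(rng) / (n_inner + 1L)
  knots <- seq(rng[1] - degree * dx, rng[2] + degree * dx, by = dx)
  splines::splineDesign(knots, x, ord = degree + 1L, outer.ok = TRUE)
}

#' @export
print.spline_gam <- function(x, ...) {
  if (x$mode == "linear_plus_smooth") {
    cat(sprintf(
      "Spline regression: beta = %.4f (SE %.4f, t = %.2f, p = %.3g); smooth edf = %.2f; adj. R2 = %.3f\n",
      x$linear_beta, x$linear_se, x$t_value, x$p_value, x$smooth_edf, x$r2_adj))
  } else {
    cat(sprintf("Pure-smooth fit: edf = %.2f, adj. R2 = %.3f\n",
                x$smooth_edf, x$r2_adj))
  }
  invisible(x)
}
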