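# Lorenz/Gini machinery: classic Gini, Dagum decomposition, Theil index,
# permutation inference --------------------------------------------------------

#' Gini coefficient
#'
#' Mean absolute pairwise difference normalized by twice the mean,
#' \eqn{G = \sum_i\sum_j |y_i - y_j| / (2 n^2 \bar y)}, computed via the exact
#' sorted-rank identity \eqn{G = 2\sum_i i\,y_{(i)}/(n\sum y) - (n+1)/n}.
#' Ranges from 0 (perfect equality) to \eqn{(n-1)/n} (all mass in one unit).
#'
#' @param values Nonnegative numeric vector (length >= 2, positive mean), or a
#'   grouped-sample tibble with a `value` column.
#' @return A single number in `[0, (n-1)/n]`.
#' @export
#' @examples
#' gini(c(1, 3))        # 0.25
#' gini(c(0, 0, 0, 1))  # 0.75
gini <- function(values) {
  values <- grouped_values(values)
  check_values(values, "values", min_n = 2L)
  n <- length(values)
  y <- sort(values)
  2 * sum(seq_len(n) * y) / (n * sum(y)) - (n + 1) / n
}

grouped_values <- function(x) {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) abort("grouped sample must have a `value` column.")
    return(as.numeric(x$value))
  }
  as.numeric(x)
}

#' Lorenz curve
#'
#' Cumulative value share against cumulative population share on ascending
#' sorted values. The trapezoidal area `A` under the returned polygon
#' satisfies `gini(values) == 1 - 2A` exactly.
#'
#' @inheritParams gini
#' @return A tibble of class `lorenz_curve` with columns `p` (cumulative
#'   population share) and `L` (cumulative value share), starting at (0, 0)
#'   and ending at (1, 1).
#' @export
#' @examples
#' lorenz_curve(c(1, 3))
lorenz_curve <- function(values) {
  values <- grouped_values(values)
  check_values(values, "values", min_n = 1L)
  y <- sort(values)
  n <- length(y)
  out <- tibble(p = c(0, seq_len(n) / n), L = c(0, cumsum(y) / sum(y)))
  class(out) <- c("lorenz_curve", class(out))
  out
}

#' Theil entropy index
#'
#' \eqn{T = \frac1n \sum_i \frac{y_i}{\bar y}\ln\frac{y_i}{\bar y}} with the
#' convention \eqn{0\ln 0 = 0}. Zero iff all values are equal; at most
#' \eqn{\ln n}.
#'
#' @inheritParams gini
#' @return A single nonnegative number.
#' @export
#' @examples
#' theil_index(c(1, 3))  # 0.1308063
theil_index <- function(values) {
  values <- grouped_values(values)
  check_values(values, "values", min_n = 2L)
  r <- values / mean(values)
  pos <- r > 0 # zero values contribute 0 * log 0 := 0
  sum(r[pos] * log(r[pos])) / length(r)
}

#' Dagum three-component decomposition of the Gini coefficient
#'
#' Splits the pooled Gini over labeled subgroups ("modules", e.g. MEDC/LEDC
#' economic blocs) into within-module inequality \eqn{G_w}, net between-module
#' inequality \eqn{G_{nb}}, and transvariation \eqn{G_t} (the part of
#' between-module differences due to overlap of the module distributions),
#' with \eqn{G = G_w + G_{nb} + G_t} exactly. Pairwise terms follow Dagum's
#' convention: for each module pair the richer module (larger mean) leads, so
#' the relative economic affluence \eqn{D_{jh} = (d_{jh}-p_{jh})/(d_{jh}+p_{jh})}
#' lies in `[0, 1]`; identical modules (\eqn{d_{jh}+p_{jh}=0}) take
#' \eqn{D_{jh}=0} by continuity.
#'
#' @param grouped A tibble with columns `unit`, `value`, `module` (see
#'   [aggregate_sample_by_unit()]), or a named list of numeric vectors.
#' @return An object of class `dagum_gini`: a list with elements `G_total`,
#'   `G_within`, `G_between_net`, `G_transvariation`, `pairwise` (tibble of
#'   `module_j`, `module_h`, `G_jh`, `d_jh`, `p_jh`, `D_jh`), `shares`
#'   (per-module population share `p_j`, value share `s_j`, mean, `G_jj`),
#'   and `n`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' g <- dagum_decomposition(tibble::tibble(
#'   unit = c("a", "b", "c", "d"), value = c(1, 3, 2, 4),
#'   module = c("A", "A", "B", "B")))
#' glance(g)
dagum_decomposition <- function(grouped) {
  if (is.list(grouped) && !is.data.frame(grouped)) {
    grouped <- dplyr::bind_rows(lapply(names(grouped), function(m) {
      tibble(unit = paste0(m, "_", seq_along(grouped[[m]])),
             value = as.numeric(grouped[[m]]), module = m)
    }))
  }
  stopifnot(is.data.frame(grouped), all(c("value", "module") %in% names(grouped)))
  values <- as.numeric(grouped$value)
  check_values(values, "values", min_n = 2L)
  modules <- split(values, grouped$module)
  if (any(vapply(modules, length, 1L) == 0L)) abort("every module must be nonempty.")

  n <- length(values)
  ybar <- mean(values)
  means <- vapply(modules, mean, 1)
  # richer module first: guarantees D_jh in [0, 1]
  ord <- order(means, decreasing = TRUE)
  modules <- modules[ord]
  means <- means[ord]
  k <- length(modules)
  n_j <- vapply(modules, length, 1L)
  p_j <- n_j / n
  s_j <- n_j * means / (n * ybar)

  G_jj <- vapply(modules, function(y) {
    if (mean(y) == 0) return(0)
    mean_abs_diff(y, y) / (2 * mean(y))
  }, 1)
  G_within <- sum(G_jj * p_j * s_j)

  pairwise <- NULL
  G_nb <- 0
  G_t <- 0
  if (k >= 2L) {
    pairs <- utils::combn(k, 2L)
    pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      j <- pairs[1, i]; h <- pairs[2, i]  # j has the larger mean
      yj <- modules[[j]]; yh <- modules[[h]]
      diffs <- outer(yj, yh, "-")
      d_jh <- mean(pmax(diffs, 0))   # gross affluence: richer over poorer
      p_jh <- mean(pmax(-diffs, 0))  # first-order moment of transvariation
      G_jh <- if (means[j] + means[h] > 0) {
        mean(abs(diffs)) / (means[j] + means[h])
      } else 0
      D_jh <- if (d_jh + p_jh > 0) (d_jh - p_jh) / (d_jh + p_jh) else 0
      tibble(module_j = names(modules)[j], module_h = names(modules)[h],
             G_jh = unname(G_jh), d_jh = d_jh, p_jh = p_jh, D_jh = unname(D_jh),
             weight = unname(p_j[j] * s_j[h] + p_j[h] * s_j[j]))
    })
    G_nb <- sum(pairwise$G_jh * pairwise$weight * pairwise$D_jh)
    G_t <- sum(pairwise$G_jh * pairwise$weight * (1 - pairwise$D_jh))
  } else {
    pairwise <- tibble(module_j = character(), module_h = character(),
                       G_jh = double(), d_jh = double(), p_jh = double(),
                       D_jh = double(), weight = double())
  }

  structure(list(
    G_total = gini(values),
    G_within = G_within,
    G_between_net = G_nb,
    G_transvariation = G_t,
    pairwise = pairwise,
    shares = tibble(module = names(modules), n_j = unname(n_j),
                    mean = unname(means), p_j = unname(p_j),
                    s_j = unname(s_j), G_jj = unname(G_jj)),
    n = n
  ), class = "dagum_gini")
}

mean_abs_diff <- function(x, y) {
  # E|X - Y| over all cross pairs without forming the outer matrix when large
  if (length(x) * length(y) <= 4e6) return(mean(abs(outer(x, y, "-"))))
  xs <- sort(x)
  total <- 0
  for (v in y) {
    lo <- sum(xs < v)
    total <- total + (lo * v - sum(xs[seq_len(lo)])) +
      (sum(xs) - sum(xs[seq_len(lo)]) - (length(xs) - lo) * v)
  }
  total / (length(x) * length(y))
}

#' @export
print.dagum_gini <- function(x, ...) {
  cat("Dagum-Gini decomposition (", x$n, " units, ",
      nrow(x$shares), " modules)\n", sep = "")
  cat(sprintf("  G_total          %.4f\n", x$G_total))
  cat(sprintf("  G_within         %.4f (%.1f%%)\n", x$G_within,
              100 * x$G_within / x$G_total))
  cat(sprintf("  G_between_net    %.4f (%.1f%%)\n", x$G_between_net,
              100 * x$G_between_net / x$G_total))
  cat(sprintf("  G_transvariation %.4f (%.1f%%)\n", x$G_transvariation,
              100 * x$G_transvariation / x$G_total))
  invisible(x)
}

#' Permutation test for sampling inequality
#'
#' Tests the observed Gini of a per-unit sample allocation against a null of
#' no sampling inequality. The default null reallocates the (rounded) grand
#' total across units by an equal-probability multinomial; the
#' `"dirichlet_uniform"` null draws continuous shares from a flat Dirichlet.
#' The p-value uses the add-one correction \eqn{p = (1 + \#\{G^* \ge G\}) /
#' (B + 1)} so it is never exactly zero.
#'
#' @param grouped Grouped sample tibble (or numeric vector of unit values).
#' @param B Number of null replicates (default 10000).
#' @param seed Integer seed (mandatory; recorded in the result).
#' @param null_model `"multinomial"` (default) or `"dirichlet_uniform"`.
#' @param alternative `"greater"` (default; inequality larger than null),
#'   `"less"`, or `"two_sided"`.
#' @return An object of class `perm_test` with `observed`, `p_value`,
#'   `null_samples` (= `B`), `null` (the null statistics), `alternative`,
#'   `null_model`, `seed`.
#' @export
#' @examples
#' g <- tibble::tibble(unit = letters[1:5], value = c(100, 2, 1, 1, 1),
#'                     module = "all")
#' gini_permutation_test(g, B = 199, seed = 7)
gini_permutation_test <- function(grouped, B = 10000, seed,
                                  null_model = c("multinomial", "dirichlet_uniform"),
                                  alternative = c("greater", "less", "two_sided")) {
  null_model <- match.arg(null_model)
  alternative <- match.arg(alternative)
  if (!is.numeric(B) || length(B) != 1L || B < 1) abort("`B` must be >= 1.")
  B <- as.integer(B)
  seed <- check_seed(seed)
  values <- grouped_values(grouped)
  check_values(values, "values", min_n = 2L)
  k <- length(values)
  observed <- gini(values)

  null_stats <- with_seed(seed, {
    if (null_model == "multinomial") {
      total <- max(1L, round(sum(values)))
      draws <- rmultinom(B, total, rep(1 / k, k))
      apply(draws, 2, gini)
    } else {
      g <- matrix(rgamma(B * k, shape = 1), nrow = k)
      apply(g, 2, gini)
    }
  })

  p_greater <- (1 + sum(null_stats >= observed)) / (B + 1)
  p_less <- (1 + sum(null_stats <= observed)) / (B + 1)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two_sided = min(1, 2 * min(p_greater, p_less)))

  structure(list(observed = observed, p_value = p, null_samples = B,
                 null = null_stats, alternative = alternative,
                 null_model = null_model, seed = seed,
                 statistic = "gini"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed = %.4f, p = %.4g (%s, B = %d, seed = %d)\n",
              x$statistic, x$observed, x$p_value, x$alternative,
              x$null_samples, x$seed))
  invisible(x)
}
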