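# Independent oracles and fixture builders used across the suite.

# O(n^2) double-sum Gini, straight from the definition.
gini_brute <- function(y) {
  n <- length(y)
  sum(abs(outer(y, y, "-"))) / (2 * n^2 * mean(y))
}

# Sorted-rank identity, independent derivation.
gini_rank <- function(y) {
  n <- length(y)
  ys <- sort(y)
  2 * sum(seq_len(n) * ys) / (n * sum(ys)) - (n + 1) / n
}

# Mann-Kendall S by exhaustive pair enumeration.
mk_S_brute <- function(x) {
  s <- 0L
  n <- length(x)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) s <- s + sign(x[j] - x[i])
  }
  as.integer(s)
}

# Fine-grid trapezoid quadrature oracle for the JZS integrals, independent of
# stats::integrate. Integrates over u = g / (1 + g) in (0, 1).
bf_grid_oracle <- function(log_integrand, n_grid = 2e5) {
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- u / (1 - u)
  v <- exp(log_integrand(g)) / (1 - u)^2
  sum((v[-1] + v[-length(v)]) / 2) * (u[2] - u[1])
}

bf_corr_oracle <- function(r, n, s = 0.34) {
  b <- n * s^2 / 2
  bf_grid_oracle(function(g) {
    ((n - 2) / 2) * log1p(g) - ((n - 1) / 2) * log1p((1 - r^2) * g) +
      0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g
  })
}

bf_two_sample_oracle <- function(t, n1, n2, s = 0.34) {
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  b <- s^2 / 2
  log_h0 <- -((nu + 1) / 2) * log1p(t^2 / nu)
  bf_grid_oracle(function(g) {
    -0.5 * log1p(N * g) - ((nu + 1) / 2) * log1p(t^2 / ((1 + N * g) * nu)) +
      0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g - log_h0
  })
}

# Random grouped sample with 2-4 modules and heavy-tailed positive values.
random_grouped_sample <- function() {
  k <- sample(2:4, 1)
  sizes <- sample(2:8, k, replace = TRUE)
  dplyr::bind_rows(lapply(seq_len(k), function(j) {
    tibble::tibble(
      unit = paste0("m", j, "_", seq_len(sizes[j])),
      value = rlnorm(sizes[j], meanlog = runif(1, 0, 3), sdlog = runif(1, 0.2, 1.5)),
      module = paste0("M", j))
  }))
}

# All permutations of 1:n as rows (n! x n matrix), by recursion.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# Minimal valid evidence rows for IO tests.
make_evidence_df <- function(n = 3) {
  tibble::tibble(
    study_id = sprintf("S%02d", seq_len(n)),
    year = 2010L + seq_len(n),
    disorder = "SZ",
    sample_country = rep(c("CN", "US"), length.out = n),
    economic_bloc = "MEDC",
    cv_scheme = rep(c("LOOCV", "kfold", "none"), length.out = n),
    external_validation = "none",
    n_patients = 30L + seq_len(n),
    n_controls = 25L + seq_len(n),
    n_total = 55L + 2L * seq_len(n),
    n_sites = 1L,
    accuracy = 0.7 + 0.02 * seq_len(n),
    sensitivity = 0.72,
    specificity = NA_real_,
    balanced_accuracy = NA_real_,
    auc = NA_real_,
    reported_metrics = "sensitivity",
    data_claimed = FALSE, data_verified = FALSE,
    model_claimed = FALSE, model_verified = FALSE
  )
}
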