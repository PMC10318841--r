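test_that("spearman correlation handles monotone, anti-monotone and tied cases", {
  x <- c(0.3, 1.1, 2.7, 3.2, 5.9)
  expect_equal(spearman_bootstrap(x, 2 * x + 1, n_boot = 50, seed = 1,
                                  bayes = FALSE)$rho, 1)
  expect_equal(spearman_bootstrap(x, -x^3, n_boot = 50, seed = 1,
                                  bayes = FALSE)$rho, -1)
  r <- spearman_bootstrap(1:4, c(1, 3, 2, 4), n_boot = 100, seed = 1,
                          bayes = FALSE)
  expect_equal(r$rho, 0.8) # 1 - 6*2/(4*15)
  expect_error(spearman_bootstrap(1:5, rep(2, 5), n_boot = 10, seed = 1),
               "constant")
  expect_error(spearman_bootstrap(1:3, 1:3, n_boot = 10, seed = 1), "at least 4")
})

test_that("spearman rho is invariant under strictly monotone transforms", {
  set.seed(11)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  base <- spearman_bootstrap(x, y, n_boot = 20, seed = 1, bayes = FALSE)$rho
  expect_equal(spearman_bootstrap(exp(x), y, n_boot = 20, seed = 1,
                                  bayes = FALSE)$rho, base)
  expect_equal(spearman_bootstrap(x, y^3 + 5 * y, n_boot = 20, seed = 1,
                                  bayes = FALSE)$rho, base)
})

test_that("bootstrap CI brackets rho and is seed-reproducible", {
  set.seed(12)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60, sd = 0.8)
  r1 <- spearman_bootstrap(x, y, n_boot = 500, seed = 4, bayes = FALSE)
  r2 <- spearman_bootstrap(x, y, n_boot = 500, seed = 4, bayes = FALSE)
  expect_identical(r1$ci95, r2$ci95)
  expect_lte(r1$ci95[1], r1$rho)
  expect_gte(r1$ci95[2], r1$rho)
})

test_that("permutation correlation is exact at the identity and doubles two-sided", {
  p <- permutation_correlation(1:10, 1:10, B = 999, seed = 3,
                               alternative = "greater")
  expect_equal(p$p_value, 1 / 1000) # only the identity order reaches rho = 1

  set.seed(13)
  x <- rnorm(40); y <- rnorm(40)
  pg <- permutation_correlation(x, y, B = 1999, seed = 5, alternative = "greater")
  pl <- permutation_correlation(x, y, B = 1999, seed = 5, alternative = "less")
  pt <- permutation_correlation(x, y, B = 1999, seed = 5, alternative = "two_sided")
  # for a symmetric null the two-sided p doubles the smaller tail (MC slack)
  expect_lte(abs(pt$p_value - 2 * min(pg$p_value, pl$p_value)), 0.05)
})

test_that("mann-kendall S, variance and labels match the textbook cases", {
  up <- mann_kendall(c(1, 2, 3, 4, 5))
  expect_equal(up$S, 10L)
  expect_equal(up$var_S, 5 * 4 * 15 / 18)
  down <- mann_kendall(c(5, 4, 3, 2, 1))
  expect_equal(down$S, -10L)
  expect_equal(down$Z, -up$Z)

  tied <- mann_kendall(c(1, 2, 2, 3))
  expect_equal(tied$S, 5L)
  expect_equal(tied$var_S, (4 * 3 * 13 - 2 * 1 * 9) / 18)

  flat <- mann_kendall(rep(3, 6))
  expect_equal(flat$S, 0L)
  expect_equal(flat$trend, "none")
  expect_error(mann_kendall(c(1, 2)), "length >= 3")
})

test_that("mann-kendall S equals exhaustive enumeration on random series", {
  set.seed(14)
  for (i in 1:30) {
    x <- sample(1:5, sample(3:9, 1), replace = TRUE)
    expect_identical(mann_kendall(x)$S, mk_S_brute(x))
  }
})

test_that("exponential growth fit recovers exact and degenerate curves", {
  tt <- 1996:2020
  k <- 2 * exp(0.3 * (tt - mean(tt)))
  fit <- exp_growth_fit(tt, k)
  expect_equal(fit$b, 0.3, tolerance = 1e-8)
  expect_equal(fit$scale, 2, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  flat <- exp_growth_fit(tt, rep(5, length(tt)))
  expect_equal(flat$b, 0, tolerance = 1e-8)
  expect_error(exp_growth_fit(tt, rep(0, length(tt))), "all counts")

  set.seed(15)
  noisy <- rpois(length(tt), 3 * exp(0.25 * (tt - mean(tt))))
  nf <- exp_growth_fit(tt, noisy)
  expect_true(nf$b_ci95[1] <= 0.25 && 0.25 <= nf$b_ci95[2])
})

test_that("JZS Bayes factors point the right way and are symmetric in r", {
  expect_lt(jzs_bayes_factor("correlation", r = 0, n = 50), 1)
  expect_lt(jzs_bayes_factor("two_sample", t = 0, n1 = 20, n2 = 20), 1)
  expect_equal(jzs_bayes_factor("correlation", r = 0.4, n = 30),
               jzs_bayes_factor("correlation", r = -0.4, n = 30),
               tolerance = 1e-9)
  # evidence accumulates with n at fixed nonzero r
  bfs <- vapply(c(10, 30, 90, 270),
                function(n) jzs_bayes_factor("correlation", r = 0.4, n = n), 1)
  expect_true(all(diff(bfs) > 0))
  # raw two-sample data route agrees with the t route
  set.seed(16)
  x <- rnorm(25, 0.5); y <- rnorm(30)
  sp <- sqrt((24 * var(x) + 29 * var(y)) / 53)
  tstat <- (mean(x) - mean(y)) / (sp * sqrt(1 / 25 + 1 / 30))
  expect_equal(jzs_bayes_factor("two_sample", x = x, y = y),
               jzs_bayes_factor("two_sample", t = tstat, n1 = 25, n2 = 30),
               tolerance = 1e-9)
})

test_that("spline fit recovers the linear limit and a smooth signal", {
  x <- seq(0, 1, length.out = 120)
  fit <- spline_gam_fit(x, 2 - 3 * x)
  expect_equal(fit$linear_beta, -3, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # near-linear data: the penalty prunes the smooth almost entirely
  set.seed(27)
  fit1 <- spline_gam_fit(x, 2 - 3 * x + rnorm(120, sd = 0.05))
  expect_equal(fit1$linear_beta, -3, tolerance = 0.1)
  expect_lt(fit1$smooth_edf, 1.5)
  expect_gt(fit1$r2_adj, 0.99)

  set.seed(17)
  x2 <- seq(0, pi, length.out = 200)
  y2 <- sin(4 * x2) + rnorm(200, sd = 0.2)
  fit2 <- spline_gam_fit(x2, y2)
  expect_gt(fit2$r2_adj, 0.8)
  expect_gt(fit2$smooth_edf, 3)

  expect_error(spline_gam_fit(x[1:9], (2 - 3 * x)[1:9], k = 10), "reduce `k`")
  fit3 <- spline_gam_fit(x2, y2, mode = "smooth_only")
  expect_true(is.na(fit3$linear_beta))
  expect_gt(fit3$r2_adj, 0.8)
})

test_that("spline beta is recovered within sampling error on known data", {
  set.seed(18)
  hits <- 0L
  for (i in 1:40) {
    x <- runif(150, 0, 2)
    # the identifiable linear slope excludes any linear leakage of the smooth,
    # so generate the smooth part orthogonal to {1, x} in-sample
    f_perp <- resid(lm(cos(4 * x) ~ x))
    y <- 1 - 2.75 * x + 0.6 * f_perp + rnorm(150, sd = 0.4)
    fit <- spline_gam_fit(x, y)
    if (abs(fit$linear_beta - (-2.75)) <= 2 * fit$linear_se) hits <- hits + 1L
  }
  expect_gte(hits, 34L) # ~90% nominal coverage of beta +/- 2 SE
})
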