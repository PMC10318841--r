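test_that("gini matches hand-derived values and rejects degenerate input", {
  expect_equal(gini(c(2, 2, 2, 2)), 0)
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)   # brute double sum 6 / (2*16*0.25)
  expect_equal(gini(c(1, 3)), 0.25)         # brute double sum 4 / (2*4*2)
  expect_error(gini(c(0, 0, 0)), "positive mean")
  expect_error(gini(5), "at least 2")
  expect_error(gini(c(-1, 2)), "nonnegative")
})

test_that("gini agrees with the brute-force and rank-formula oracles", {
  set.seed(41)
  for (i in 1:50) {
    y <- rlnorm(sample(2:40, 1), sdlog = runif(1, 0.1, 2))
    expect_equal(gini(y), gini_brute(y), tolerance = 1e-12)
    expect_equal(gini(y), gini_rank(y), tolerance = 1e-12)
    expect_lt(gini(y), (length(y) - 1) / length(y) + 1e-12)
  }
})

test_that("lorenz curve has the documented geometry and the 1 - 2A identity", {
  lc <- lorenz_curve(c(1, 1, 1, 1))
  expect_equal(lc$p, lc$L) # diagonal
  lc2 <- lorenz_curve(c(0, 0, 0, 1))
  expect_equal(lc2$L[lc2$p == 0.75], 0)
  expect_equal(lc2$L[lc2$p == 1], 1)
  expect_equal(lorenz_curve(c(1, 3))$L[2], 0.25)
  expect_error(lorenz_curve(c(-1, 2)), "nonnegative")

  set.seed(42)
  for (i in 1:20) {
    y <- rlnorm(sample(2:60, 1), sdlog = 1)
    lc <- lorenz_curve(y)
    expect_true(all(diff(lc$p) >= 0) && all(diff(lc$L) >= -1e-12))
    expect_true(all(lc$L <= lc$p + 1e-12))
    area <- sum(diff(lc$p) * (head(lc$L, -1) + lc$L[-1]) / 2)
    expect_equal(1 - 2 * area, gini(y), tolerance = 1e-9)
  }
})

test_that("theil index matches closed forms and its bounds", {
  expect_equal(theil_index(c(5, 5, 5)), 0)
  expect_equal(theil_index(c(1, 3)), (0.5 * log(0.5) + 1.5 * log(1.5)) / 2)
  expect_equal(theil_index(c(0, 1)), log(2))
  set.seed(43)
  for (i in 1:20) {
    y <- rlnorm(sample(2:40, 1))
    expect_gte(theil_index(y), 0)
    expect_lte(theil_index(y), log(length(y)) + 1e-12)
  }
})

test_that("gini and theil are scale invariant and respect Pigou-Dalton", {
  set.seed(44)
  for (i in 1:25) {
    y <- rlnorm(sample(3:30, 1), sdlog = 1)
    c0 <- runif(1, 0.1, 50)
    expect_equal(gini(c0 * y), gini(y), tolerance = 1e-12)
    expect_equal(theil_index(c0 * y), theil_index(y), tolerance = 1e-12)
    # mean-preserving transfer rich -> poor never increases inequality
    rich <- which.max(y); poor <- which.min(y)
    eps <- runif(1, 0, (y[rich] - y[poor]) / 2)
    y2 <- y; y2[rich] <- y2[rich] - eps; y2[poor] <- y2[poor] + eps
    expect_lte(gini(y2), gini(y) + 1e-12)
    expect_lte(theil_index(y2), theil_index(y) + 1e-12)
  }
})

test_that("dagum decomposition reproduces the hand-computed examples", {
  d1 <- dagum_decomposition(list(A = c(1, 1), B = c(3, 3)))
  expect_equal(d1$G_total, 0.25)
  expect_equal(d1$G_within, 0)
  expect_equal(d1$G_between_net, 0.25)
  expect_equal(d1$G_transvariation, 0)
  expect_equal(d1$pairwise$D_jh, 1)
  expect_equal(d1$pairwise$G_jh, 0.5)

  d2 <- dagum_decomposition(list(A = c(1, 3), B = c(2, 4)))
  expect_equal(d2$G_total, 0.25)
  expect_equal(d2$G_within, 0.10)
  expect_equal(d2$G_between_net, 0.10)
  expect_equal(d2$G_transvariation, 0.05)
  expect_equal(d2$pairwise$d_jh, 1.25)
  expect_equal(d2$pairwise$p_jh, 0.25)
  expect_equal(d2$pairwise$D_jh, 2 / 3)
})

test_that("single-module decomposition collapses to the pooled gini", {
  d <- dagum_decomposition(list(all = c(1, 2, 5, 9)))
  expect_equal(d$G_within, d$G_total)
  expect_equal(d$G_between_net, 0)
  expect_equal(d$G_transvariation, 0)
})

test_that("decomposition identity and share constraints hold on random samples", {
  set.seed(45)
  for (i in 1:100) {
    g <- random_grouped_sample()
    d <- dagum_decomposition(g)
    expect_equal(d$G_within + d$G_between_net + d$G_transvariation,
                 d$G_total, tolerance = 1e-10)
    expect_equal(d$G_total, gini(g$value), tolerance = 1e-12)
    expect_equal(sum(d$shares$p_j), 1, tolerance = 1e-12)
    expect_equal(sum(d$shares$s_j), 1, tolerance = 1e-12)
    expect_true(all(d$pairwise$D_jh >= -1e-12 & d$pairwise$D_jh <= 1 + 1e-12))
  }
})

test_that("identical modules give D = 0 and a pure-overlap pair term", {
  d <- dagum_decomposition(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_equal(d$pairwise$D_jh, 0)
  expect_equal(d$G_between_net, 0)
  expect_equal(d$G_within + d$G_transvariation, d$G_total, tolerance = 1e-12)
})

test_that("permutation test behaves at both tails and is reproducible", {
  equal_units <- tibble::tibble(unit = letters[1:10], value = 100, module = "all")
  pt_hi <- gini_permutation_test(equal_units, B = 199, seed = 2)
  expect_gt(pt_hi$p_value, 0.95) # equal split sits at the null's lower tail

  onehot <- tibble::tibble(unit = paste0("u", 1:20),
                           value = c(10000, rep(0, 19)), module = "all")
  pt_lo <- gini_permutation_test(onehot, B = 999, seed = 1)
  expect_equal(pt_lo$p_value, 1 / 1000) # no replicate as extreme

  expect_error(gini_permutation_test(onehot, B = 0, seed = 1), "B")
  expect_error(gini_permutation_test(onehot, B = 99, seed = 1,
                                     null_model = "bogus"))

  rep1 <- gini_permutation_test(onehot, B = 99, seed = 7)
  rep2 <- gini_permutation_test(onehot, B = 99, seed = 7)
  expect_identical(rep1$null, rep2$null)
  d <- gini_permutation_test(onehot, B = 99, seed = 7,
                             null_model = "dirichlet_uniform")
  expect_lte(d$p_value, 0.05)
})
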