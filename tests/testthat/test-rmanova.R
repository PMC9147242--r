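test_that("estimate_delta matches the dense Ledoit-Wolf oracle", {
  withr::with_seed(21, {
    for (dims in list(c(12, 40), c(10, 10), c(30, 4))) {
      n_per <- dims[1] %/% 2
      x <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
      rownames(x) <- sprintf("S%02d", seq_len(dims[1]))
      d <- toy_design(n_per, ids = rownames(x))
      expect_equal(estimate_delta(x, d, "group"),
                   oracle_lw_delta(x, d$factors$group), tolerance = 1e-10)
    }
  })
})

test_that("delta behaves at the dimensionality extremes", {
  # p = 1: scalar within-covariance, delta finite in [0, 1]
  x1 <- toy_two_group(4, 1, seed = 1)
  d1 <- estimate_delta(x1, toy_design(4), "group")
  expect_true(is.finite(d1) && d1 >= 0 && d1 <= 1)

  # same heteroscedastic covariance, opposite sample/variable regimes:
  # p >> n forces strong shrinkage, n >> p needs almost none
  hetero <- function(n_per, p, seed) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
      x <- sweep(x, 2L, seq(0.5, 3, length.out = p), `*`)
      rownames(x) <- sprintf("S%03d", seq_len(2 * n_per))
      x
    })
  }
  wide <- hetero(5, 200, seed = 2)
  expect_gt(estimate_delta(wide, toy_design(5, ids = rownames(wide)), "group"),
            0.5)
  tall <- hetero(250, 5, seed = 3)
  expect_lt(estimate_delta(tall, toy_design(250, ids = rownames(tall)), "group"),
            0.1)

  expect_error(estimate_delta(toy_two_group(1, 3),
                              toy_design(1), "group"), "fewer than 2")
})

test_that("delta = 0 with n > p reproduces the Lawley-Hotelling trace", {
  withr::with_seed(31, {
    x <- matrix(rnorm(30 * 5), 30, 5)
    x[16:30, 1] <- x[16:30, 1] + 1
    rownames(x) <- sprintf("S%02d", 1:30)
    d <- toy_design(15, ids = rownames(x))
    m <- fit_rmanova(x, d, "group", delta = 0)
    expect_equal(m$statistic, oracle_lh_trace(x, d$factors$group),
                 tolerance = 1e-9)
  })
})

test_that("delta = 1 collapses to ASCA: same p-values seed for seed", {
  ds <- generate_feature_dataset(
    synthetic_config(n_per_group = 5, n_variables = 40, n_markers = 5,
                     effect_size = 1, n_internal_standards = 0, seed = 8))
  xs <- autoscale(ds$features$values)
  pa <- permutation_test(xs, ds$design, "group", 299, seed = 7)
  pr <- rmanova_significance(xs, ds$design, "group", delta = 1,
                             n_permutations = 299, seed = 7)
  expect_identical(pa$p_value, pr$p_value)
  # statistic at delta 1 is the monotone transform ssqE / gamma
  m <- fit_rmanova(xs, ds$design, "group", delta = 1)
  dec <- decompose_effects(xs, ds$design, "group")
  gamma <- dec$ssq_residual / ((nrow(xs) - 2) * ncol(xs))
  expect_equal(m$statistic, unname(dec$ssq[["group"]]) / gamma,
               tolerance = 1e-9)
  # variable ranking at delta = 1 equals the SCA first-loading ranking
  sca <- fit_sca(dec$effect_matrices$group, dec$residuals)
  expect_equal(cor(abs(m$canonical$loadings[, 1]), abs(sca$loadings[, 1]),
                   method = "spearman"), 1)
})

test_that("statistic is continuous in delta and W stays positive definite", {
  # p < n so the delta -> 0 limit is finite and the whole path is smooth
  x <- toy_two_group(8, 6, shift = 1, markers = 1:2, seed = 12)
  d <- toy_design(8)
  grid <- seq(0.02, 1, by = 0.02)
  stats <- vapply(grid, function(dl) fit_rmanova(x, d, "group", dl)$statistic,
                  numeric(1))
  rel_jump <- abs(diff(stats)) / abs(stats[-1])
  expect_lt(max(rel_jump), 0.2)
  m <- fit_rmanova(x, d, "group", 0.4)
  ev <- eigen(m$regularized_within, symmetric = TRUE, only.values = TRUE)$values
  gamma <- sum(diag(m$within_scatter)) / ncol(x)
  expect_gte(min(ev), 0.4 * gamma - 1e-12)
})

test_that("singular delta = 0 in p >= n - k data is rejected with advice", {
  x <- toy_two_group(4, 30, seed = 14)
  d <- toy_design(4)
  expect_error(fit_rmanova(x, d, "group", delta = 0), "delta > 0")
  expect_error(rmanova_significance(x, d, "group", delta = 0,
                                    n_permutations = 5, seed = 1),
               "delta > 0")
})

test_that("Gram-matrix fast path equals the dense statistic when p > n", {
  ds <- generate_feature_dataset(
    synthetic_config(n_per_group = 5, n_variables = 60, n_markers = 6,
                     effect_size = 1.5, n_internal_standards = 0, seed = 19))
  xs <- autoscale(ds$features$values)
  for (dl in list(0.3, 1, "auto")) {
    pt <- rmanova_significance(xs, ds$design, "group", delta = dl,
                               n_permutations = 3, seed = 1)
    dense <- fit_rmanova(xs, ds$design, "group", delta = dl)
    expect_equal(pt$statistic_observed, dense$statistic, tolerance = 1e-9)
  }
})

test_that("auto and fixed delta give comparable significance", {
  ds <- generate_feature_dataset(
    synthetic_config(n_per_group = 5, n_variables = 30, n_markers = 8,
                     effect_size = 2, n_internal_standards = 0, seed = 23))
  xs <- autoscale(ds$features$values)
  d_hat <- estimate_delta(xs, ds$design, "group")
  p_auto <- rmanova_significance(xs, ds$design, "group", "auto", 199, seed = 5)
  p_fix <- rmanova_significance(xs, ds$design, "group", d_hat, 199, seed = 5)
  expect_equal(p_auto$statistic_observed, p_fix$statistic_observed)
  expect_lt(abs(p_auto$p_value - p_fix$p_value), 0.1)
  expect_lt(p_auto$p_value, 0.05)
})
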