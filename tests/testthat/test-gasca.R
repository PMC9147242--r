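test_that("find_groups builds thresholded-correlation components", {
  withr::with_seed(41, {
    x <- matrix(rnorm(30 * 6), 30, 6)
    x[, 2] <- x[, 1]                       # duplicated column: always grouped
    colnames(x) <- paste0("V", 1:6)
    g <- find_groups(x, threshold = 1)
    expect_true(any(vapply(g$groups, function(s) all(c(1L, 2L) %in% s),
                           logical(1))))
    # threshold just above the max off-diagonal |r| of independent columns
    r <- abs(cor(x[, 3:6]))
    thr <- max(r[upper.tri(r)]) + 1e-6
    g2 <- find_groups(x[, 3:6], thr)
    expect_length(g2$groups, 4)
    expect_true(all(lengths(g2$groups) == 1))
  })

  ds <- generate_feature_dataset(
    synthetic_config(n_per_group = 30, n_variables = 30, n_markers = 0,
                     block_spec = list(c(10, 0.95)),
                     n_internal_standards = 0, seed = 6))
  xl <- log(ds$features$values)
  g3 <- find_groups(xl, 0.7)
  block_idx <- match(ds$truth_blocks[[1]], colnames(xl))
  hit <- vapply(g3$groups, function(s) all(block_idx %in% s), logical(1))
  expect_true(any(hit))

  xc <- cbind(x, const = 1)
  expect_warning(find_groups(xc, 0.9), "constant")
  expect_error(find_groups(x, 0), "threshold")
})

test_that("fit_gasca extracts group-supported components", {
  x <- toy_two_group(4, 10, shift = 4, markers = 1:3, seed = 7)
  d <- toy_design(4)
  e <- decompose_effects(x, d, "group")$effect_matrices$group

  # singleton groups: first component = largest effect-column SSQ
  singles <- variable_groups(as.list(1:10))
  m1 <- fit_gasca(e, singles, 2)
  expect_equal(sum(m1$loadings[, 1] != 0), 1)
  expect_equal(unname(which(m1$loadings[, 1] != 0)),
               unname(which.max(colSums(e^2))))
  expect_equal(m1$explained_ssq[1], max(colSums(e^2)))

  # two disjoint blocks with the effect confined to block 1
  blocks <- variable_groups(list(1:5, 6:10))
  e2 <- e
  e2[, 6:10] <- e2[, 6:10] * 1e-4
  m2 <- fit_gasca(e2, blocks, 1)
  expect_true(all(which(m2$loadings[, 1] != 0) %in% 1:5))

  # unit norm and single-group support for every component
  g <- variable_groups(list(1:4, 5:7, 8:10))
  m3 <- fit_gasca(e, g, 2)
  for (a in 1:2) {
    expect_equal(sum(m3$loadings[, a]^2), 1, tolerance = 1e-12)
    support <- which(m3$loadings[, a] != 0)
    expect_true(any(vapply(g$groups, function(s) all(support %in% s),
                           logical(1))))
  }
  expect_error(fit_gasca(matrix(0, 4, 3), singles), "no effect variance")
  expect_error(fit_gasca(e, variable_groups(list(1:10)), 5),
               "non-trivial component")
})

test_that("single all-variable group reduces GASCA to SCA", {
  x <- toy_two_group(5, 8, shift = 2, markers = 1:4, seed = 9)
  e <- decompose_effects(x, toy_design(5), "group")$effect_matrices$group
  all_g <- variable_groups(list(1:8))
  mg <- fit_gasca(e, all_g, 1)
  ms <- fit_sca(e, n_components = 1)
  expect_equal(abs(mg$loadings[, 1]), abs(ms$loadings[, 1]), tolerance = 1e-9)
  expect_equal(mg$explained_ssq[1], ms$explained[1] * ssq(e), tolerance = 1e-9)
})

test_that("deflation shrinks SSQ and sparsity cannot beat unconstrained SCA", {
  d3 <- toy_design(3, c("c", "l", "h"))
  x3 <- withr::with_seed(15, {
    base <- matrix(rnorm(9 * 12), 9, 12)
    base[4:6, 1:3] <- base[4:6, 1:3] + 2
    base[7:9, 4:6] <- base[7:9, 4:6] + 3
    rownames(base) <- d3$sample_ids
    base
  })
  dec <- decompose_effects(x3, d3, "group")
  e <- dec$effect_matrices$group
  groups <- variable_groups(list(1:3, 4:6, 7:12))
  m <- fit_gasca(e, groups, 2)
  expect_true(all(diff(m$explained_ssq) <= 1e-9))
  sca <- fit_sca(e, n_components = 2)
  expect_lte(m$explained_ssq[1], sca$explained[1] * ssq(e) + 1e-9)
  expect_lte(m$explained[1], sca$explained[1] + 1e-12)
})

test_that("gasca statistic fast path equals fit_gasca's first component", {
  for (levels in list(c("A", "B"), c("c", "l", "h"))) {
    ds <- generate_feature_dataset(
      synthetic_config(n_per_group = 4, group_levels = levels,
                       n_variables = 20, n_markers = 4, effect_size = 2,
                       block_spec = list(c(6, 0.9)),
                       n_internal_standards = 0, seed = 27))
    xs <- autoscale(ds$features$values)
    g <- find_groups(xs, 0.6)
    pt <- gasca_significance(xs, ds$design, "group", n_permutations = 3,
                             seed = 1, groups = g)
    dec <- decompose_effects(xs, ds$design, "group")
    m <- fit_gasca(dec$effect_matrices$group, g, 1)
    expect_equal(pt$statistic_observed, m$explained_ssq[1], tolerance = 1e-9)
    # bound: first-component SSQ never exceeds the total effect SSQ
    expect_lte(pt$statistic_observed, unname(dec$ssq[["group"]]) + 1e-9)
    expect_true(all(pt$statistic_permuted <=
                      max(pt$statistic_permuted, pt$statistic_observed) + 1e-9))
  }
})

test_that("groups are invariant under row permutation of X", {
  x <- toy_two_group(5, 12, shift = 1, markers = 1:3, seed = 33)
  g0 <- find_groups(x, 0.5)
  withr::with_seed(2, {
    for (i in 1:3) {
      gp <- find_groups(x[sample(nrow(x)), ], 0.5)
      expect_identical(gp$groups, g0$groups)
    }
  })
})

test_that("a strong effect confined to one correlated block is detected", {
  ds <- generate_feature_dataset(
    synthetic_config(n_per_group = 8, n_variables = 30, n_markers = 6,
                     effect_size = 4, block_spec = list(c(6, 0.9)),
                     n_internal_standards = 0, seed = 44))
  xs <- autoscale(ds$features$values)
  pg <- gasca_significance(xs, ds$design, "group", 199, seed = 3)
  pa <- permutation_test(xs, ds$design, "group", 199, seed = 3)
  expect_lt(pg$p_value, 0.05)
  expect_lt(pa$p_value, 0.05)
})
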