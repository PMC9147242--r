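test_that("fit_pca meets rank, reconstruction and ordering contracts", {
  # rank-1 data: one component explains everything
  u <- 1:6; v <- c(2, -1, 0.5)
  x1 <- outer(u, v) + 0
  expect_equal(fit_pca(x1, "center")$explained[1], 1)

  withr::with_seed(3, {
    x <- matrix(rnorm(8 * 5), 8, 5)
    m <- fit_pca(x, "autoscale")
    xs <- autoscale(x)
    expect_lt(max(abs(xs - m$scores %*% t(m$loadings))), 1e-9)
    expect_true(all(diff(m$explained) <= 1e-12))
    expect_lte(sum(m$explained), 1 + 1e-12)
  })
})

test_that("fit_plsda separates classes and is deterministic", {
  x <- toy_two_group(5, 10, shift = 6, markers = 1:3, seed = 5)
  cls <- rep(c("A", "B"), each = 5)
  m <- fit_plsda(x, cls, n_latent = 2, scaling = "autoscale")
  expect_gt(m$explained_y[1], 0.8)
  expect_identical(predict(m), cls)
  m2 <- fit_plsda(x, cls, n_latent = 2, scaling = "autoscale")
  expect_identical(m$weights, m2$weights)
  expect_equal(colSums(m$weights^2), rep(1, m$n_latent), tolerance = 1e-12)

  # three classes: indicator matrix, one column per class
  x3 <- rbind(x, x[1:4, ] + 10)
  rownames(x3) <- sprintf("S%02d", 1:14)
  cls3 <- c(cls, "C", "C", "C", "C")
  m3 <- fit_plsda(x3, cls3, 2)
  expect_equal(ncol(m3$y_loadings), m3$n_latent)
  expect_identical(predict(m3), cls3)

  expect_error(fit_plsda(x, rep("A", 10), 2), "2 or 3 classes")
  expect_error(fit_plsda(x, c("A", rep("B", 9)), 2), "at least 2 samples")
})

test_that("VIP scores satisfy the exact normalization", {
  withr::with_seed(11, {
    for (rep in 1:4) {
      n <- sample(6:12, 1); p <- sample(c(4, 15, 40), 1)
      x <- matrix(rnorm(n * p), n, p)
      cls <- rep(c("A", "B"), length.out = n)
      m <- fit_plsda(x, cls, n_latent = sample(1:3, 1), scaling = "center")
      v <- vip_scores(m)
      expect_equal(mean(v^2), 1, tolerance = 1e-12)
      expect_equal(sum(v^2), p, tolerance = 1e-10)
      expect_true(all(v >= 0))
    }
  })
  # p = 1 forces VIP = 1
  x1 <- matrix(c(rnorm(4), rnorm(4) + 3), 8, 1)
  m1 <- fit_plsda(x1, rep(c("A", "B"), each = 4), 1, "center")
  expect_equal(unname(vip_scores(m1)), 1)
  # a centered-to-zero (constant) column has zero weight everywhere -> VIP 0
  x0 <- cbind(toy_two_group(4, 3, shift = 2, markers = 1, seed = 2), 5)
  m0 <- fit_plsda(x0, rep(c("A", "B"), each = 4), 2, "center")
  expect_equal(unname(vip_scores(m0)[4]), 0)
})

test_that("selectivity ratio matches the explicit target-projection oracle", {
  withr::with_seed(13, {
    x <- matrix(rnorm(6 * 20), 6, 20)
    cls <- rep(c("A", "B"), each = 3)
    m <- fit_plsda(x, cls, 2, "center")
    sr <- selectivity_ratio(m)
    # brute-force reconstruction from the regression vector
    xs <- m$Xs
    b <- m$coefficients / sqrt(sum(m$coefficients^2))
    t_tp <- xs %*% b
    xhat <- t_tp %*% t(crossprod(xs, t_tp) / sum(t_tp^2))
    expect_equal(unname(sr),
                 colSums(xhat^2) / colSums((xs - xhat)^2), tolerance = 1e-9)
  })
  # constant column is orthogonal to the projection -> SR = 0
  x0 <- cbind(toy_two_group(4, 3, shift = 2, markers = 1, seed = 2), 5)
  m0 <- fit_plsda(x0, rep(c("A", "B"), each = 4), 1, "center")
  expect_equal(unname(selectivity_ratio(m0)[4]), 0)
  # exact rank-1 data along the regression vector hits the cap
  u <- c(-1, -1, -1, 1, 1, 1)
  xr <- outer(u, c(1, 2, -1))
  mr <- fit_plsda(xr, rep(c("A", "B"), each = 3), 1, "none")
  expect_true(all(selectivity_ratio(mr, xr) == 1e12))
})

test_that("stability replicates are reproducible and respect removal", {
  ds <- generate_feature_dataset(
    synthetic_config(n_per_group = 6, n_variables = 40, n_markers = 5,
                     effect_size = 3, n_internal_standards = 0, seed = 31))
  xs <- autoscale(ds$features$values)
  cls <- ds$design$factors$group
  f1 <- stability_replicates(xs, cls, n_models = 40, k = 10, seed = 77)
  f2 <- stability_replicates(xs, cls, n_models = 40, k = 10, seed = 77)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
  # strong markers are selected in nearly every replicate where they survive
  # the removal draw (mean removal rate ~5%)
  expect_true(all(f1[ds$truth_markers] > 0.8))
  expect_gt(min(f1[ds$truth_markers]), max(0, median(f1)))
  # with 10% removal a variable is absent from ~ that many replicates
  expect_lt(max(f1), 1 + 1e-12)
  f3 <- stability_replicates(xs, cls, n_models = 20, selector = "vip_gt1",
                             seed = 1)
  expect_true(all(f3 >= 0 & f3 <= 1))
  expect_error(stability_replicates(xs, cls, n_models = 0), "n_models")
  expect_error(stability_replicates(xs, cls, removal_range = c(0.5, 0.2)),
               "removal_range")
})

test_that("univariate tests match t/aov oracles and handle degeneracy", {
  withr::with_seed(17, {
    x <- toy_two_group(5, 6, shift = 1, markers = 1:2, seed = 17)
    d <- toy_design(5)
    p <- univariate_tests(x, d, "group")
    for (j in 1:6) {
      ref <- t.test(x[1:5, j], x[6:10, j], var.equal = TRUE)$p.value
      expect_equal(unname(p[j]), ref, tolerance = 1e-12)
      # algebraic identity: two-group t-test p equals one-way ANOVA F p
      f_ref <- anova(lm(x[, j] ~ d$factors$group))[1, "Pr(>F)"]
      expect_equal(unname(p[j]), f_ref, tolerance = 1e-12)
    }
    # three groups: one-way ANOVA
    d3 <- toy_design(4, c("c", "l", "h"))
    x3 <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(d3$sample_ids, NULL))
    p3 <- univariate_tests(x3, d3, "group")
    for (j in 1:4) {
      ref <- anova(lm(x3[, j] ~ d3$factors$group))[1, "Pr(>F)"]
      expect_equal(unname(p3[j]), ref, tolerance = 1e-12)
    }
  })
  # identical group values -> p = 1 with warning
  xc <- matrix(rep(c(1, 2), 5), 10, 1)
  xc <- cbind(xc, rnorm(10))
  rownames(xc) <- sprintf("S%02d", 1:10)
  dd <- design_table(rownames(xc), data.frame(g = rep(c("A", "B"), 5)))
  xdeg <- matrix(3, 10, 1, dimnames = list(rownames(xc), "v"))
  expect_warning(pd <- univariate_tests(xdeg, dd, "g"), "constant")
  expect_equal(unname(pd), 1)
  expect_error(univariate_tests(xc, design_table(rownames(xc),
               data.frame(g = c("A", rep("B", 9)))), "g"), "fewer than 2")
})

test_that("planted markers reach small univariate p-values", {
  ds <- generate_feature_dataset(
    synthetic_config(n_per_group = 10, n_variables = 60, n_markers = 10,
                     effect_size = 3, drift_sd = 0,
                     n_internal_standards = 0, seed = 55))
  logx <- log(ds$features$values)
  p <- univariate_tests(logx, ds$design, "group")
  expect_lt(median(p[ds$truth_markers]), 0.01)
})

test_that("bh_adjust matches hand computation, base R and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  withr::with_seed(23, {
    for (i in 1:20) {
      p <- runif(sample(1:30, 1))^sample(1:3, 1)
      q <- bh_adjust(p)
      expect_equal(q, p.adjust(p, "BH"))
      expect_equal(q, oracle_bh(p))
      # monotone in p (note: BH is not idempotent in general, e.g.
      # bh_adjust(c(0.1, 0.5)) = c(0.2, 0.5) but adjusting again gives 0.4)
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))
    }
  })
})

test_that("label permutation destroys marker recovery (overfitting guard)", {
  ds <- generate_feature_dataset(
    synthetic_config(n_per_group = 8, n_variables = 200, n_markers = 50,
                     effect_size = 3, n_internal_standards = 0, seed = 61))
  xs <- autoscale(ds$features$values)
  cls <- ds$design$factors$group
  vip_true <- vip_scores(fit_plsda(xs, cls, 2, "none"))
  top_true <- select_top_k(vip_true, "vip", 50)$top_k
  recall_true <- length(intersect(top_true, ds$truth_markers)) / 50
  recalls_perm <- withr::with_seed(9, vapply(1:5, function(i) {
    vip_p <- vip_scores(fit_plsda(xs, sample(cls), 2, "none"))
    length(intersect(select_top_k(vip_p, "vip", 50)$top_k,
                     ds$truth_markers)) / 50
  }, numeric(1)))
  expect_gt(recall_true, 0.8)
  # chance level is 50/200 = 0.25
  expect_lt(mean(recalls_perm), 0.45)
})
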