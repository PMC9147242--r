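test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_per_group = 0), "n_per_group")
  expect_error(synthetic_config(n_markers = -1), "n_markers")
  expect_error(synthetic_config(n_markers = 10, n_variables = 5), "n_markers")
  expect_error(synthetic_config(zero_inflation = 1.5), "zero_inflation")
  expect_error(synthetic_config(group_levels = c("A", "B", "C", "D")),
               "group_levels")
  expect_error(synthetic_config(block_spec = list(c(5, 2))), "block_spec")
  expect_error(synthetic_config(block_spec = list(c(400, 0.5)),
                                n_variables = 100), "block_spec")
})

test_that("feature generator honours null cases and determinism", {
  cfg0 <- synthetic_config(n_per_group = 3, n_variables = 20, n_markers = 5,
                           effect_size = 0, seed = 7)
  ds0 <- generate_feature_dataset(cfg0)
  expect_true(all(ds0$truth_effect == 0))

  cfg1 <- synthetic_config(n_per_group = 3, n_variables = 20, n_markers = 0,
                           seed = 7)
  expect_length(generate_feature_dataset(cfg1)$truth_markers, 0)

  cfg <- synthetic_config(n_per_group = 4, n_variables = 30, n_markers = 6,
                          zero_inflation = 0.2, seed = 99)
  a <- generate_feature_dataset(cfg)
  b <- generate_feature_dataset(cfg)
  expect_identical(a$features$values, b$features$values)
  cfg2 <- synthetic_config(n_per_group = 4, n_variables = 30, n_markers = 6,
                           zero_inflation = 0.2, seed = 100)
  expect_false(identical(a$features$values,
                         generate_feature_dataset(cfg2)$features$values))
})

test_that("dataset structure matches the design contract", {
  cfg <- synthetic_config(n_per_group = 5, group_levels = c("ctl", "low", "high"),
                          n_variables = 40, n_markers = 8, effect_size = 1.5,
                          n_internal_standards = 3, seed = 4)
  ds <- generate_feature_dataset(cfg)
  expect_equal(nrow(ds$features$values), 15)
  expect_equal(ncol(ds$features$values), 43)
  expect_equal(sum(ds$features$is_internal_standard), 3)
  expect_setequal(ds$design$sample_ids, ds$features$sample_ids)
  expect_true(all(ds$truth_markers %in% ds$features$variable_ids))
  # three-group effects monotone in level order: 0 / e / 2e
  expect_equal(unname(ds$truth_effect[, ds$truth_markers[1]]),
               c(0, 1.5, 3))
})

test_that("planted marker shift is recovered by group sample means", {
  cfg <- synthetic_config(n_per_group = 200, n_variables = 50, n_markers = 10,
                          effect_size = 2, zero_inflation = 0, drift_sd = 0,
                          n_internal_standards = 0, seed = 21)
  ds <- generate_feature_dataset(cfg)
  logx <- log(ds$features$values)
  g <- ds$design$factors$group
  for (v in ds$truth_markers) {
    d <- mean(logx[g == "B", v]) - mean(logx[g == "A", v])
    se <- sqrt(var(logx[g == "A", v]) / 200 + var(logx[g == "B", v]) / 200)
    expect_lt(abs(d - 2), 3 * se)
  }
})

test_that("zero inflation hits non-IS variables at the configured rate", {
  cfg <- synthetic_config(n_per_group = 50, n_variables = 100, n_markers = 0,
                          zero_inflation = 0.3, n_internal_standards = 2,
                          seed = 5)
  ds <- generate_feature_dataset(cfg)
  is_cols <- ds$features$is_internal_standard
  rate <- mean(ds$features$values[, !is_cols] == 0)
  expect_lt(abs(rate - 0.3), 0.02)
  expect_true(all(ds$features$values[, is_cols] > 0))
})

test_that("planted blocks are more correlated within than between", {
  cfg <- synthetic_config(n_per_group = 50, n_variables = 40, n_markers = 0,
                          block_spec = list(c(10, 0.8), c(10, 0.8)),
                          n_internal_standards = 0, seed = 8)
  ds <- generate_feature_dataset(cfg)
  r <- abs(cor(log(ds$features$values)))
  b1 <- match(ds$truth_blocks[[1]], ds$features$variable_ids)
  b2 <- match(ds$truth_blocks[[2]], ds$features$variable_ids)
  within <- mean(r[b1, b1][upper.tri(r[b1, b1])])
  between <- mean(r[b1, b2])
  expect_gt(within, between)
  expect_gt(within, 0.5)
})

test_that("internal-standard normalization removes drift exactly", {
  cfg <- synthetic_config(n_per_group = 4, n_variables = 20, n_markers = 0,
                          drift_sd = 1, n_internal_standards = 2, seed = 12)
  ds <- generate_feature_dataset(cfg)
  norm <- normalize_features(ds$features, ds$design)
  is_cols <- norm$is_internal_standard
  # after normalization IS channels are identical across samples
  expect_equal(apply(norm$values[, is_cols, drop = FALSE], 2, sd),
               setNames(c(0, 0), colnames(norm$values)[is_cols]),
               tolerance = 1e-12)
})

test_that("TIC generator builds Gaussian-peak chromatograms", {
  cfg0 <- synthetic_config(n_per_group = 3, n_markers = 0, seed = 2)
  ds0 <- generate_tic_dataset(cfg0, n_timepoints = 100, n_peaks = 0,
                              noise_sd = 0)
  expect_true(all(ds0$features$values == 0))
  expect_identical(ds0$features$variable_kind, "tic_channel")

  # one differential peak at channel 100, sigma = 3 -> channels 94..106
  cfg1 <- synthetic_config(n_per_group = 3, n_markers = 1, effect_size = 2,
                           seed = 2)
  ds1 <- generate_tic_dataset(cfg1, n_timepoints = 200, n_peaks = 2,
                              peak_sigma = 3, peak_positions = c(100, 160))
  expect_identical(ds1$truth_markers, as.character(94:106))

  # effect_size = 0: group-mean chromatograms equal in expectation
  cfg2 <- synthetic_config(n_per_group = 40, n_markers = 0, effect_size = 0,
                           drift_sd = 0, seed = 3)
  ds2 <- generate_tic_dataset(cfg2, n_timepoints = 120, n_peaks = 3,
                              noise_sd = 0.1)
  g <- ds2$design$factors$group
  ma <- colMeans(ds2$features$values[g == "A", ])
  mb <- colMeans(ds2$features$values[g == "B", ])
  expect_lt(max(abs(ma - mb)) / max(ma), 0.05)

  expect_error(generate_tic_dataset(cfg0, n_timepoints = 20, n_peaks = 3),
               "n_timepoints")
})

test_that("centroid scans plant recoverable features", {
  cfg <- synthetic_config(n_per_group = 2, n_variables = 5, n_markers = 0,
                          baseline_log_mean = 8, seed = 6)
  # zero planted features -> empty record set (and empty ROI output)
  empty <- generate_centroid_scans(cfg, n_scans = 10, n_features = 0)
  expect_true(all(vapply(empty$scans, nrow, integer(1)) == 0L))
  expect_equal(ncol(roi_features(empty$scans[[1]], empty$params)$values), 0)
  out <- generate_centroid_scans(cfg, n_scans = 30)
  expect_length(out$scans, 4)
  expect_equal(nrow(out$truth), 5)
  out2 <- generate_centroid_scans(cfg, n_scans = 30)
  expect_identical(out$scans, out2$scans)

  # every sample's ROI extraction recovers exactly the planted features
  for (s in names(out$scans)) {
    ft <- roi_features(out$scans[[s]], out$params, sample_id = s)
    expect_equal(ncol(ft$values), nrow(out$truth))
    expect_equal(sort(as.numeric(ft$variable_ids)), sort(round(out$truth$mz, 4)),
                 tolerance = 1e-3)
  }
})
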