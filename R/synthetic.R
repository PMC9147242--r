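#' Configuration of the synthetic designed-metabolomics generator
#'
#' Describes a synthetic LC-MS experiment: a one-factor design with 2 or 3
#' groups, log-normal baseline intensities, a sparse set of marker variables
#' whose group means shift on the log scale, blocks of correlated variables,
#' zero-inflation, noise-free internal-standard channels, and a per-sample
#' multiplicative drift shared by all variables (so internal-standard
#' normalization can undo it exactly).
#'
#' Within-group log-scale noise has unit standard deviation, so `effect_size`
#' is expressed in within-group standard-deviation units: group `l` (0-based
#' level order) shifts each marker's log intensity by `effect_size * l`
#' (monotone in level order, emulating control < low < high designs).
#' Internal standards are generated in addition to `n_variables` and appended
#' as variables `IS_1`, `IS_2`, ...
#'
#' @param n_per_group samples per group (default 7, a balanced two-group
#'   experiment of 14 samples).
#' @param group_levels ordered level labels, length 2 or 3.
#' @param n_variables number of non-internal-standard variables.
#' @param n_markers number of affected variables (the first `n_markers`
#'   variables).
#' @param effect_size group-mean shift in within-group sd units.
#' @param block_spec list of `c(block_size, within_block_correlation)` pairs;
#'   blocks occupy consecutive variables from the first one.
#' @param zero_inflation probability that a non-internal-standard value is
#'   replaced by zero (after effect injection).
#' @param baseline_log_mean,baseline_log_sd mean and sd of the per-variable
#'   baseline log intensity.
#' @param n_internal_standards number of internal-standard channels.
#' @param drift_sd sd of the per-sample log-scale drift.
#' @param seed integer seed; one RNG stream per dataset.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 7,
                             group_levels = c("A", "B"),
                             n_variables = 300,
                             n_markers = 30,
                             effect_size = 2,
                             block_spec = list(),
                             zero_inflation = 0,
                             baseline_log_mean = 11,
                             baseline_log_sd = 1,
                             n_internal_standards = 2,
                             drift_sd = 0.3,
                             seed = 1L) {
  assert_scalar_number(n_per_group, "n_per_group", min = 1, integer = TRUE)
  if (!length(group_levels) %in% c(2L, 3L) || anyDuplicated(group_levels)) {
    stop_metanova("invalid configuration: field 'group_levels' must be 2 or 3 distinct labels",
                  class = "metanova_config_error")
  }
  assert_scalar_number(n_variables, "n_variables", min = 1, integer = TRUE)
  assert_scalar_number(n_markers, "n_markers", min = 0, integer = TRUE)
  if (n_markers > n_variables) {
    stop_metanova("invalid configuration: field 'n_markers' exceeds n_variables",
                  class = "metanova_config_error")
  }
  if (!is.list(block_spec)) {
    stop_metanova("invalid configuration: field 'block_spec' must be a list of (size, correlation) pairs",
                  class = "metanova_config_error")
  }
  for (b in block_spec) {
    if (length(b) != 2L || b[1L] < 1 || b[1L] != round(b[1L]) ||
        b[2L] < 0 || b[2L] > 1) {
      stop_metanova("invalid configuration: field 'block_spec' entries must be (positive size, correlation in [0,1])",
                    class = "metanova_config_error")
    }
  }
  if (sum(vapply(block_spec, `[`, numeric(1), 1L)) > n_variables) {
    stop_metanova("invalid configuration: field 'block_spec' sizes exceed n_variables",
                  class = "metanova_config_error")
  }
  assert_scalar_number(zero_inflation, "zero_inflation", min = 0, max = 1)
  assert_scalar_number(baseline_log_mean, "baseline_log_mean")
  assert_scalar_number(baseline_log_sd, "baseline_log_sd", min = 0)
  assert_scalar_number(n_internal_standards, "n_internal_standards", min = 0,
                       integer = TRUE)
  assert_scalar_number(drift_sd, "drift_sd", min = 0)
  assert_scalar_number(seed, "seed", integer = TRUE)
  structure(list(n_per_group = as.integer(n_per_group),
                 group_levels = as.character(group_levels),
                 n_variables = as.integer(n_variables),
                 n_markers = as.integer(n_markers),
                 effect_size = effect_size,
                 block_spec = block_spec,
                 zero_inflation = zero_inflation,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 n_internal_standards = as.integer(n_internal_standards),
                 drift_sd = drift_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

synthetic_design <- function(config) {
  k <- length(config$group_levels)
  n <- config$n_per_group * k
  sample_ids <- sprintf("S%02d", seq_len(n))
  group <- rep(config$group_levels, each = config$n_per_group)
  design_table(sample_ids, data.frame(group = group))
}

#' Generate a synthetic feature-matrix dataset with known ground truth
#'
#' Produces a samples x variables peak-area matrix following the intensity
#' model of [synthetic_config()], along with the design and the planted
#' truth (marker IDs, block memberships, group-mean log offsets).
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_dataset` with elements `features`
#'   ([feature_table()]), `design` ([design_table()]), `truth_markers`
#'   (character), `truth_blocks` (list of character vectors), `truth_effect`
#'   (groups x variables matrix of planted log-scale offsets).
#' @export
generate_feature_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- length(config$group_levels)
  n <- config$n_per_group * k
  p <- config$n_variables
  p_all <- p + config$n_internal_standards
  design <- synthetic_design(config)
  level_index <- rep(seq_len(k) - 1L, each = config$n_per_group)

  var_ids <- c(sprintf("V%04d", seq_len(p)),
               if (config$n_internal_standards > 0)
                 paste0("IS_", seq_len(config$n_internal_standards)))
  is_flags <- c(rep(FALSE, p), rep(TRUE, config$n_internal_standards))

  blocks <- list()
  at <- 1L
  for (b in config$block_spec) {
    blocks[[length(blocks) + 1L]] <-
      list(idx = seq.int(at, at + b[1L] - 1L), rho = b[2L])
    at <- at + as.integer(b[1L])
  }

  truth_effect <- matrix(0, nrow = k, ncol = p_all,
                         dimnames = list(config$group_levels, var_ids))
  if (config$n_markers > 0) {
    truth_effect[, seq_len(config$n_markers)] <-
      outer(seq_len(k) - 1L, rep(config$effect_size, config$n_markers))
  }

  values <- withr::with_seed(config$seed, {
    mu <- stats::rnorm(p_all, config$baseline_log_mean, config$baseline_log_sd)
    drift <- stats::rnorm(n, 0, config$drift_sd)
    eps <- matrix(stats::rnorm(n * p), n, p)
    for (bl in blocks) {
      shared <- stats::rnorm(n)
      eps[, bl$idx] <- sqrt(bl$rho) * shared +
        sqrt(1 - bl$rho) * eps[, bl$idx, drop = FALSE]
    }
    logx <- matrix(mu[seq_len(p)], n, p, byrow = TRUE) + eps +
      truth_effect[level_index + 1L, seq_len(p), drop = FALSE] + drift
    x <- exp(logx)
    if (config$zero_inflation > 0) {
      x[matrix(stats::runif(n * p) < config$zero_inflation, n, p)] <- 0
    }
    if (config$n_internal_standards > 0) {
      # internal standards: baseline + drift only, no noise, no zeros
      is_idx <- p + seq_len(config$n_internal_standards)
      x <- cbind(x, exp(outer(drift, mu[is_idx], `+`)))
    }
    x
  })
  dimnames(values) <- list(design$sample_ids, var_ids)

  structure(list(
    features = feature_table(values, variable_kind = "feature",
                             is_internal_standard = is_flags),
    design = design,
    truth_markers = var_ids[seq_len(config$n_markers)],
    truth_blocks = lapply(blocks, function(bl) var_ids[bl$idx]),
    truth_effect = truth_effect,
    config = config
  ), class = "synthetic_dataset")
}

#' Generate synthetic TIC chromatograms with group-specific peaks
#'
#' Each sample's chromatogram is a sum of Gaussian peaks plus additive noise,
#' times a per-sample drift factor.  The first `n_markers` peaks are
#' differential: their log height shifts by `effect_size` within-group
#' height-sd units per level step.  Ground-truth marker channels are those
#' within two peak widths of a differential apex.  Zero-inflation and
#' internal standards from the config do not apply to TIC channels.
#'
#' @param config a [synthetic_config()]; `n_markers` here counts differential
#'   peaks and must not exceed `n_peaks`; `n_variables` is ignored (the
#'   variables are the `n_timepoints` channels).
#' @param n_timepoints number of retention-time channels (>= 10 * n_peaks).
#' @param n_peaks number of Gaussian peaks.
#' @param peak_sigma common peak width (channels).
#' @param peak_positions optional apex channels (length `n_peaks`); evenly
#'   spaced with seeded jitter when `NULL`.
#' @param noise_sd additive channel noise sd (intensity units).
#' @param height_jitter_sd within-group sd of log peak height (the unit in
#'   which `effect_size` is expressed for TIC data).
#' @return a `synthetic_dataset` whose features are a `tic_channel` table.
#' @export
generate_tic_dataset <- function(config, n_timepoints, n_peaks,
                                 peak_sigma = 3, peak_positions = NULL,
                                 noise_sd = 0.5, height_jitter_sd = 0.05) {
  stopifnot(inherits(config, "synthetic_config"))
  assert_scalar_number(n_timepoints, "n_timepoints", min = 1, integer = TRUE)
  assert_scalar_number(n_peaks, "n_peaks", min = 0, integer = TRUE)
  if (n_peaks > 0 && n_timepoints < 10 * n_peaks) {
    stop_metanova("invalid configuration: n_timepoints must be >= 10 * n_peaks",
                  class = "metanova_config_error")
  }
  if (config$n_markers > n_peaks) {
    stop_metanova("invalid configuration: n_markers exceeds n_peaks",
                  class = "metanova_config_error")
  }
  k <- length(config$group_levels)
  n <- config$n_per_group * k
  design <- synthetic_design(config)
  level_index <- rep(seq_len(k) - 1L, each = config$n_per_group)
  tgrid <- seq_len(n_timepoints)

  out <- withr::with_seed(config$seed, {
    if (n_peaks > 0 && is.null(peak_positions)) {
      spacing <- n_timepoints / n_peaks
      peak_positions <- round((seq_len(n_peaks) - 0.5) * spacing +
                                stats::runif(n_peaks, -spacing / 8, spacing / 8))
    }
    h0 <- if (n_peaks > 0)
      exp(stats::rnorm(n_peaks, config$baseline_log_mean, config$baseline_log_sd))
    else numeric(0)
    drift <- stats::rnorm(n, 0, config$drift_sd)
    x <- matrix(0, n, n_timepoints)
    if (n_peaks > 0) {
      shapes <- vapply(peak_positions,
                       function(a) exp(-(tgrid - a)^2 / (2 * peak_sigma^2)),
                       numeric(n_timepoints))        # n_timepoints x n_peaks
      for (i in seq_len(n)) {
        logh <- log(h0) + stats::rnorm(n_peaks, 0, height_jitter_sd)
        if (config$n_markers > 0) {
          logh[seq_len(config$n_markers)] <-
            logh[seq_len(config$n_markers)] +
            config$effect_size * height_jitter_sd * level_index[i]
        }
        x[i, ] <- as.numeric(shapes %*% exp(logh))
      }
    }
    if (noise_sd > 0) x <- x + matrix(stats::rnorm(n * n_timepoints, 0, noise_sd),
                                      n, n_timepoints)
    x <- pmax(x, 0) * exp(drift)
    x
  })
  var_ids <- as.character(tgrid)
  dimnames(out) <- list(design$sample_ids, var_ids)

  truth_channels <- integer(0)
  if (config$n_markers > 0) {
    for (a in peak_positions[seq_len(config$n_markers)]) {
      truth_channels <- union(truth_channels,
                              seq.int(max(1L, ceiling(a - 2 * peak_sigma)),
                                      min(n_timepoints, floor(a + 2 * peak_sigma))))
    }
  }
  truth_effect <- matrix(0, k, n_timepoints,
                         dimnames = list(config$group_levels, var_ids))
  structure(list(
    features = feature_table(out, variable_kind = "tic_channel"),
    design = design,
    truth_markers = as.character(sort(truth_channels)),
    truth_blocks = list(),
    truth_effect = truth_effect,
    peak_positions = peak_positions,
    config = config
  ), class = "synthetic_dataset")
}

#' Generate synthetic centroided scan tables
#'
#' Plants `config$n_variables` features per sample: each feature is a run of
#' consecutive scans at a stable m/z (jitter strictly below half the ROI
#' tolerance) with log-normal intensities above the ROI threshold, so the
#' simplified ROI extractor recovers exactly the planted features.  Feature
#' m/z values are spaced at least 10 tolerances apart.
#'
#' @param config a [synthetic_config()].
#' @param n_scans number of scans (>= 2).
#' @param params the [roi_params()] the scans are constructed to satisfy.
#' @param rt_step retention-time increment per scan.
#' @param n_features planted features per sample (default
#'   `config$n_variables`; 0 gives empty scan tables).
#' @return list with `scans` (named list of per-sample data.frames with
#'   columns scan, rt, mz, intensity), `truth` (data.frame of planted
#'   features: mz, first_scan, n_scans), `design`, and `params`.
#' @export
generate_centroid_scans <- function(config, n_scans, params = roi_params(),
                                    rt_step = 0.5,
                                    n_features = config$n_variables) {
  stopifnot(inherits(config, "synthetic_config"), inherits(params, "roi_params"))
  assert_scalar_number(n_scans, "n_scans", min = 2, integer = TRUE)
  assert_scalar_number(n_features, "n_features", min = 0, integer = TRUE)
  n_feat <- n_features
  design <- synthetic_design(config)
  n <- length(design$sample_ids)

  withr::with_seed(config$seed, {
    mz0 <- 100 + (seq_len(n_feat) - 1L) * max(10 * params$mz_tolerance, 0.5) +
      stats::runif(n_feat, 0, params$mz_tolerance)
    min_run <- min(params$min_consecutive_scans, n_scans)
    first <- sample.int(max(1L, n_scans - min_run + 1L), n_feat, replace = TRUE)
    run_len <- pmin(n_scans - first + 1L,
                    min_run + stats::rpois(n_feat, 2))
    scans <- vector("list", n)
    names(scans) <- design$sample_ids
    for (i in seq_len(n)) {
      recs <- lapply(seq_len(n_feat), function(j) {
        sc <- seq.int(first[j], first[j] + run_len[j] - 1L)
        data.frame(
          scan = sc,
          rt = sc * rt_step,
          mz = mz0[j] + stats::runif(length(sc), -params$mz_tolerance / 4,
                                     params$mz_tolerance / 4),
          intensity = params$min_intensity + 1 +
            stats::rlnorm(length(sc), config$baseline_log_mean,
                          config$baseline_log_sd)
        )
      })
      tab <- if (length(recs)) do.call(rbind, recs) else
        data.frame(scan = integer(0), rt = numeric(0),
                   mz = numeric(0), intensity = numeric(0))
      scans[[i]] <- tab[order(tab$scan, tab$mz), , drop = FALSE]
      rownames(scans[[i]]) <- NULL
    }
    list(scans = scans,
         truth = data.frame(mz = mz0, first_scan = first, n_scans = run_len),
         design = design,
         params = params)
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d samples x %d variables (%s); %d marker(s), %d block(s), effect_size = %g\n",
              nrow(x$features$values), ncol(x$features$values),
              x$features$variable_kind, length(x$truth_markers),
              length(x$truth_blocks), x$config$effect_size))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the feature CSV, design CSV and a ground-truth JSON
#' (`{markers: [...], blocks: [[...]], effect_size, seed}`).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the three paths, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir, prefix = "synthetic") {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_features.csv", "_design.csv",
                                           "_truth.json")))
  write_feature_table(dataset$features, paths[1L])
  write_design(dataset$design, paths[2L])
  jsonlite::write_json(list(markers = dataset$truth_markers,
                            blocks = dataset$truth_blocks,
                            effect_size = dataset$config$effect_size,
                            seed = dataset$config$seed),
                       paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
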