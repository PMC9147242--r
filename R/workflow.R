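#' End-to-end designed-metabolomics workflow
#'
#' Runs the full analysis pipeline on a configuration: load (or synthesize)
#' the feature and design tables, optional internal-standard normalization,
#' scaling, ANOVA decomposition of the tested factor, the three ANOVA-based
#' methods (ASCA, rMANOVA, GASCA) with SSQ permutation tests, the reference
#' methods (PLS-DA with VIP and selectivity ratio, univariate tests with
#' Benjamini-Hochberg correction), top-k selection per method, Venn
#' partition, profile correlations and coincidence counts against the PLS-DA
#' VIP reference.  Writes `report.json`, per-method score/loading/ranking
#' CSVs and a parameter log; rerunning the same configuration and seed
#' reproduces the report byte for byte (timestamps only in the log).
#'
#' Configuration keys (list or path to a JSON file): either `features` +
#' `design` (CSV paths) or `synthetic` (arguments for [synthetic_config()]);
#' `factor` (mandatory); optional `scaling` (`"center"`/`"autoscale"`,
#' default autoscale for feature tables, center for TIC), `normalize`
#' (default: TRUE when internal standards are present), `methods` (default
#' all of asca, rmanova, gasca, plsda, univariate), `k` (50),
#' `n_permutations` (10000), `n_latent` (2), `delta` ("auto"), `threshold`
#' (0.7), `absolute_loadings` (TRUE), `seed` (1), `output_dir`.
#'
#' @param config named list or path to a JSON config file.
#' @return an object of class `metanova_report` (invisibly if written to
#'   disk): selections, venn counts, profile correlations, coincidences,
#'   permutation p-values and the fitted models.
#' @export
run_workflow <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop_metanova("config must be a list or a JSON file path",
                  class = "metanova_config_error")
  }
  if (is.null(config$factor)) {
    stop_metanova("config validation: 'factor' is mandatory",
                  class = "metanova_config_error")
  }

  # ---- inputs ----------------------------------------------------------
  if (!is.null(config$synthetic)) {
    sc <- do.call(synthetic_config, as.list(config$synthetic))
    ds <- generate_feature_dataset(sc)
    features <- ds$features
    design <- ds$design
  } else if (!is.null(config$features) && !is.null(config$design)) {
    features <- read_feature_table(config$features,
                                   variable_kind = config$variable_kind %||% "feature")
    design <- read_design(config$design)
  } else {
    stop_metanova("config validation: provide 'features' + 'design' paths or a 'synthetic' spec",
                  class = "metanova_config_error")
  }
  term <- config$factor
  design_levels(design, term, features$sample_ids)  # validate before compute

  do_normalize <- config$normalize %||% any(features$is_internal_standard)
  if (isTRUE(do_normalize)) {
    features <- normalize_features(features, design)
  }
  # internal standards carry no biological signal: exclude from the analysis
  analysis <- features$values[, !features$is_internal_standard, drop = FALSE]
  scaling <- config$scaling %||%
    if (features$variable_kind == "tic_channel") "center" else "autoscale"
  constant <- apply(analysis, 2L, stats::sd) == 0
  if (scaling == "autoscale" && any(constant)) {
    analysis <- analysis[, !constant, drop = FALSE]
  }
  xs <- apply_scaling(analysis, scaling)

  methods <- config$methods %||% c("asca", "rmanova", "gasca", "plsda",
                                   "univariate")
  k <- config$k %||% 50L
  n_perm <- config$n_permutations %||% 10000L
  n_latent <- config$n_latent %||% 2L
  delta <- config$delta %||% "auto"
  threshold <- config$threshold %||% 0.7
  seed <- config$seed %||% 1L
  abs_loadings <- config$absolute_loadings %||% TRUE

  decomp <- decompose_effects(xs, design, term)
  classes <- design_levels(design, term, rownames(xs) %||% design$sample_ids)

  models <- list(); selections <- list(); p_values <- c(); profiles <- list()
  if ("asca" %in% methods) {
    models$asca <- fit_sca(decomp$effect_matrices[[term]], decomp$residuals)
    perm <- permutation_test(xs, design, term, n_perm, seed,
                             statistic = "asca_ssq")
    p_values["asca"] <- perm$p_value
    models$asca_permutation <- perm
    selections$asca <- select_top_k(models$asca, "asca", k)
    profiles$asca <- profile_of(models$asca, abs_loadings)
  }
  if ("rmanova" %in% methods) {
    models$rmanova <- fit_rmanova(xs, design, term, delta)
    perm <- rmanova_significance(xs, design, term, delta, n_perm, seed)
    p_values["rmanova"] <- perm$p_value
    models$rmanova_permutation <- perm
    selections$rmanova <- select_top_k(models$rmanova, "rmanova", k)
    profiles$rmanova <- profile_of(models$rmanova$canonical, abs_loadings)
  }
  if ("gasca" %in% methods) {
    groups <- find_groups(xs, threshold)
    models$gasca <- fit_gasca(decomp$effect_matrices[[term]], groups)
    perm <- gasca_significance(xs, design, term, n_perm, seed, groups = groups)
    p_values["gasca"] <- perm$p_value
    models$gasca_groups <- groups
    models$gasca_permutation <- perm
    selections$gasca <- select_top_k(models$gasca, "gasca", k)
    profiles$gasca <- profile_of(models$gasca, abs_loadings)
  }
  if ("plsda" %in% methods) {
    models$plsda <- fit_plsda(xs, classes, n_latent, scaling = "none")
    vip <- vip_scores(models$plsda)
    sr <- selectivity_ratio(models$plsda)
    selections$plsda_vip <- select_top_k(vip, "plsda_vip", k)
    selections$plsda_sr <- select_top_k(sr, "plsda_sr", k)
    profiles$plsda_vip <- vip
    profiles$plsda_sr <- sr
  }
  if ("univariate" %in% methods) {
    p_raw <- univariate_tests(analysis, design, term)
    p_adj <- bh_adjust(p_raw)
    models$univariate <- list(p_raw = p_raw, p_adjusted = p_adj,
                              significant = names(p_adj)[p_adj < 0.05])
    selections$univariate <- select_top_k(1 - p_adj, "univariate", k)
  }

  # Venn over the five multivariate selections (univariate BH hits are
  # reported separately, as in the source comparison)
  venn_methods <- intersect(c("asca", "rmanova", "gasca", "plsda_vip",
                              "plsda_sr"), names(selections))
  venn <- if (length(venn_methods) >= 2L) {
    venn_partition(lapply(selections[venn_methods], `[[`, "top_k"))
  }
  correlations <- if (length(profiles) >= 2L) profile_correlation(profiles)
  coincidence <- if ("plsda_vip" %in% names(selections) &&
                     length(selections) >= 2L) {
    coincidence_with_reference(selections, "plsda_vip")
  }

  report <- structure(list(
    term = term, k = k, n_permutations = n_perm, seed = seed,
    scaling = scaling, methods = methods,
    p_values = p_values,
    selections = selections,
    venn = venn,
    profile_correlations = correlations,
    coincidence_with_plsda_vip = coincidence,
    models = models,
    percent_variance = decomp$percent_variance
  ), class = "metanova_report")

  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir, config)
  }
  if (is.null(config$output_dir)) report else invisible(report)
}

profile_of <- function(model, absolute = TRUE) {
  v <- stats::setNames(model$loadings[, 1L], rownames(model$loadings))
  if (absolute) abs(v) else v
}

write_report <- function(report, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    term = report$term, k = report$k,
    n_permutations = report$n_permutations, seed = report$seed,
    scaling = report$scaling,
    p_values = as.list(report$p_values),
    top_k_sets = lapply(report$selections, `[[`, "top_k"),
    venn_partition = as.list(report$venn),
    profile_correlations = report$profile_correlations,
    coincidence_with_plsda_vip = as.list(report$coincidence_with_plsda_vip),
    percent_variance = as.list(report$percent_variance)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$selections)) {
    s <- report$selections[[nm]]
    utils::write.csv(data.frame(variable = names(s$score), score = s$score,
                                selected = names(s$score) %in% s$top_k,
                                row.names = NULL),
                     file.path(dir, sprintf("ranking_%s.csv", nm)),
                     row.names = FALSE)
  }
  for (nm in intersect(c("asca", "gasca"), names(report$models))) {
    m <- report$models[[nm]]
    utils::write.csv(as.data.frame(m$loadings),
                     file.path(dir, sprintf("loadings_%s.csv", nm)))
    utils::write.csv(as.data.frame(m$scores),
                     file.path(dir, sprintf("scores_%s.csv", nm)))
  }
  if ("rmanova" %in% names(report$models)) {
    m <- report$models$rmanova$canonical
    utils::write.csv(as.data.frame(m$loadings),
                     file.path(dir, "loadings_rmanova.csv"))
    utils::write.csv(as.data.frame(m$scores),
                     file.path(dir, "scores_rmanova.csv"))
  }
  log_lines <- c(sprintf("metanova run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 sprintf("factor: %s", report$term),
                 sprintf("seed: %d", report$seed),
                 sprintf("n_permutations: %d", report$n_permutations),
                 sprintf("k: %d", report$k),
                 sprintf("scaling: %s", report$scaling),
                 sprintf("methods: %s", paste(report$methods, collapse = ", ")))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.metanova_report <- function(x, ...) {
  cat(sprintf("<metanova_report> factor '%s', k = %d, %d permutations\n",
              x$term, x$k, x$n_permutations))
  if (length(x$p_values)) {
    cat("  permutation p-values:\n")
    for (m in names(x$p_values)) {
      cat(sprintf("    %-8s p = %.4f\n", m, x$p_values[[m]]))
    }
  }
  if (!is.null(x$coincidence_with_plsda_vip)) {
    cat("  coincidences with PLS-DA VIP top-k:\n")
    for (m in names(x$coincidence_with_plsda_vip)) {
      cat(sprintf("    %-10s %d of %d\n", m,
                  x$coincidence_with_plsda_vip[[m]], x$k))
    }
  }
  invisible(x)
}
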