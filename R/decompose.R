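#' ANOVA decomposition of a data matrix by experimental design
#'
#' Splits a samples x variables matrix into a grand-mean term, one effect
#' matrix per design factor (rows are level-mean deviations from the grand
#' mean, replicated within level), an optional two-factor interaction term
#' (cell mean minus both level means plus grand mean), and residuals.  The
#' sum of squared elements (SSQ) of each effect matrix measures the variance
#' explained by that term; in balanced designs the term SSQs and the residual
#' SSQ add up to the SSQ of the centered matrix.
#'
#' Unbalanced designs are supported for single-factor models only; for
#' multi-factor unbalanced data use [balance_by_removal()] first.
#'
#' @param X numeric matrix or [feature_table()], rows aligned to `design`.
#' @param design a [design_table()].
#' @param terms character vector of factor names, optionally plus one
#'   two-factor interaction written `"A:B"`.  Defaults to all design factors.
#' @return an object of class `effect_decomposition` with elements `terms`,
#'   `effect_matrices` (named list), `residuals`, `ssq` (named), `ssq_residual`,
#'   `ssq_total` (SSQ of the centered matrix), `percent_variance`, `balanced`,
#'   `grand_mean`, and `levels` (per-factor level assignments).
#' @export
decompose_effects <- function(X, design, terms = names(design$factors)) {
  x <- as_values(X)
  sample_ids <- rownames(x) %||% design$sample_ids
  if (nrow(x) != length(design$sample_ids)) {
    stop_metanova("matrix has %d rows but design has %d samples",
                  nrow(x), length(design$sample_ids),
                  class = "metanova_alignment_error")
  }
  is_inter <- grepl(":", terms, fixed = TRUE)
  if (sum(is_inter) > 1L) {
    stop_metanova("at most one two-factor interaction term is supported",
                  class = "metanova_design_error")
  }
  main_terms <- terms[!is_inter]
  inter_term <- terms[is_inter]
  needed <- unique(c(main_terms, unlist(strsplit(inter_term, ":", fixed = TRUE))))
  levels_list <- lapply(needed, function(f) design_levels(design, f, sample_ids))
  names(levels_list) <- needed

  # balance: all cells of the crossed design equally filled
  cell <- interaction(as.data.frame(levels_list), drop = FALSE)
  balanced <- length(unique(table(factor(cell)))) == 1L &&
    all(table(factor(cell)) > 0L)
  if (length(needed) > 1L && !balanced) {
    stop_metanova("unbalanced multi-factor design: balance it first (see balance_by_removal)",
                  class = "metanova_design_error")
  }

  grand <- colMeans(x)
  xc <- sweep(x, 2L, grand, `-`)
  effects <- list()
  for (f in main_terms) {
    lv <- levels_list[[f]]
    m <- rowsum(xc, lv) / as.vector(table(lv)[sort(unique(lv))])
    effects[[f]] <- m[lv, , drop = FALSE]
    rownames(effects[[f]]) <- rownames(x)
  }
  if (length(inter_term)) {
    fs <- strsplit(inter_term, ":", fixed = TRUE)[[1L]]
    if (length(fs) != 2L) {
      stop_metanova("interaction term '%s' must name exactly two factors",
                    inter_term, class = "metanova_design_error")
    }
    cl <- paste(levels_list[[fs[1L]]], levels_list[[fs[2L]]], sep = "\r")
    tab <- table(cl)
    if (any(tab == 0L)) {
      stop_metanova("empty design cell for interaction '%s'", inter_term,
                    class = "metanova_design_error")
    }
    cm <- rowsum(xc, cl) / as.vector(tab[sort(unique(cl))])
    effects[[inter_term]] <- cm[cl, , drop = FALSE] -
      effects[[fs[1L]]] - effects[[fs[2L]]]
    rownames(effects[[inter_term]]) <- rownames(x)
  }
  residuals <- xc - Reduce(`+`, effects, accumulate = FALSE)
  ssq_terms <- vapply(effects, ssq, numeric(1))
  ssq_res <- ssq(residuals)
  ssq_tot <- ssq(xc)
  structure(list(terms = c("mean", terms),
                 effect_matrices = effects,
                 residuals = residuals,
                 ssq = ssq_terms,
                 ssq_residual = ssq_res,
                 ssq_total = ssq_tot,
                 percent_variance = 100 * ssq_terms / ssq_tot,
                 balanced = balanced,
                 grand_mean = grand,
                 levels = levels_list),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat("<effect_decomposition>\n")
  for (t in names(x$ssq)) {
    cat(sprintf("  %-20s SSQ = %12.4g (%5.1f%%)\n", t, x$ssq[[t]],
                x$percent_variance[[t]]))
  }
  cat(sprintf("  %-20s SSQ = %12.4g (%5.1f%%)\n", "residuals",
              x$ssq_residual, 100 * x$ssq_residual / x$ssq_total))
  cat(sprintf("  balanced: %s\n", x$balanced))
  invisible(x)
}

#' Balance a one-factor design by random sample removal
#'
#' Randomly removes samples from over-represented levels until every level
#' has the minimum level count (the strategy used when one replicate is lost
#' and the permutation SSQ logic requires a balanced set).
#'
#' @param table a [feature_table()].
#' @param design a [design_table()] covering the table's samples.
#' @param factor_name the factor to balance on.
#' @param seed integer seed making the removal deterministic.
#' @return list with `features`, `design` (both subset), and `removed`
#'   (character IDs of the dropped samples).
#' @export
balance_by_removal <- function(table, design, factor_name, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "design_table"))
  lv <- design_levels(design, factor_name, table$sample_ids)
  counts <- table(lv)
  if (any(counts == 0L)) {
    stop_metanova("factor '%s' has an empty level", factor_name,
                  class = "metanova_design_error")
  }
  target <- min(counts)
  removed <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(l) {
      ids <- table$sample_ids[lv == l]
      excess <- length(ids) - target
      if (excess > 0L) sample(ids, excess) else character(0)
    }), use.names = FALSE)
  })
  keep <- setdiff(table$sample_ids, removed)
  features <- feature_table(table$values[keep, , drop = FALSE],
                            variable_kind = table$variable_kind,
                            is_internal_standard = table$is_internal_standard)
  design2 <- design_table(keep,
                          design$factors[keep, , drop = FALSE],
                          design$sample_amount[keep])
  list(features = features, design = design2, removed = removed)
}

#' Export an ANOVA decomposition to disk
#'
#' Writes one CSV per term (and residuals) plus a JSON SSQ summary.
#'
#' @param decomp an `effect_decomposition`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return paths written, invisibly.
#' @export
write_decomposition <- function(decomp, dir, prefix = "decomp") {
  stopifnot(inherits(decomp, "effect_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  mats <- c(decomp$effect_matrices, list(residuals = decomp$residuals))
  for (nm in names(mats)) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, gsub(":", "x", nm)))
    utils::write.csv(as.data.frame(mats[[nm]]), p, row.names = TRUE)
    paths <- c(paths, p)
  }
  pj <- file.path(dir, paste0(prefix, "_ssq.json"))
  jsonlite::write_json(list(ssq = as.list(decomp$ssq),
                            ssq_residual = decomp$ssq_residual,
                            ssq_total = decomp$ssq_total,
                            percent_variance = as.list(decomp$percent_variance),
                            balanced = decomp$balanced),
                       pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}
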