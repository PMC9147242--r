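#' Component model container
#'
#' Scores/loadings/explained-variance triple shared by SCA, group-wise PCA,
#' canonical (rMANOVA), PCA and PLS fits.  Loadings columns are unit-norm with
#' the sign convention that each column's largest-magnitude entry is positive.
#'
#' @param method one of `"sca"`, `"gpca"`, `"canonical"`, `"pca"`, `"pls"`.
#' @param scores samples x components matrix.
#' @param loadings variables x components matrix (unit-norm columns).
#' @param explained fraction of variance per component.
#' @param augmented_scores optional scores of effect + projected residuals.
#' @return an object of class `component_model`.
#' @export
component_model <- function(method, scores, loadings, explained,
                            augmented_scores = NULL) {
  structure(list(method = method, scores = scores, loadings = loadings,
                 explained = explained, augmented_scores = augmented_scores),
            class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf("<component_model:%s> %d component(s); explained: %s\n",
              x$method, ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Simultaneous component analysis of an effect matrix
#'
#' PCA-like bilinear decomposition of an ANOVA effect matrix via its singular
#' value decomposition.  Scores of samples sharing a level are identical (the
#' effect rows are level means); the optional residual-augmented scores
#' project effect + residuals onto the same loadings, restoring within-group
#' spread for display.
#'
#' @param effect effect matrix (samples x variables) from
#'   [decompose_effects()].
#' @param residuals residual matrix from the same decomposition (optional,
#'   enables augmented scores).
#' @param n_components number of components (default: the effect rank, at
#'   most `rank(effect)`).
#' @return a [component_model()] with method `"sca"`; `explained` is squared
#'   singular value over the effect SSQ.
#' @export
fit_sca <- function(effect, residuals = NULL, n_components = NULL) {
  effect <- as.matrix(effect)
  total <- ssq(effect)
  if (total == 0) {
    stop_metanova("no effect variance: the effect matrix is all zeros",
                  class = "metanova_model_error")
  }
  sv <- svd(effect)
  rank <- sum(sv$d > max(sv$d) * 1e-9)
  a <- n_components %||% rank
  if (a > rank) {
    stop_metanova("n_components (%d) exceeds the effect matrix rank (%d)",
                  a, rank, class = "metanova_model_error")
  }
  loadings <- fix_signs(sv$v[, seq_len(a), drop = FALSE])
  rownames(loadings) <- colnames(effect)
  scores <- effect %*% loadings
  augmented <- if (!is.null(residuals)) (effect + as.matrix(residuals)) %*% loadings
  component_model("sca", scores, loadings,
                  explained = sv$d[seq_len(a)]^2 / total,
                  augmented_scores = augmented)
}

#' Permutation result container
#'
#' @param statistic_observed observed statistic on the true assignment.
#' @param statistic_permuted vector of permuted statistics.
#' @param p_value `(#\{permuted > observed\} + 1) / (n_permutations + 1)`.
#' @param seed seed used.
#' @param term tested term.
#' @param statistic statistic tag.
#' @return an object of class `permutation_result`.
#' @export
permutation_result <- function(statistic_observed, statistic_permuted,
                               p_value, seed, term, statistic) {
  structure(list(statistic_observed = statistic_observed,
                 statistic_permuted = statistic_permuted,
                 n_permutations = length(statistic_permuted),
                 p_value = p_value, seed = seed, term = term,
                 statistic = statistic),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> term '%s', statistic %s = %.6g, %d permutations, p = %.4g\n",
              x$term, x$statistic, x$statistic_observed, x$n_permutations,
              x$p_value))
  invisible(x)
}

# Exceedances are counted strictly (permuted > observed): permutations that
# recreate the observed partition give the same statistic up to summation
# order, and counting those ties would put the attainable floor at ~7e-4
# instead of 1e-4 for a balanced 7v7 design.  The tolerance keeps bitwise
# reordering noise from turning an exact tie into an exceedance.
tie_tol <- function(obs) abs(obs) * 1e-10

#' SSQ permutation test of a design term
#'
#' Shared significance engine of the three ANOVA-based methods.  The observed
#' statistic is computed on the true row-to-design assignment; each
#' permutation shuffles the rows of the data matrix against the whole design
#' uniformly at random (unrestricted), recomputes the decomposition and the
#' statistic.  The p-value is `(b + 1) / (N + 1)` where `b` counts permuted
#' statistics strictly larger than the observed one (permutations recreating
#' the observed partition tie exactly and do not count), so the smallest
#' attainable p with 10,000 permutations is 0.0001.
#'
#' Statistic tags: `"asca_ssq"` (SSQ of the term's effect matrix),
#' `"rmanova_trace"` (regularized Lawley-Hotelling trace, see
#' [fit_rmanova()]), `"gasca_ssq"` (SSQ explained by the first group-wise
#' component, see [fit_gasca()]).
#'
#' With `exact = TRUE` all distinct level assignments of a one-factor design
#' are enumerated instead of sampled, and the p-value is the exact proportion
#' of assignments (identity included) whose statistic reaches the observed
#' one.
#'
#' @param X numeric matrix or [feature_table()] (rows aligned to `design`).
#' @param design a [design_table()].
#' @param term tested term name.
#' @param n_permutations number of random permutations (default 10,000).
#' @param seed integer seed.
#' @param statistic statistic tag.
#' @param exact enumerate all assignments instead of sampling (one-factor
#'   terms only, guarded by a count cap).
#' @param model_terms terms of the fitted model (defaults to `term`);
#'   relevant when the statistic is the SSQ of one term of a two-factor
#'   model.
#' @param delta rMANOVA regularization factor in \[0,1\] or `"auto"`
#'   (re-estimated inside each permutation).
#' @param groups optional [find_groups()] result for `"gasca_ssq"`.
#' @param threshold grouping threshold when `groups` is `NULL`.
#' @return a [permutation_result()].
#' @export
permutation_test <- function(X, design, term,
                             n_permutations = 10000, seed = 1L,
                             statistic = c("asca_ssq", "rmanova_trace",
                                           "gasca_ssq"),
                             exact = FALSE,
                             model_terms = term,
                             delta = "auto",
                             groups = NULL, threshold = 0.7) {
  statistic <- match.arg(statistic)
  if (!exact && n_permutations < 1) {
    stop_metanova("n_permutations must be >= 1",
                  class = "metanova_permutation_error")
  }
  x <- as_values(X)
  n <- nrow(x)
  stat_fun <- make_stat_fun(statistic, x, design, term, model_terms,
                            delta = delta, groups = groups,
                            threshold = threshold)
  obs <- stat_fun(seq_len(n))

  if (exact) {
    if (length(model_terms) != 1L || grepl(":", term, fixed = TRUE)) {
      stop_metanova("exact enumeration supports one-factor terms only",
                    class = "metanova_permutation_error")
    }
    lv <- as.character(design_levels(design, term,
                                     rownames(x) %||% design$sample_ids))
    assignments <- multiset_permutations(lv)
    # build, for each enumerated label assignment, a row permutation under
    # which the engine's fast path sees exactly those labels
    stats_all <- vapply(assignments, function(lab) {
      inv <- integer(n)
      for (l in unique(lv)) inv[lab == l] <- which(lv == l)
      stat_fun(invert_perm(inv))
    }, numeric(1))
    # drop one instance matching the identity assignment
    id_at <- which(vapply(assignments, identical, logical(1), as.character(lv)))[1L]
    permuted <- stats_all[-id_at]
    b <- sum(permuted > obs + tie_tol(obs))
    return(permutation_result(obs, permuted,
                              p_value = (b + 1) / (length(permuted) + 1),
                              seed = NA_integer_, term = term,
                              statistic = statistic))
  }

  permuted <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(i) stat_fun(sample.int(n)), numeric(1))
  })
  b <- sum(permuted > obs + tie_tol(obs))
  permutation_result(obs, permuted, p_value = (b + 1) / (n_permutations + 1),
                     seed = seed, term = term, statistic = statistic)
}

# Builds a closure evaluating the statistic for a given row permutation of X
# (identity = observed).  One-factor terms use closed-form fast paths; other
# models fall back to a full decomposition per permutation.
make_stat_fun <- function(statistic, x, design, term, model_terms,
                          delta = "auto", groups = NULL, threshold = 0.7) {
  sample_ids <- rownames(x) %||% design$sample_ids
  one_factor <- length(model_terms) == 1L && identical(model_terms, term) &&
    !grepl(":", term, fixed = TRUE)

  if (statistic %in% c("rmanova_trace") && !one_factor) {
    stop_metanova("rMANOVA supports single-factor terms only",
                  class = "metanova_design_error")
  }

  if (one_factor) {
    lv <- design_levels(design, term, sample_ids)
    xc <- sweep(x, 2L, colMeans(x), `-`)
    lv_f <- factor(lv, levels = unique(lv))
    counts <- as.vector(table(lv_f))
    k <- nlevels(lv_f)
    n <- nrow(x)
    lv_int <- as.integer(lv_f)

    if (statistic == "asca_ssq") {
      return(function(perm) {
        g <- lv_int[invert_perm(perm)]
        sums <- rowsum(xc, g, reorder = TRUE)
        sum(rowSums(sums^2) / counts)
      })
    }
    if (statistic == "rmanova_trace") {
      return(make_rmanova_stat(xc, lv_int, counts, k, delta))
    }
    if (statistic == "gasca_ssq") {
      if (is.null(groups)) groups <- find_groups(x, threshold)
      gidx <- lapply(groups$groups, function(g) match_group(g, colnames(x), ncol(x)))
      return(function(perm) {
        g <- lv_int[invert_perm(perm)]
        sums <- rowsum(xc, g, reorder = TRUE)          # k x p group sums
        m <- sums / counts                             # level means
        wm <- m * sqrt(counts)                         # rows scaled by sqrt(n_g)
        max(vapply(gidx, function(j) {
          wg <- wm[, j, drop = FALSE]
          if (k == 2L) sum(wg^2) else max(eigen(tcrossprod(wg),
                                                symmetric = TRUE,
                                                only.values = TRUE)$values)
        }, numeric(1)))
      })
    }
  }

  # generic path: permute the design rows against a fixed X
  function(perm) {
    dp <- design
    dp$factors <- design$factors[perm, , drop = FALSE]
    rownames(dp$factors) <- design$sample_ids
    d <- decompose_effects(x, dp, model_terms)
    if (statistic == "asca_ssq") {
      d$ssq[[term]]
    } else if (statistic == "gasca_ssq") {
      gr <- groups %||% find_groups(x, threshold)
      fit_gasca(d$effect_matrices[[term]], gr, n_components = 1L)$explained_ssq[1L]
    } else {
      stop_metanova("unsupported statistic for multi-factor models",
                    class = "metanova_design_error")
    }
  }
}

invert_perm <- function(perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  inv
}

match_group <- function(g, var_names, p) {
  if (is.numeric(g)) return(as.integer(g))
  idx <- match(g, var_names)
  if (anyNA(idx)) {
    stop_metanova("unknown variable in group: %s",
                  paste(g[is.na(idx)], collapse = ", "),
                  class = "metanova_model_error")
  }
  idx
}

#' One-stop ASCA analysis of one design term
#'
#' Convenience wrapper: mean-centering ANOVA decomposition, SCA of the term's
#' effect matrix (with residual-augmented scores), and the SSQ permutation
#' test.
#'
#' @inheritParams permutation_test
#' @param n_components SCA components (default effect rank).
#' @return list of class `asca_result`: `decomposition`, `model`
#'   ([component_model()]), `permutation` ([permutation_result()]).
#' @export
asca <- function(X, design, term, n_permutations = 10000, seed = 1L,
                 n_components = NULL, model_terms = term) {
  decomp <- decompose_effects(X, design, model_terms)
  model <- fit_sca(decomp$effect_matrices[[term]], decomp$residuals,
                   n_components)
  perm <- permutation_test(X, design, term, n_permutations, seed,
                           statistic = "asca_ssq", model_terms = model_terms)
  structure(list(decomposition = decomp, model = model, permutation = perm),
            class = "asca_result")
}

#' @export
print.asca_result <- function(x, ...) {
  cat("ASCA\n")
  print(x$model)
  print(x$permutation)
  invisible(x)
}
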