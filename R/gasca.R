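#' Identify groups of correlated variables
#'
#' Deterministic grouping for group-wise ASCA: variables are nodes, edges
#' connect pairs with absolute Pearson correlation at or above `threshold`,
#' and groups are the connected components (singletons allowed).  This is a
#' documented simplification of the original group-identification algorithms
#' used with group-wise PCA.  Constant columns have undefined correlations
#' and are isolated as singletons with a warning.
#'
#' @param X numeric matrix or [feature_table()] (>= 2 rows).
#' @param threshold absolute-correlation threshold in (0, 1].
#' @return an object of class `variable_groups`: `groups` (list of integer
#'   index vectors, each sorted, ordered by first member), `threshold`,
#'   `source = "correlation"`, `variable_ids`.
#' @export
find_groups <- function(X, threshold = 0.7) {
  x <- as_values(X)
  if (nrow(x) < 2L) {
    stop_metanova("find_groups requires at least 2 samples",
                  class = "metanova_model_error")
  }
  assert_scalar_number(threshold, "threshold", min = 1e-12, max = 1)
  p <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sprintf("find_groups: %d constant column(s) isolated as singletons",
                    sum(const)))
  }
  adj <- matrix(FALSE, p, p)
  ok <- which(!const)
  if (length(ok) >= 2L) {
    r <- suppressWarnings(stats::cor(x[, ok, drop = FALSE]))
    # small slack so exact duplicates pass a threshold of 1 despite rounding
    adj[ok, ok] <- abs(r) >= threshold - 1e-12
  }
  diag(adj) <- FALSE
  # connected components by BFS
  comp <- integer(p)
  cur <- 0L
  for (v in seq_len(p)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  groups <- split(seq_len(p), comp)
  groups <- lapply(unname(groups), sort)
  structure(list(groups = groups, threshold = threshold,
                 source = "correlation",
                 variable_ids = colnames(x) %||% as.character(seq_len(p))),
            class = "variable_groups")
}

#' User-supplied variable groups
#'
#' @param groups list of variable index (or ID) vectors; overlap allowed.
#' @param variable_ids optional full ID vector.
#' @return a `variable_groups` object with `source = "user"`.
#' @export
variable_groups <- function(groups, variable_ids = NULL) {
  if (!length(groups) || any(!lengths(groups))) {
    stop_metanova("groups must be a non-empty list of non-empty vectors",
                  class = "metanova_model_error")
  }
  structure(list(groups = groups, threshold = NA_real_, source = "user",
                 variable_ids = variable_ids),
            class = "variable_groups")
}

#' @export
print.variable_groups <- function(x, ...) {
  sz <- lengths(x$groups)
  cat(sprintf("<variable_groups:%s> %d group(s); sizes: %s%s\n",
              x$source, length(sz),
              paste(utils::head(sort(sz, decreasing = TRUE), 10), collapse = ", "),
              if (length(sz) > 10) ", ..." else ""))
  invisible(x)
}

#' Group-wise sparse components of an effect matrix
#'
#' Group-wise PCA applied to an ANOVA effect matrix: at each step, for every
#' candidate group the leading right singular vector of the effect submatrix
#' restricted to that group is computed together with the SSQ it explains;
#' the best group wins (ties broken by group order), the component loading is
#' that vector embedded in full variable space with zeros outside the group,
#' and the effect matrix is deflated by the rank-1 fit.  Each component's
#' support therefore lies inside exactly one group, which is what makes the
#' loadings interpretable for correlated metabolite panels.
#'
#' @param effect effect matrix (samples x variables).
#' @param groups a `variable_groups` from [find_groups()] or
#'   [variable_groups()].
#' @param n_components number of components to extract.
#' @return a [component_model()] with method `"gpca"` plus extra fields
#'   `component_groups` (index of the group supporting each component) and
#'   `explained_ssq` (absolute SSQ explained per component); `explained` is
#'   relative to the initial effect SSQ.
#' @export
fit_gasca <- function(effect, groups, n_components = 1L) {
  effect <- as.matrix(effect)
  stopifnot(inherits(groups, "variable_groups"))
  assert_scalar_number(n_components, "n_components", min = 1, integer = TRUE)
  total <- ssq(effect)
  if (total == 0) {
    stop_metanova("no effect variance: the effect matrix is all zeros",
                  class = "metanova_model_error")
  }
  p <- ncol(effect)
  gidx <- lapply(groups$groups, match_group,
                 var_names = colnames(effect), p = p)

  loadings <- matrix(0, p, n_components)
  scores <- matrix(0, nrow(effect), n_components)
  expl_ssq <- numeric(n_components)
  comp_group <- integer(n_components)
  current <- effect
  for (a in seq_len(n_components)) {
    best <- 0; best_g <- 0L; best_v <- NULL
    for (gi in seq_along(gidx)) {
      sub <- current[, gidx[[gi]], drop = FALSE]
      sv <- svd(sub, nu = 0L, nv = 1L)
      if (sv$d[1L]^2 > best + best * 1e-12) {
        best <- sv$d[1L]^2
        best_g <- gi
        best_v <- sv$v[, 1L]
      }
    }
    if (best <= total * 1e-18) {
      stop_metanova("only %d non-trivial component(s) extractable, %d requested",
                    a - 1L, n_components, class = "metanova_model_error")
    }
    v <- numeric(p)
    v[gidx[[best_g]]] <- best_v
    i_max <- which.max(abs(v))
    if (v[i_max] < 0) v <- -v
    t_a <- current %*% v
    current <- current - tcrossprod(t_a, v)
    loadings[, a] <- v
    scores[, a] <- t_a
    expl_ssq[a] <- best
    comp_group[a] <- best_g
  }
  rownames(loadings) <- colnames(effect)
  m <- component_model("gpca", scores, loadings, explained = expl_ssq / total)
  m$component_groups <- comp_group
  m$explained_ssq <- expl_ssq
  m
}

#' Permutation significance of a factor under group-wise ASCA
#'
#' [permutation_test()] with the `gasca_ssq` statistic: the SSQ explained by
#' the first group-wise component of the term's effect matrix.  Variable
#' groups come from [find_groups()] on the data matrix; column correlations
#' are invariant under row permutation, so the groups computed once equal the
#' groups of every permuted matrix.
#'
#' @inheritParams permutation_test
#' @return a [permutation_result()].
#' @export
gasca_significance <- function(X, design, term, n_permutations = 10000,
                               seed = 1L, threshold = 0.7, groups = NULL,
                               exact = FALSE) {
  permutation_test(X, design, term, n_permutations, seed,
                   statistic = "gasca_ssq", exact = exact,
                   groups = groups, threshold = threshold)
}

#' One-stop group-wise ASCA analysis of one design term
#'
#' @inheritParams gasca_significance
#' @param n_components group-wise components to extract.
#' @return list of class `gasca_result`: `decomposition`, `groups`, `model`,
#'   `permutation`.
#' @export
gasca <- function(X, design, term, n_permutations = 10000, seed = 1L,
                  threshold = 0.7, n_components = 1L) {
  decomp <- decompose_effects(X, design, term)
  groups <- find_groups(X, threshold)
  model <- fit_gasca(decomp$effect_matrices[[term]], groups, n_components)
  perm <- permutation_test(X, design, term, n_permutations, seed,
                           statistic = "gasca_ssq", groups = groups)
  structure(list(decomposition = decomp, groups = groups, model = model,
                 permutation = perm),
            class = "gasca_result")
}

#' @export
print.gasca_result <- function(x, ...) {
  cat("GASCA\n")
  print(x$groups)
  print(x$model)
  print(x$permutation)
  invisible(x)
}
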