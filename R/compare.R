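#' Top-k relevant-variable selection
#'
#' Ranks variables by decreasing relevance and returns the top k (default
#' 50, the size used to compare method concordance).  ANOVA-based component
#' models are ranked by the absolute value of the first-component loading
#' (SCA loading 1 for ASCA, canonical loading 1 for rMANOVA, group-wise
#' loading 1 for GASCA); PLS references are ranked by the VIP or selectivity
#' ratio value itself.  Ties are broken by ascending variable index, so the
#' selection is deterministic.
#'
#' @param x a [component_model()], `rmanova_model`, or a named numeric score
#'   vector (VIP, SR, 1 - adjusted p, ...).
#' @param method method tag recorded in the result.
#' @param k selection size; if larger than the number of variables, all
#'   variables are returned with a warning.
#' @return an object of class `selection_result`: `method`, `ranking`
#'   (variable IDs by decreasing relevance), `score` (named, in input order),
#'   `top_k` (character set), `k`.
#' @export
select_top_k <- function(x, method, k = 50L) {
  assert_scalar_number(k, "k", min = 1, integer = TRUE)
  score <- selection_score(x)
  ids <- names(score) %||% as.character(seq_along(score))
  if (k > length(score)) {
    warning(sprintf("k = %d exceeds %d variables: selecting all", k,
                    length(score)))
    k <- length(score)
  }
  ord <- order(-score, seq_along(score))
  ranking <- ids[ord]
  structure(list(method = method, ranking = ranking,
                 score = stats::setNames(as.numeric(score), ids),
                 top_k = ranking[seq_len(k)], k = as.integer(k)),
            class = "selection_result")
}

selection_score <- function(x) {
  if (inherits(x, "component_model")) {
    abs(stats::setNames(x$loadings[, 1L], rownames(x$loadings)))
  } else if (inherits(x, "rmanova_model")) {
    selection_score(x$canonical)
  } else if (is.numeric(x)) {
    x
  } else {
    stop_metanova("cannot rank object of class '%s'", class(x)[1L],
                  class = "metanova_model_error")
  }
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result:%s> top %d of %d variables; head: %s\n",
              x$method, x$k, length(x$score),
              paste(utils::head(x$top_k, 5), collapse = ", ")))
  invisible(x)
}

#' Venn partition of method selections
#'
#' Exact element counts for every non-empty region signature of 2-5 sets:
#' the counts over all regions containing a method reconstruct that method's
#' set size, and all counts sum to the union size.
#'
#' @param sets named list (method -> character vector) of selected variable
#'   IDs.
#' @return named integer vector; names are region signatures like `"A&B"`
#'   (methods joined by `&`), covering all `2^m - 1` regions.
#' @export
venn_partition <- function(sets) {
  m <- length(sets)
  if (m < 2L || m > 5L) {
    stop_metanova("venn_partition supports 2 to 5 sets, got %d", m,
                  class = "metanova_model_error")
  }
  methods <- names(sets) %||% LETTERS[seq_len(m)]
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  signature_of <- function(mask) paste(methods[mask], collapse = "&")
  counts <- integer(0)
  for (bits in seq_len(2^m - 1L)) {
    mask <- as.logical(bitwAnd(bits, 2^(seq_len(m) - 1L)))
    inside <- apply(membership, 1L, function(row) all(row == mask))
    counts[signature_of(mask)] <- sum(inside)
  }
  counts
}

#' Pairwise correlation of method relevance profiles
#'
#' Pearson correlation between variable-indexed relevance profiles (e.g.
#' absolute first loadings vs VIP vs SR).  ANOVA loadings are signed while
#' VIP/SR are non-negative, so callers normally pass absolute loadings (the
#' workflow does this by default).  Zero-variance profiles yield `NA` with a
#' warning.
#'
#' @param profiles named list of equal-length numeric vectors.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
profile_correlation <- function(profiles) {
  if (length(unique(lengths(profiles))) != 1L) {
    stop_metanova("profiles must have equal length",
                  class = "metanova_model_error")
  }
  mat <- do.call(cbind, profiles)
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance profile(s): %s",
                    paste(colnames(mat)[sds == 0], collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(mat))
  diag(r) <- 1
  r
}

#' Coincidence counts with a reference selection
#'
#' Size of the intersection of each method's top-k set with the reference
#' method's top-k set (by convention PLS-DA VIP scores, the field's reference
#' variable-selection method).
#'
#' @param selections named list of [select_top_k()] results (or plain
#'   character sets).
#' @param reference name of the reference method present in `selections`.
#' @return named integer vector (one count per non-reference method), each
#'   bounded by k.
#' @export
coincidence_with_reference <- function(selections, reference = "plsda_vip") {
  if (!reference %in% names(selections)) {
    stop_metanova("reference method '%s' missing from selections", reference,
                  class = "metanova_model_error")
  }
  as_set <- function(s) if (inherits(s, "selection_result")) s$top_k else
    as.character(s)
  ref <- as_set(selections[[reference]])
  out <- vapply(selections[setdiff(names(selections), reference)],
                function(s) length(intersect(as_set(s), ref)), integer(1))
  out
}
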