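# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Sum of squared elements
#'
#' The SSQ of a matrix (or vector): the sum of its squared elements.  This is
#' the effect-size measure and permutation statistic used throughout the
#' ANOVA-based methods.
#'
#' @param x numeric matrix or vector.
#' @return a single non-negative number.
#' @export
ssq <- function(x) sum(x * x)

stop_metanova <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "metanova_error", "error"),
                      call = sys.call(-1)))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x <= max && (!integer || x == round(x))
  if (!ok) {
    stop_metanova("invalid configuration: field '%s' must be a %s in [%s, %s], got %s",
                  name, if (integer) "whole number" else "number",
                  format(min), format(max),
                  paste(format(x), collapse = ","),
                  class = "metanova_config_error")
  }
  invisible(x)
}

# Flip the sign of each column so its largest-magnitude entry is positive.
# Applied to all loading matrices (shared sign convention); scores flipped
# in step by the caller.
fix_signs <- function(loadings) {
  flip <- apply(loadings, 2L, function(v) {
    i <- which.max(abs(v))
    if (v[i] < 0) -1 else 1
  })
  sweep(loadings, 2L, flip, `*`)
}

unit_cols <- function(m) {
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- 1
  sweep(m, 2L, nrm, `/`)
}

# All distinct permutations of a label vector (multiset permutations),
# returned as a list of index-free label vectors. Guarded by a hard cap.
multiset_permutations <- function(labels, cap = 1e5) {
  labels <- as.character(labels)
  tab <- table(labels)
  n_total <- exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
  if (n_total > cap) {
    stop_metanova("exact enumeration would require %.0f assignments (cap %g)",
                  n_total, cap, class = "metanova_enumeration_error")
  }
  rec <- function(counts) {
    if (sum(counts) == 0L) return(list(character(0)))
    out <- list()
    for (lv in names(counts)) {
      if (counts[[lv]] == 0L) next
      counts2 <- counts
      counts2[[lv]] <- counts2[[lv]] - 1L
      for (tail in rec(counts2)) out[[length(out) + 1L]] <- c(lv, tail)
    }
    out
  }
  rec(stats::setNames(as.integer(tab), names(tab)))
}
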