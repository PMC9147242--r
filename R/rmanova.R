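# Ledoit-Wolf shrinkage intensity toward the scaled identity target, computed
# from the Gram matrix of within-group-centered rows (1/n pilot convention).
lw_intensity_from_gram <- function(Gr, n, p) {
  trG <- sum(diag(Gr))
  if (trG <= 0) return(0)
  m <- trG / (n * p)
  fro2 <- sum(Gr^2)                 # ||R'R||_F^2 = ||RR'||_F^2
  d2 <- fro2 / (n^2 * p) - m^2
  if (d2 <= .Machine$double.eps * m^2) return(0)
  b2 <- (sum(diag(Gr)^2) - fro2 / n) / (n^2 * p)
  min(max(b2, 0), d2) / d2
}

# One-factor residual rows (within-group centered X) and bookkeeping.
within_group_residuals <- function(x, lv) {
  lv_f <- factor(lv, levels = unique(lv))
  counts <- as.vector(table(lv_f))
  if (any(counts < 2L)) {
    stop_metanova("cannot estimate within-group covariance: level '%s' has fewer than 2 samples",
                  levels(lv_f)[counts < 2L][1L], class = "metanova_design_error")
  }
  g <- as.integer(lv_f)
  m <- rowsum(x, g, reorder = TRUE) / counts
  list(residuals = x - m[g, , drop = FALSE], counts = counts,
       k = nlevels(lv_f), g = g)
}

#' Ledoit-Wolf regularization factor for the within-group covariance
#'
#' Estimates the shrinkage intensity delta in \[0,1\] of the pooled
#' within-group covariance toward the scaled identity target
#' `gamma * I`, `gamma = trace(S)/p`, using the Ledoit-Wolf single-target
#' estimator applied to the within-group-centered rows.  `delta = 0` leaves
#' the covariance untouched (MANOVA); `delta = 1` replaces it entirely by the
#' identity target (ASCA).  In p >> n data the estimate approaches 1, in
#' n >> p data it approaches 0.
#'
#' The paper behind this workflow names only "the Ledoit-Wolf theorem" for
#' this step; the transcription here follows the original single-target
#' shrinkage estimator (see the methods vignette for the exact convention).
#'
#' @param X numeric matrix or [feature_table()].
#' @param design a [design_table()].
#' @param term single-factor term; every level needs >= 2 samples.
#' @return shrinkage intensity in \[0, 1\].
#' @export
estimate_delta <- function(X, design, term) {
  x <- as_values(X)
  lv <- design_levels(design, term, rownames(x) %||% design$sample_ids)
  w <- within_group_residuals(x, lv)
  lw_intensity_from_gram(tcrossprod(w$residuals), nrow(x), ncol(x))
}

#' Regularized MANOVA of one design factor
#'
#' Computes the between-group scatter `H = E'E` of the factor's effect
#' matrix, the pooled within-group scatter `S = R'R / (n - k)`, the
#' regularized within covariance `W = (1 - delta) S + delta gamma I`
#' (`gamma = trace(S)/p`), the Lawley-Hotelling-type test statistic
#' `trace(W^{-1} H)` and the canonical variates (leading eigenvectors of
#' `W^{-1} H`, computed in the symmetrized whitened form for numerical
#' stability).  `delta = 1` recovers ASCA: the statistic becomes a monotone
#' transform of the effect SSQ, so permutation p-values coincide with ASCA's
#' seed for seed.  `delta = 0` with `n > p` is classical MANOVA.
#'
#' @param X numeric matrix or [feature_table()].
#' @param design a [design_table()].
#' @param term single-factor term.
#' @param delta number in \[0,1\] or `"auto"` ([estimate_delta()]).
#' @param n_components canonical components (default: rank of H, i.e. number
#'   of levels minus 1).
#' @return an object of class `rmanova_model`: `delta`, `within_scatter`,
#'   `between_scatter`, `regularized_within`, `statistic`, `canonical`
#'   ([component_model()]), `term`.
#' @export
fit_rmanova <- function(X, design, term, delta = "auto", n_components = NULL) {
  x <- as_values(X)
  n <- nrow(x); p <- ncol(x)
  lv <- design_levels(design, term, rownames(x) %||% design$sample_ids)
  xc <- sweep(x, 2L, colMeans(x), `-`)
  w <- within_group_residuals(xc, lv)
  k <- w$k
  E <- xc - w$residuals    # level-mean matrix replicated per sample
  R <- w$residuals

  if (identical(delta, "auto")) {
    delta <- lw_intensity_from_gram(tcrossprod(R), n, p)
  }
  assert_scalar_number(delta, "delta", min = 0, max = 1)

  S <- crossprod(R) / (n - k)
  gamma <- sum(diag(S)) / p
  if (gamma <= 0) {
    stop_metanova("no residual variance: within-group scatter is zero",
                  class = "metanova_model_error")
  }
  W <- (1 - delta) * S
  diag(W) <- diag(W) + delta * gamma
  H <- crossprod(E)

  ew <- eigen(W, symmetric = TRUE)
  tol <- max(ew$values) * 1e-10
  if (min(ew$values) <= tol) {
    stop_metanova("regularized within-covariance is singular (delta = %g, p = %d, n - k = %d): use delta > 0",
                  delta, p, n - k, class = "metanova_singularity_error")
  }
  whalf <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))  # W^{-1/2}
  msym <- whalf %*% H %*% whalf
  msym <- (msym + t(msym)) / 2
  es <- eigen(msym, symmetric = TRUE)
  statistic <- sum(pmax(es$values, 0))

  r <- min(k - 1L, p)
  a <- n_components %||% r
  if (a > r) {
    stop_metanova("n_components (%d) exceeds the between-scatter rank (%d)",
                  a, r, class = "metanova_model_error")
  }
  loadings <- unit_cols(whalf %*% es$vectors[, seq_len(a), drop = FALSE])
  loadings <- fix_signs(loadings)
  rownames(loadings) <- colnames(x)
  canonical <- component_model("canonical",
                               scores = xc %*% loadings,
                               loadings = loadings,
                               explained = pmax(es$values[seq_len(a)], 0) /
                                 max(statistic, .Machine$double.xmin))
  structure(list(delta = delta, within_scatter = S, between_scatter = H,
                 regularized_within = W, statistic = statistic,
                 canonical = canonical, term = term),
            class = "rmanova_model")
}

#' @export
print.rmanova_model <- function(x, ...) {
  cat(sprintf("<rmanova_model> term '%s', delta = %.4f, trace statistic = %.6g\n",
              x$term, x$delta, x$statistic))
  invisible(x)
}

#' Permutation significance of a factor under regularized MANOVA
#'
#' [permutation_test()] with the `rmanova_trace` statistic.  With
#' `delta = "auto"` the shrinkage intensity is re-estimated inside every
#' permutation (the estimator is part of the procedure, keeping the null
#' exchangeable).
#'
#' @inheritParams permutation_test
#' @return a [permutation_result()].
#' @export
rmanova_significance <- function(X, design, term, delta = "auto",
                                 n_permutations = 10000, seed = 1L,
                                 exact = FALSE) {
  permutation_test(X, design, term, n_permutations, seed,
                   statistic = "rmanova_trace", exact = exact, delta = delta)
}

# Fast rmanova_trace statistic closure for the permutation engine.
# Direct dense route for p <= n; Gram-matrix (Woodbury) route for p > n.
make_rmanova_stat <- function(xc, lv_int, counts, k, delta) {
  n <- nrow(xc); p <- ncol(xc)
  if (any(counts < 2L)) {
    stop_metanova("cannot estimate within-group covariance: a level has fewer than 2 samples",
                  class = "metanova_design_error")
  }
  auto <- identical(delta, "auto")
  if (!auto) assert_scalar_number(delta, "delta", min = 0, max = 1)

  if (p <= n) {
    return(function(perm) {
      g <- lv_int[invert_perm(perm)]
      m <- rowsum(xc, g, reorder = TRUE) / counts
      E <- m[g, , drop = FALSE]
      R <- xc - E
      d <- if (auto) lw_intensity_from_gram(tcrossprod(R), n, p) else delta
      S <- crossprod(R) / (n - k)
      gamma <- sum(diag(S)) / p
      if (gamma <= 0) {
        stop_metanova("no residual variance: within-group scatter is zero",
                      class = "metanova_model_error")
      }
      W <- (1 - d) * S
      diag(W) <- diag(W) + d * gamma
      H <- crossprod(E)
      st <- try(sum(diag(solve(W, H))), silent = TRUE)
      if (inherits(st, "try-error")) {
        stop_metanova("regularized within-covariance is singular (delta = %g): use delta > 0",
                      d, class = "metanova_singularity_error")
      }
      st
    })
  }

  G <- tcrossprod(xc)
  function(perm) {
    g <- lv_int[invert_perm(perm)]
    GZ <- t(rowsum(t(G), g, reorder = TRUE))          # n x k column-group sums
    GP <- sweep(GZ, 2L, counts, `/`)[, g, drop = FALSE]  # G P
    C <- rowsum(GZ, g, reorder = TRUE)                # k x k: Z'GZ
    PGP <- (C / outer(counts, counts))[g, g, drop = FALSE]
    Gr <- G - GP - t(GP) + PGP                        # RR'
    B <- GP - PGP                                     # RE'
    ssqE <- sum(diag(C) / counts)
    d <- if (auto) lw_intensity_from_gram(Gr, n, p) else delta
    ssqR <- sum(diag(Gr))
    gamma <- ssqR / ((n - k) * p)
    if (gamma <= 0) {
      stop_metanova("no residual variance: within-group scatter is zero",
                    class = "metanova_model_error")
    }
    if (d == 0) {
      stop_metanova("regularized within-covariance is singular (delta = 0 with p >= n - k): use delta > 0",
                    class = "metanova_singularity_error")
    }
    cc <- d * gamma
    A <- (1 - d) / (n - k)
    if (A == 0) return(ssqE / cc)                     # delta = 1: pure ASCA scale
    Q <- diag(n) + (A / cc) * Gr
    ssqE / cc - (A / cc^2) * sum(diag(solve(Q, tcrossprod(B))))
  }
}
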