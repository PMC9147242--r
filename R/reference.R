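#' Principal component analysis for data exploration
#'
#' Standard PCA via the singular value decomposition after mean-centering
#' (TIC matrices) or autoscaling (feature matrices).
#'
#' @param X numeric matrix or [feature_table()].
#' @param scaling `"center"` or `"autoscale"`.
#' @param n_components number of components (default: rank).
#' @return a [component_model()] with method `"pca"`; `explained` is variance
#'   fraction of the scaled matrix.
#' @export
fit_pca <- function(X, scaling = c("center", "autoscale"), n_components = NULL) {
  scaling <- match.arg(scaling)
  xs <- apply_scaling(X, scaling)
  sv <- svd(xs)
  rank <- sum(sv$d > max(sv$d) * 1e-9)
  a <- min(n_components %||% rank, rank)
  loadings <- fix_signs(sv$v[, seq_len(a), drop = FALSE])
  rownames(loadings) <- colnames(xs)
  component_model("pca", scores = xs %*% loadings, loadings = loadings,
                  explained = sv$d[seq_len(a)]^2 / sum(sv$d^2))
}

#' Partial least squares discriminant analysis
#'
#' NIPALS PLS2 regression of the scaled data matrix on a class-indicator
#' response: a single 0/1 column for two classes, one indicator column per
#' class for three.  X is scaled per `scaling` (mean-centered for TIC data,
#' autoscaled for feature matrices); Y is mean-centered.  Deterministic.
#'
#' @param X numeric matrix or [feature_table()].
#' @param classes factor/character of class labels (2 or 3 classes, each with
#'   >= 2 samples).
#' @param n_latent number of latent variables (default 2).
#' @param scaling `"center"`, `"autoscale"` or `"none"` (X scaled by caller).
#' @return an object of class `pls_model`: `n_latent`, `weights` (p x a,
#'   unit-norm), `x_loadings`, `y_loadings`, `scores`, `explained_y`
#'   (fraction of Y variance per LV), `coefficients` (regression matrix on
#'   the scaled X), `class_encoding`, `classes`, `levels`, scaling metadata
#'   (`x_center`, `x_scale`), and `Xs` (the scaled training matrix).
#' @export
fit_plsda <- function(X, classes, n_latent = 2L,
                      scaling = c("center", "autoscale", "none")) {
  scaling <- match.arg(scaling)
  x <- as_values(X)
  classes <- as.character(classes)
  lev <- unique(classes)
  if (length(lev) < 2L || length(lev) > 3L) {
    stop_metanova("PLS-DA needs 2 or 3 classes, got %d", length(lev),
                  class = "metanova_model_error")
  }
  if (any(table(classes) < 2L)) {
    stop_metanova("every class needs at least 2 samples",
                  class = "metanova_model_error")
  }
  assert_scalar_number(n_latent, "n_latent", min = 1, integer = TRUE)

  x_center <- colMeans(x)
  x_scale <- rep(1, ncol(x))
  if (scaling == "autoscale") {
    x_scale <- apply(x, 2L, stats::sd)
    if (any(x_scale == 0)) {
      stop_metanova("autoscale: zero-variance column(s): %s",
                    paste(colnames(x)[x_scale == 0], collapse = ", "),
                    class = "metanova_scaling_error")
    }
  }
  xs <- if (scaling == "none") x else
    sweep(sweep(x, 2L, x_center, `-`), 2L, x_scale, `/`)
  if (scaling == "none") { x_center <- rep(0, ncol(x)) }

  if (length(lev) == 2L) {
    y <- matrix(as.numeric(classes == lev[2L]), ncol = 1L,
                dimnames = list(NULL, lev[2L]))
  } else {
    y <- vapply(lev, function(l) as.numeric(classes == l),
                numeric(length(classes)))
  }
  y_center <- colMeans(y)
  ys <- sweep(y, 2L, y_center, `-`)
  tot_ssy <- ssq(ys)

  n <- nrow(xs); p <- ncol(xs); q <- ncol(ys)
  a_max <- min(n_latent, n - 1L, p)
  W <- matrix(0, p, a_max); P <- matrix(0, p, a_max)
  C <- matrix(0, q, a_max); Tm <- matrix(0, n, a_max)
  ssy <- numeric(a_max)
  Xd <- xs; Yd <- ys
  for (a in seq_len(a_max)) {
    u <- Yd[, which.max(colSums(Yd^2)), drop = TRUE]
    w <- crossprod(Xd, u)
    for (it in seq_len(500L)) {
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      cc <- crossprod(Yd, tt) / sum(tt^2)
      u_new <- Yd %*% cc / sum(cc^2)
      if (sum((u_new - u)^2) <= 1e-24 * sum(u^2)) { u <- u_new; break }
      u <- u_new
      w <- crossprod(Xd, u)
    }
    w <- w / sqrt(sum(w^2))
    tt <- Xd %*% w
    tt2 <- sum(tt^2)
    if (tt2 <= .Machine$double.eps * ssq(xs)) break
    pp <- crossprod(Xd, tt) / tt2
    cc <- crossprod(Yd, tt) / tt2
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
    ssy[a] <- tt2 * sum(cc^2)
  }
  got <- which(colSums(Tm^2) > 0)
  if (!length(got)) {
    stop_metanova("no predictive latent variable could be extracted",
                  class = "metanova_model_error")
  }
  keep <- seq_len(max(got))
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  C <- C[, keep, drop = FALSE]; Tm <- Tm[, keep, drop = FALSE]
  ssy <- ssy[keep]
  # regression matrix on the scaled X: B = W (P'W)^{-1} C'
  B <- W %*% solve(crossprod(P, W), t(C))
  rownames(W) <- rownames(P) <- rownames(B) <- colnames(xs)
  colnames(B) <- colnames(y)
  structure(list(n_latent = ncol(W), weights = W, x_loadings = P,
                 y_loadings = C, scores = Tm,
                 explained_y = ssy / tot_ssy,
                 coefficients = B,
                 class_encoding = stats::setNames(as.list(colnames(y)),
                                                  colnames(y)),
                 classes = classes, levels = lev,
                 y_center = y_center,
                 x_center = x_center, x_scale = x_scale, scaling = scaling,
                 Xs = xs),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d classes; Y variance explained: %s\n",
              x$n_latent, length(x$levels),
              paste(sprintf("%.1f%%", 100 * x$explained_y), collapse = ", ")))
  invisible(x)
}

#' Predict classes from a fitted PLS-DA model
#'
#' @param object a `pls_model`.
#' @param newdata matrix on the original (unscaled) variable scale; defaults
#'   to the training data.
#' @param ... unused.
#' @return character vector of predicted class labels (binary: indicator
#'   threshold 0.5; ternary: largest indicator column).
#' @export
predict.pls_model <- function(object, newdata = NULL, ...) {
  xs <- if (is.null(newdata)) object$Xs else
    sweep(sweep(as_values(newdata), 2L, object$x_center, `-`),
          2L, object$x_scale, `/`)
  yhat <- sweep(xs %*% object$coefficients, 2L, object$y_center, `+`)
  if (length(object$levels) == 2L) {
    unname(ifelse(yhat[, 1L] >= 0.5, object$levels[2L], object$levels[1L]))
  } else {
    object$levels[max.col(yhat[, object$levels, drop = FALSE])]
  }
}

#' Variable Influence on Projection (VIP) scores
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with unit-norm
#' weight columns, where `SSY_a` is the Y variance explained by latent
#' variable `a`.  By construction the average of the squared VIP scores is
#' exactly one, so VIP > 1 is the conventional relevance threshold.
#'
#' @param model a fitted `pls_model`.
#' @return named non-negative numeric vector, one score per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  w2 <- model$weights^2                          # columns already unit norm
  ssy <- model$explained_y
  p <- nrow(w2)
  vip <- sqrt(p * as.numeric(w2 %*% ssy) / sum(ssy))
  stats::setNames(vip, rownames(model$weights))
}

#' Selectivity ratio along the target-projection vector
#'
#' Projects the scaled data onto the normalized PLS regression vector (the
#' target projection), reconstructs the rank-1 approximation, and returns per
#' variable the ratio of explained to residual variance.  Columns orthogonal
#' to the regression vector get 0; numerically zero residual variance is
#' capped at `cap`.
#'
#' @param model a fitted `pls_model`.
#' @param X data matrix on the original variable scale (default: training
#'   data).
#' @param cap upper bound replacing infinite ratios.
#' @return named non-negative numeric vector.
#' @export
selectivity_ratio <- function(model, X = NULL, cap = 1e12) {
  stopifnot(inherits(model, "pls_model"))
  xs <- if (is.null(X)) model$Xs else
    sweep(sweep(as_values(X), 2L, model$x_center, `-`), 2L, model$x_scale, `/`)
  b <- model$coefficients
  if (ncol(b) > 1L) {
    # dominant discriminating direction for multi-class models
    b <- b %*% svd(b, nu = 0L, nv = 1L)$v
  }
  bn <- b / sqrt(sum(b^2))
  t_tp <- xs %*% bn
  p_tp <- crossprod(xs, t_tp) / sum(t_tp^2)
  xhat <- tcrossprod(t_tp, p_tp)
  expl <- colSums(xhat^2)
  resid <- colSums((xs - xhat)^2)
  sr <- ifelse(resid <= expl / cap, cap, expl / resid)
  sr[expl == 0] <- 0
  stats::setNames(pmin(sr, cap), colnames(xs))
}

#' Selection stability under random variable removal
#'
#' Refits the PLS-DA model many times (default 1000), each time removing a
#' uniform-random fraction of the variables (default between 1% and 10%),
#' and records how often each variable is selected (top-k VIP, VIP > 1, or
#' top-k selectivity ratio).  A removed variable cannot be selected in that
#' replicate.
#'
#' @param X numeric matrix or [feature_table()].
#' @param classes class labels.
#' @param n_models number of replicate models.
#' @param removal_range fraction range of variables removed per replicate.
#' @param selector `"vip_top_k"`, `"vip_gt1"` or `"sr_top_k"`.
#' @param k top-k size for the top-k selectors.
#' @param n_latent latent variables per replicate model.
#' @param scaling passed to [fit_plsda()].
#' @param seed integer seed.
#' @return named numeric vector of selection frequencies in \[0, 1\].
#' @export
stability_replicates <- function(X, classes, n_models = 1000,
                                 removal_range = c(0.01, 0.10),
                                 selector = c("vip_top_k", "vip_gt1",
                                              "sr_top_k"),
                                 k = 50L, n_latent = 2L,
                                 scaling = "autoscale", seed = 1L) {
  selector <- match.arg(selector)
  assert_scalar_number(n_models, "n_models", min = 1, integer = TRUE)
  if (length(removal_range) != 2L || any(removal_range < 0) ||
      any(removal_range >= 1) || removal_range[1L] > removal_range[2L]) {
    stop_metanova("removal_range must be two non-decreasing fractions in [0, 1)",
                  class = "metanova_config_error")
  }
  x <- as_values(X)
  p <- ncol(x)
  hits <- stats::setNames(numeric(p), colnames(x))
  withr::with_seed(seed, {
    for (i in seq_len(n_models)) {
      frac <- stats::runif(1L, removal_range[1L], removal_range[2L])
      drop_n <- max(if (removal_range[2L] > 0) 1L else 0L, round(frac * p))
      keep <- sort(sample.int(p, p - drop_n))
      m <- fit_plsda(x[, keep, drop = FALSE], classes, n_latent, scaling)
      score <- if (selector == "sr_top_k") selectivity_ratio(m) else vip_scores(m)
      sel <- if (selector == "vip_gt1") which(score > 1) else
        utils::head(order(-score, seq_along(score)), min(k, length(score)))
      hits[keep[sel]] <- hits[keep[sel]] + 1
    }
  })
  hits / n_models
}

#' Univariate significance tests per variable
#'
#' Two-sided equal-variance t-tests for two-level factors, one-way ANOVA
#' F-tests for three (or more) levels, computed column-wise.  Variables that
#' are constant within every group get p = 1 with a warning.
#'
#' @param X numeric matrix or [feature_table()].
#' @param design a [design_table()].
#' @param term factor name; every level needs >= 2 samples.
#' @return named vector of raw p-values in (0, 1\].
#' @export
univariate_tests <- function(X, design, term) {
  x <- as_values(X)
  lv <- design_levels(design, term, rownames(x) %||% design$sample_ids)
  lv_f <- factor(lv, levels = unique(lv))
  counts <- as.vector(table(lv_f))
  if (any(counts < 2L)) {
    stop_metanova("level '%s' has fewer than 2 samples",
                  levels(lv_f)[counts < 2L][1L], class = "metanova_design_error")
  }
  g <- as.integer(lv_f)
  k <- nlevels(lv_f)
  n <- nrow(x)
  m <- rowsum(x, g, reorder = TRUE) / counts
  within <- x - m[g, , drop = FALSE]
  ssw <- colSums(within^2)
  grand <- colMeans(x)
  ssb <- colSums(counts * sweep(m, 2L, grand, `-`)^2)
  degenerate <- ssw == 0 & ssb == 0
  if (any(degenerate)) {
    warning(sprintf("%d variable(s) constant within all groups: p set to 1",
                    sum(degenerate)))
  }
  if (k == 2L) {
    sp2 <- ssw / (n - 2L)
    se <- sqrt(sp2 * (1 / counts[1L] + 1 / counts[2L]))
    tstat <- (m[2L, ] - m[1L, ]) / se
    p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  } else {
    fstat <- (ssb / (k - 1L)) / (ssw / (n - k))
    p <- stats::pf(fstat, k - 1L, n - k, lower.tail = FALSE)
  }
  p[degenerate] <- 1
  p[ssw == 0 & ssb > 0] <- .Machine$double.xmin  # perfectly separated column
  stats::setNames(pmin(pmax(p, .Machine$double.xmin), 1), colnames(x))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false-discovery-rate correction:
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the input
#' order.  Monotone and idempotent.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length/names.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_metanova("p-values must lie in [0, 1]", class = "metanova_model_error")
  }
  m <- length(p)
  if (m == 0L) return(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- p
  out[o] <- pmin(q, 1)
  out
}
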