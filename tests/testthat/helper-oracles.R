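# Independent oracles: deliberately naive implementations, kept free of the
# package's code paths so the two routes cannot share a bug.

# Loop-based one/two-factor ANOVA decomposition.
oracle_decompose <- function(x, levels_list) {
  n <- nrow(x)
  grand <- colMeans(x)
  xc <- sweep(x, 2L, grand, `-`)
  effects <- list()
  for (f in names(levels_list)) {
    lv <- levels_list[[f]]
    e <- matrix(0, n, ncol(x))
    for (l in unique(lv)) {
      rows <- which(lv == l)
      e[rows, ] <- matrix(colMeans(xc[rows, , drop = FALSE]),
                          length(rows), ncol(x), byrow = TRUE)
    }
    effects[[f]] <- e
  }
  effects
}

# One-factor effect SSQ from first principles.
oracle_effect_ssq <- function(x, lv) {
  grand <- colMeans(x)
  total <- 0
  for (l in unique(lv)) {
    rows <- which(lv == l)
    m <- colMeans(x[rows, , drop = FALSE]) - grand
    total <- total + length(rows) * sum(m^2)
  }
  total
}

# Exhaustive two-group enumeration: exact permutation p with the strict
# exceedance convention (identity assignment contributes the +1).
oracle_exact_p <- function(x, lv, stat_fun = oracle_effect_ssq) {
  n <- length(lv)
  lev <- unique(lv)
  stopifnot(length(lev) == 2L)
  n1 <- sum(lv == lev[1L])
  obs <- stat_fun(x, lv)
  combos <- utils::combn(n, n1)
  stats <- apply(combos, 2L, function(idx) {
    lab <- rep(lev[2L], n)
    lab[idx] <- lev[1L]
    stat_fun(x, lab)
  })
  # identity appears exactly once among the combinations
  sum(stats > obs + 1e-10 * abs(obs)) + 1
}

# Direct dense Ledoit-Wolf intensity on within-group-centered rows.
oracle_lw_delta <- function(x, lv) {
  n <- nrow(x); p <- ncol(x)
  r <- x
  for (l in unique(lv)) {
    rows <- which(lv == l)
    r[rows, ] <- sweep(x[rows, , drop = FALSE], 2L,
                       colMeans(x[rows, , drop = FALSE]), `-`)
  }
  S <- crossprod(r) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - m * diag(p))^2) / p
  b2 <- 0
  for (i in seq_len(n)) {
    b2 <- b2 + sum((tcrossprod(r[i, ]) - S)^2)
  }
  b2 <- b2 / (n^2 * p)
  min(min(b2, d2) / d2, 1)
}

# Dense Lawley-Hotelling trace: trace(S^{-1} H), S unbiased within scatter.
oracle_lh_trace <- function(x, lv) {
  xc <- sweep(x, 2L, colMeans(x), `-`)
  k <- length(unique(lv))
  e <- xc
  for (l in unique(lv)) {
    rows <- which(lv == l)
    e[rows, ] <- matrix(colMeans(xc[rows, , drop = FALSE]),
                        length(rows), ncol(x), byrow = TRUE)
  }
  r <- xc - e
  S <- crossprod(r) / (nrow(x) - k)
  sum(diag(solve(S, crossprod(e))))
}

# Brute-force Benjamini-Hochberg: for each p_i, q_i = min over j with
# p_j >= p_i of p_j * m / rank(p_j), using maximal ranks for ties.
oracle_bh <- function(p) {
  m <- length(p)
  ranks <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    min(1, min(p[p >= p[i]] * m / ranks[p >= p[i]]))
  }, numeric(1))
}

# Textbook Pearson correlation.
oracle_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Small balanced two-group gaussian matrix with a planted mean shift.
toy_two_group <- function(n_per = 3, p = 4, shift = 0, markers = integer(0),
                          seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
    if (length(markers)) {
      x[seq_len(n_per) + n_per, markers] <-
        x[seq_len(n_per) + n_per, markers] + shift
    }
    rownames(x) <- sprintf("S%02d", seq_len(2 * n_per))
    colnames(x) <- paste0("V", seq_len(p))
    x
  })
}

toy_design <- function(n_per = 3, levels = c("A", "B"),
                       ids = sprintf("S%02d", seq_len(n_per * length(levels)))) {
  design_table(ids, data.frame(group = rep(levels, each = n_per)))
}
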