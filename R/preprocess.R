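#' Total ion current chromatogram from a centroided scan table
#'
#' Sums all centroid intensities within each scan.  The result has one value
#' per scan index from 1 to the largest scan index present; scans with no
#' records contribute 0.
#'
#' @param scans data.frame with columns `scan` (positive integer index),
#'   `rt`, `mz`, `intensity`.
#' @return numeric vector of per-scan summed intensity (length 0 for an
#'   empty table).
#' @export
extract_tic <- function(scans) {
  stopifnot(all(c("scan", "intensity") %in% names(scans)))
  if (nrow(scans) == 0L) return(numeric(0))
  n <- max(scans$scan)
  tic <- numeric(n)
  agg <- rowsum(scans$intensity, group = scans$scan)
  tic[as.integer(rownames(agg))] <- agg[, 1L]
  tic
}

#' Region-of-interest extraction parameters
#'
#' @param mz_tolerance maximum m/z deviation (Da) for a centroid to extend an
#'   open trace.
#' @param min_intensity centroids below this intensity are discarded.
#' @param min_consecutive_scans minimum trace length (scans) for a trace to
#'   become a feature.
#' @return an object of class `roi_params`.
#' @export
roi_params <- function(mz_tolerance = 0.01, min_intensity = 0,
                       min_consecutive_scans = 3L) {
  assert_scalar_number(mz_tolerance, "mz_tolerance", min = 1e-12)
  assert_scalar_number(min_intensity, "min_intensity", min = 0)
  assert_scalar_number(min_consecutive_scans, "min_consecutive_scans",
                       min = 1, integer = TRUE)
  structure(list(mz_tolerance = mz_tolerance,
                 min_intensity = min_intensity,
                 min_consecutive_scans = as.integer(min_consecutive_scans)),
            class = "roi_params")
}

#' Simplified region-of-interest feature extraction
#'
#' A deliberately simplified stand-in for the full MSROI algorithm: greedy
#' trace building over centroided scans.  Centroids below `min_intensity` are
#' dropped; a centroid extends an open trace when its m/z is within
#' `mz_tolerance` of the trace's running mean m/z and the trace was last
#' extended in the current or previous scan; otherwise it opens a new trace.
#' Traces spanning at least `min_consecutive_scans` scans become features
#' whose value is the summed trace intensity (area) and whose variable ID is
#' the mean m/z rounded to 4 decimals (collisions suffixed `_2`, `_3`, ...).
#'
#' @param scans data.frame with columns `scan`, `rt`, `mz`, `intensity`
#'   (one sample's centroided data).
#' @param params a [roi_params()].
#' @param sample_id row label of the resulting single-sample table.
#' @return a single-sample [feature_table()] (possibly with 0 variables).
#' @export
roi_features <- function(scans, params = roi_params(), sample_id = "S1") {
  stopifnot(inherits(params, "roi_params"),
            all(c("scan", "mz", "intensity") %in% names(scans)))
  scans <- scans[scans$intensity >= params$min_intensity, , drop = FALSE]
  scans <- scans[order(scans$scan, scans$mz), , drop = FALSE]

  # open traces: running mean m/z, accumulated area, span, last scan touched
  open_mz <- numeric(0); open_n <- integer(0); open_area <- numeric(0)
  open_first <- integer(0); open_last <- integer(0)
  done_mz <- numeric(0); done_area <- numeric(0); done_span <- integer(0)

  close_stale <- function(current_scan) {
    stale <- open_last < current_scan - 1L
    if (any(stale)) {
      done_mz <<- c(done_mz, open_mz[stale])
      done_area <<- c(done_area, open_area[stale])
      done_span <<- c(done_span, open_last[stale] - open_first[stale] + 1L)
      keep <- !stale
      open_mz <<- open_mz[keep]; open_n <<- open_n[keep]
      open_area <<- open_area[keep]
      open_first <<- open_first[keep]; open_last <<- open_last[keep]
    }
  }

  for (s in unique(scans$scan)) {
    close_stale(s)
    rows <- which(scans$scan == s)
    for (r in rows) {
      mz <- scans$mz[r]; it <- scans$intensity[r]
      if (length(open_mz)) {
        d <- abs(open_mz - mz)
        j <- which.min(d)
        if (d[j] <= params$mz_tolerance) {
          open_mz[j] <- (open_mz[j] * open_n[j] + mz) / (open_n[j] + 1L)
          open_n[j] <- open_n[j] + 1L
          open_area[j] <- open_area[j] + it
          open_last[j] <- s
          next
        }
      }
      open_mz <- c(open_mz, mz); open_n <- c(open_n, 1L)
      open_area <- c(open_area, it)
      open_first <- c(open_first, s); open_last <- c(open_last, s)
    }
  }
  done_mz <- c(done_mz, open_mz)
  done_area <- c(done_area, open_area)
  done_span <- c(done_span, open_last - open_first + 1L)

  keep <- done_span >= params$min_consecutive_scans
  mzs <- done_mz[keep]; areas <- done_area[keep]
  if (!length(mzs)) {
    empty <- matrix(numeric(0), nrow = 1L, ncol = 0L,
                    dimnames = list(sample_id, NULL))
    return(feature_table(empty, variable_kind = "feature",
                         is_internal_standard = logical(0)))
  }
  ord <- order(mzs)
  mzs <- mzs[ord]; areas <- areas[ord]
  ids <- sprintf("%.4f", mzs)
  if (anyDuplicated(ids)) {
    for (id in unique(ids[duplicated(ids)])) {
      at <- which(ids == id)
      ids[at[-1L]] <- paste0(id, "_", seq_along(at[-1L]) + 1L)
    }
  }
  feature_table(matrix(areas, nrow = 1L, dimnames = list(sample_id, ids)),
                variable_kind = "feature")
}

#' Internal-standard and sample-amount normalization
#'
#' Corrects multiplicative between-injection intensity drift: each sample's
#' row is divided by the mean of that sample's internal-standard values times
#' the sample's amount (A600 / embryo-count analogue) taken from the design.
#' Internal-standard columns are retained and stay flagged.
#'
#' @param table a [feature_table()] with at least one internal-standard
#'   variable.
#' @param design a [design_table()] covering the table's samples (provides
#'   `sample_amount`; all 1 when the design was read without an amount
#'   column).
#' @return the normalized [feature_table()].
#' @export
normalize_features <- function(table, design) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "design_table"))
  if (!any(table$is_internal_standard)) {
    stop_metanova("normalize_features requires at least one internal-standard variable",
                  class = "metanova_normalization_error")
  }
  missing <- setdiff(table$sample_ids, design$sample_ids)
  if (length(missing)) {
    stop_metanova("samples absent from design: %s",
                  paste(missing, collapse = ", "),
                  class = "metanova_alignment_error")
  }
  is_cols <- table$is_internal_standard
  is_mean <- rowMeans(table$values[, is_cols, drop = FALSE])
  if (any(is_mean == 0)) {
    bad <- table$sample_ids[is_mean == 0][1L]
    stop_metanova("degenerate sample '%s': internal-standard mean is zero", bad,
                  class = "metanova_normalization_error")
  }
  amount <- design$sample_amount[table$sample_ids]
  table$values <- table$values / (is_mean * amount)
  table
}

#' Column mean-centering and autoscaling
#'
#' `mean_center` subtracts column means; `autoscale` additionally divides by
#' column standard deviations (n-1 divisor), the conventional chemometrics
#' scaling for feature matrices.  TIC matrices are analyzed mean-centered,
#' feature matrices autoscaled.
#'
#' @param x numeric matrix with at least 2 rows (a [feature_table()] is
#'   accepted and its value matrix used).
#' @return the scaled matrix.
#' @export
mean_center <- function(x) {
  x <- as_values(x)
  if (nrow(x) < 2L) {
    stop_metanova("scaling requires at least 2 rows", class = "metanova_scaling_error")
  }
  sweep(x, 2L, colMeans(x), `-`)
}

#' @rdname mean_center
#' @export
autoscale <- function(x) {
  x <- as_values(x)
  if (nrow(x) < 2L) {
    stop_metanova("scaling requires at least 2 rows", class = "metanova_scaling_error")
  }
  s <- apply(x, 2L, stats::sd)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0] %||% which(s == 0)
    stop_metanova("autoscale: zero-variance column(s): %s (drop them first)",
                  paste(bad, collapse = ", "),
                  class = "metanova_scaling_error")
  }
  sweep(sweep(x, 2L, colMeans(x), `-`), 2L, s, `/`)
}

as_values <- function(x) {
  if (inherits(x, "feature_table")) x$values else as.matrix(x)
}

apply_scaling <- function(x, scaling = c("center", "autoscale", "none")) {
  scaling <- match.arg(scaling)
  switch(scaling,
         center = mean_center(x),
         autoscale = autoscale(x),
         none = as_values(x))
}
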