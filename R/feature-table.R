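#' Feature table: samples x variables intensity matrix
#'
#' The central data container: a non-negative numeric matrix of samples
#' (rows) by variables (columns), where variables are either m/z-defined
#' LC-MS features (peak areas) or retention-time channels of a total ion
#' current chromatogram.  Variables can be flagged as internal standards,
#' which drives drift normalization (see [normalize_features()]).
#'
#' @param values numeric matrix (samples x variables), all finite and
#'   non-negative.
#' @param sample_ids unique character labels, one per row.  Defaults to the
#'   rownames of `values`.
#' @param variable_ids unique character labels, one per column.  Defaults to
#'   the colnames of `values`.
#' @param variable_kind `"feature"` or `"tic_channel"`.
#' @param is_internal_standard logical vector, one flag per variable.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values,
                          sample_ids = rownames(values),
                          variable_ids = colnames(values),
                          variable_kind = c("feature", "tic_channel"),
                          is_internal_standard = rep(FALSE, ncol(values))) {
  variable_kind <- match.arg(variable_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%d", seq_len(nrow(values)))
  }
  if (is.null(variable_ids)) {
    variable_ids <- sprintf("V%d", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  variable_ids <- as.character(variable_ids)
  if (length(sample_ids) != nrow(values)) {
    stop_metanova("sample_ids length (%d) does not match rows (%d)",
                  length(sample_ids), nrow(values),
                  class = "metanova_format_error")
  }
  if (length(variable_ids) != ncol(values)) {
    stop_metanova("variable_ids length (%d) does not match columns (%d)",
                  length(variable_ids), ncol(values),
                  class = "metanova_format_error")
  }
  if (anyDuplicated(sample_ids)) {
    stop_metanova("duplicated sample_id: %s",
                  paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
                  class = "metanova_format_error")
  }
  if (anyDuplicated(variable_ids)) {
    stop_metanova("duplicated variable column: %s",
                  paste(unique(variable_ids[duplicated(variable_ids)]), collapse = ", "),
                  class = "metanova_format_error")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop_metanova("non-finite value at row %d ('%s'), column %d ('%s')",
                  bad[1L], sample_ids[bad[1L]], bad[2L], variable_ids[bad[2L]],
                  class = "metanova_format_error")
  }
  is_internal_standard <- as.logical(is_internal_standard)
  if (length(is_internal_standard) != ncol(values)) {
    stop_metanova("is_internal_standard must have one flag per variable",
                  class = "metanova_format_error")
  }
  dimnames(values) <- list(sample_ids, variable_ids)
  structure(list(values = values,
                 sample_ids = sample_ids,
                 variable_ids = variable_ids,
                 variable_kind = variable_kind,
                 is_internal_standard = is_internal_standard),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d variables (%s), %d internal standard(s)\n",
              nrow(x$values), ncol(x$values), x$variable_kind,
              sum(x$is_internal_standard)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Design table: per-sample factor levels
#'
#' Maps each sample to its level on each experimental factor, plus a
#' per-sample amount (e.g. A600 optical density or embryo count) used in
#' normalization.
#'
#' @param sample_ids unique character labels.
#' @param factors data.frame (or named list) with one column per factor and
#'   one row per sample; coerced to character levels.
#' @param sample_amount positive numeric per sample (default all 1).
#' @return an object of class `design_table`.
#' @export
design_table <- function(sample_ids, factors,
                         sample_amount = rep(1, length(sample_ids))) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop_metanova("duplicated sample_id in design",
                  class = "metanova_format_error")
  }
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != length(sample_ids)) {
    stop_metanova("design factors have %d rows for %d samples",
                  nrow(factors), length(sample_ids),
                  class = "metanova_format_error")
  }
  factors[] <- lapply(factors, as.character)
  if (any(is.na(factors) | factors == "")) {
    stop_metanova("missing factor level in design",
                  class = "metanova_format_error")
  }
  sample_amount <- as.numeric(sample_amount)
  if (length(sample_amount) != length(sample_ids) ||
      any(!is.finite(sample_amount)) || any(sample_amount <= 0)) {
    stop_metanova("sample_amount must be positive and finite for every sample",
                  class = "metanova_format_error")
  }
  rownames(factors) <- sample_ids
  names(sample_amount) <- sample_ids
  structure(list(sample_ids = sample_ids,
                 factors = factors,
                 sample_amount = sample_amount),
            class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  lv <- vapply(x$factors, function(f) length(unique(f)), integer(1))
  cat(sprintf("<design_table> %d samples; factors: %s\n",
              length(x$sample_ids),
              paste(sprintf("%s (%d levels)", names(lv), lv), collapse = ", ")))
  invisible(x)
}

# Level vector of one factor, checked and aligned to a sample order.
design_levels <- function(design, factor_name, sample_ids = design$sample_ids) {
  if (!factor_name %in% names(design$factors)) {
    stop_metanova("factor '%s' not present in design (have: %s)",
                  factor_name, paste(names(design$factors), collapse = ", "),
                  class = "metanova_design_error")
  }
  missing <- setdiff(sample_ids, design$sample_ids)
  if (length(missing)) {
    stop_metanova("samples present in features but absent from design: %s",
                  paste(missing, collapse = ", "),
                  class = "metanova_alignment_error")
  }
  lv <- design$factors[sample_ids, factor_name]
  if (length(unique(lv)) < 2L) {
    stop_metanova("factor '%s' has fewer than 2 levels among the analyzed samples",
                  factor_name, class = "metanova_design_error")
  }
  lv
}

#' Read / write a feature table CSV
#'
#' Format: comma-separated UTF-8, `.` decimal.  First header column is
#' `sample_id`, remaining header cells are variable IDs.  An optional second
#' header row whose first cell is `is_internal_standard` carries 0/1 flags
#' per variable.  Each following row is one sample.
#'
#' @param path file path.
#' @param variable_kind passed to [feature_table()].
#' @return `read_feature_table`: a [feature_table()]. `write_feature_table`:
#'   the path, invisibly.
#' @export
read_feature_table <- function(path, variable_kind = c("feature", "tic_channel")) {
  variable_kind <- match.arg(variable_kind)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) {
    stop_metanova("feature table CSV '%s' has no data rows", path,
                  class = "metanova_format_error")
  }
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "sample_id") {
    stop_metanova("first header column must be 'sample_id', got '%s'",
                  header[1L], class = "metanova_format_error")
  }
  var_ids <- header[-1L]
  is_flags <- rep(FALSE, length(var_ids))
  body_start <- 2L
  second <- strsplit(lines[[2L]], ",", fixed = TRUE)[[1L]]
  if (identical(second[1L], "is_internal_standard")) {
    if (length(second) != length(header)) {
      stop_metanova("internal-standard flag row has %d cells, expected %d",
                    length(second), length(header),
                    class = "metanova_format_error")
    }
    is_flags <- as.numeric(second[-1L]) != 0
    body_start <- 3L
  }
  rows <- strsplit(lines[seq(body_start, length(lines))], ",", fixed = TRUE)
  n_col <- length(header)
  values <- matrix(NA_real_, nrow = length(rows), ncol = length(var_ids))
  sample_ids <- character(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != n_col) {
      stop_metanova("ragged row %d in '%s': %d cells, expected %d",
                    body_start + i - 1L, path, length(r), n_col,
                    class = "metanova_format_error")
    }
    sample_ids[i] <- r[1L]
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop_metanova("non-numeric cell at row %d, column '%s' in '%s'",
                    body_start + i - 1L, var_ids[j], path,
                    class = "metanova_format_error")
    }
    values[i, ] <- v
  }
  feature_table(values, sample_ids, var_ids,
                variable_kind = variable_kind,
                is_internal_standard = is_flags)
}

#' @param table a [feature_table()].
#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("sample_id", table$variable_ids), collapse = ","), con)
  if (any(table$is_internal_standard)) {
    writeLines(paste(c("is_internal_standard",
                       as.integer(table$is_internal_standard)), collapse = ","),
               con)
  }
  for (i in seq_along(table$sample_ids)) {
    writeLines(paste(c(table$sample_ids[i],
                       format(table$values[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)), collapse = ","), con)
  }
  invisible(path)
}

#' Read a design table CSV
#'
#' Format: header `sample_id`, one column per factor, optional final column
#' `sample_amount` (defaults to 1 when absent).
#'
#' @param path file path.
#' @return a [design_table()].
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!"sample_id" %in% names(df)) {
    stop_metanova("design CSV '%s' must have a 'sample_id' column", path,
                  class = "metanova_format_error")
  }
  sample_ids <- df$sample_id
  amount <- if ("sample_amount" %in% names(df)) {
    a <- suppressWarnings(as.numeric(df$sample_amount))
    if (anyNA(a)) {
      stop_metanova("non-numeric sample_amount in '%s'", path,
                    class = "metanova_format_error")
    }
    a
  } else {
    rep(1, length(sample_ids))
  }
  fac <- df[, setdiff(names(df), c("sample_id", "sample_amount")), drop = FALSE]
  if (ncol(fac) == 0L) {
    stop_metanova("design CSV '%s' has no factor columns", path,
                  class = "metanova_format_error")
  }
  design_table(sample_ids, fac, amount)
}

#' Write a design table CSV
#'
#' @param design a [design_table()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_table"))
  df <- cbind(data.frame(sample_id = design$sample_ids,
                         stringsAsFactors = FALSE),
              design$factors,
              data.frame(sample_amount = unname(design$sample_amount)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
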