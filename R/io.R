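#' Read a samples-by-features table from CSV or XLSX
#'
#' Parses a rectangular numeric table with one header row of feature names and
#' a first column of sample identifiers. Cells may be empty (missing); any
#' other non-numeric content is an error naming the offending cell. Numeric
#' parsing is locale-independent (dot decimal separator).
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param format `"auto"` (from the file extension), `"csv"` or `"xlsx"`.
#'   XLSX reads the first sheet.
#' @param transpose If `TRUE` the table on disk is features-by-samples and is
#'   transposed after reading.
#' @return A `raw_table`: a list with `sample_ids`, `feature_names` and a
#'   numeric `values` matrix (possibly containing `NA` for empty cells).
#' @seealso [validate_features()], [zscore()]
#' @export
read_feature_table <- function(path, format = c("auto", "csv", "xlsx"),
                               transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", xlsx = "xlsx",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format = 'csv' or 'xlsx'", call. = FALSE))
  }
  df <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, locale = readr::locale(decimal_mark = "."),
                    name_repair = "minimal")
  } else {
    readxl::read_xlsx(path, sheet = 1,
                      col_types = "text", .name_repair = "minimal")
  }
  if (ncol(df) < 2) {
    stop("table must have an ID column plus at least one data column",
         call. = FALSE)
  }
  ids <- as.character(df[[1]])
  cells <- as.data.frame(df[-1], check.names = FALSE)
  values <- parse_numeric_cells(cells, ids)
  rt <- new_raw_table(sample_ids = ids,
                      feature_names = colnames(cells),
                      values = values)
  if (transpose) rt <- transpose_raw(rt)
  check_raw_invariants(rt)
  rt
}

new_raw_table <- function(sample_ids, feature_names, values) {
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(sample_ids = as.character(sample_ids),
                 feature_names = as.character(feature_names),
                 values = values),
            class = "raw_table")
}

transpose_raw <- function(rt) {
  new_raw_table(sample_ids = rt$feature_names,
                feature_names = rt$sample_ids,
                values = t(rt$values))
}

# Empty strings become NA (a missing cell, reported later by
# validate_features); any other unparseable token is an immediate error.
parse_numeric_cells <- function(cells, ids) {
  m <- matrix(NA_real_, nrow = nrow(cells), ncol = ncol(cells))
  for (j in seq_along(cells)) {
    raw <- trimws(as.character(cells[[j]]))
    empty <- is.na(raw) | raw == "" | raw == "NA"
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- !empty & is.na(parsed)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-numeric cell '", raw[i], "' at sample '", ids[i],
           "', feature '", colnames(cells)[j], "'", call. = FALSE)
    }
    parsed[empty] <- NA_real_
    m[, j] <- parsed
  }
  m
}

check_raw_invariants <- function(rt) {
  n <- nrow(rt$values); m <- ncol(rt$values)
  if (n < 3) stop("need at least 3 samples (rows), got ", n, call. = FALSE)
  if (m < 2) stop("need at least 2 features (columns), got ", m, call. = FALSE)
  fn <- rt$feature_names
  if (any(!nzchar(fn))) stop("empty feature name in header", call. = FALSE)
  dup <- unique(fn[duplicated(fn)])
  if (length(dup)) {
    stop("duplicated feature name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(duplicated(rt$sample_ids))) {
    stop("duplicated sample ID(s): ",
         paste(unique(rt$sample_ids[duplicated(rt$sample_ids)]),
               collapse = ", "), call. = FALSE)
  }
  invisible(rt)
}

#' Validate a raw table into a feature matrix
#'
#' Rejects tables with missing values, listing every offending
#' (sample, feature) coordinate, and flags constant (zero-variance) columns.
#' Constant features are retained in the matrix but excluded from all
#' correlation computations downstream.
#'
#' @param raw A `raw_table` from [read_feature_table()] or
#'   [simulate_scenario()].
#' @return A `feature_matrix`: list with `values` (fully observed numeric
#'   matrix), `sample_ids`, `feature_names`, `constant_features` (character
#'   vector) and a `normalized` flag.
#' @export
validate_features <- function(raw) {
  stopifnot(inherits(raw, "raw_table"))
  check_raw_invariants(raw)
  v <- raw$values
  if (anyNA(v)) {
    idx <- which(is.na(v), arr.ind = TRUE)
    coords <- paste0("(", raw$sample_ids[idx[, 1]], ", ",
                     raw$feature_names[idx[, 2]], ")")
    stop("missing values must be imputed before analysis; missing cell(s) at: ",
         paste(coords, collapse = ", "), call. = FALSE)
  }
  const <- raw$feature_names[apply(v, 2, function(col) stats::var(col) == 0)]
  structure(list(values = v,
                 sample_ids = raw$sample_ids,
                 feature_names = raw$feature_names,
                 constant_features = const,
                 normalized = FALSE),
            class = "feature_matrix")
}

#' Z-score normalize a feature matrix
#'
#' Each non-constant column is transformed to `(x - mean) / sd` with the
#' sample standard deviation (n - 1 denominator). Constant columns are left
#' untouched (they stay flagged and excluded downstream). The transform is
#' idempotent: applying it twice changes nothing beyond 1e-12.
#'
#' @param fm A `feature_matrix` from [validate_features()].
#' @return The normalized `feature_matrix` (`normalized = TRUE`).
#' @export
zscore <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  keep <- !(fm$feature_names %in% fm$constant_features)
  for (j in which(keep)) {
    v[, j] <- (v[, j] - mean(v[, j])) / stats::sd(v[, j])
  }
  fm$values <- v
  fm$normalized <- TRUE
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " features", if (x$normalized) " (z-scored)", "\n", sep = "")
  if (length(x$constant_features)) {
    cat("constant features (excluded from correlations): ",
        paste(x$constant_features, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

n_samples <- function(fm) nrow(fm$values)

usable_features <- function(fm) {
  setdiff(fm$feature_names, fm$constant_features)
}

#' Write an edge table to CSV
#'
#' Serializes a filtered edge table (see [filter_edges()]) at full double
#' precision, one row per retained feature pair, columns in the fixed order
#' produced by the analysis mode.
#'
#' @param edges A tibble of edges.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_edges <- function(edges, path) {
  stopifnot(is.data.frame(edges))
  readr::write_csv(edges, path, progress = FALSE)
  invisible(path)
}
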