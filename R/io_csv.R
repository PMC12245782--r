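# CSV ingestion for windowed signals / feature tables. One row per window,
# a `label` column in {1..5}, all remaining columns numeric. NaN/Inf cells are
# a parse error (rejected at ingestion, never imputed).

#' Read a labeled signal/feature table from CSV
#'
#' @param path CSV file with a header row, a `label` column with values in
#'   1..5, and numeric sample (or feature) columns.
#' @return A list with `values` (numeric matrix, one row per window),
#'   `labels` (integer vector), and `column_names`.
#' @export
read_csv_dataset <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("CSV file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) {
    abort_format(sprintf("%s: missing required 'label' column", path))
  }
  value_cols <- setdiff(names(df), "label")
  if (nrow(df) == 0L) {
    return(list(values = matrix(numeric(), 0L, length(value_cols),
                                dimnames = list(NULL, value_cols)),
                labels = integer(), column_names = value_cols))
  }
  for (cn in c(value_cols, "label")) {
    col <- df[[cn]]
    if (is.character(col)) col <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(col))
    if (length(bad)) {
      abort_format(sprintf("%s: non-numeric or NaN cell at row %d, column '%s'",
                           path, bad[1], cn))
    }
    df[[cn]] <- col
  }
  labels <- as.integer(df$label)
  if (any(labels != df$label) || any(labels < 1L) || any(labels > 5L)) {
    abort_format(sprintf("%s: label column must contain integers in 1..5", path))
  }
  list(values = as.matrix(df[value_cols]), labels = labels,
       column_names = value_cols)
}

#' Write a table of rows to CSV
#'
#' Thin RFC-4180 writer used for segments, feature matrices and convergence
#' curves; header preserved so [read_csv_dataset()] round-trips.
#'
#' @param rows A data frame or matrix (with column names).
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  df <- as.data.frame(rows, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
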