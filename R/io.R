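#' Read and write case tables
#'
#' Case tables are plain comma-separated text with a header row: one row
#' per case with `case_id`, `truth_class` (malignant / benign / normal,
#' matched case-insensitively), the continuous `score_dm` and `score_abus`
#' columns, and any number of ordinal reader columns (names starting with
#' `reader`) holding BI-RADS category labels. Writing then reading a table
#' reproduces it exactly, including column order and category labels.
#'
#' @param path File path.
#' @param cases Case table to write.
#' @return `read_case_table()` returns a validated tibble;
#'   `write_case_table()` returns `cases` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' cohort <- generate_cohort(cohort_config(3, 3, 4, seed = 1))
#' write_case_table(cohort, f)
#' read_case_table(f)
read_case_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c("case_id", "truth_class", "score_dm", "score_abus")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Case table is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dup <- raw$case_id[duplicated(raw$case_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicated case_id value(s): %s", paste(unique(dup), collapse = ", ")))
  }
  bad_rows <- which(is.na(suppressWarnings(as.numeric(raw$score_dm))) |
                      is.na(suppressWarnings(as.numeric(raw$score_abus))))
  if (length(bad_rows) > 0) {
    abort(sprintf("Non-numeric score(s) in row(s): %s",
                  paste(utils::head(bad_rows, 10), collapse = ", ")))
  }
  out <- raw
  out$truth_class <- as_truth(raw$truth_class)
  out$score_dm <- as.numeric(raw$score_dm)
  out$score_abus <- as.numeric(raw$score_abus)
  for (col in reader_columns(out)) out[[col]] <- as_birads(raw[[col]])
  out
}

#' @rdname read_case_table
#' @export
write_case_table <- function(cases, path) {
  out <- cases
  out$truth_class <- as.character(out$truth_class)
  for (col in reader_columns(out)) out[[col]] <- as.character(out[[col]])
  readr::write_csv(out, path, progress = FALSE)
  invisible(cases)
}
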