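metrics_cols <- c("patient_id", "reader_id", "filter_label",
                  "mtv_cm3", "tlg", "dmax_cm", "n_lesions")

#' Read and write per-patient biomarker tables
#'
#' The on-disk exchange format for patient metrics is a UTF-8 CSV with a
#' header row and one row per patient x reader x filter variant, columns
#' `patient_id, reader_id, filter_label, mtv_cm3, tlg, dmax_cm, n_lesions`.
#' Numeric values round-trip to at least 6 significant digits.
#'
#' @param records A data frame of patient metrics, as produced by
#'   [compute_patient_metrics()] or [simulate_metrics()].
#' @param path CSV file path.
#' @return `read_metrics_table()` returns a tibble with the columns above;
#'   `write_metrics_table()` returns `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' rec <- tibble::tibble(patient_id = "p1", reader_id = "A",
#'                       filter_label = "all", mtv_cm3 = 1.5, tlg = 6,
#'                       dmax_cm = 0, n_lesions = 1L)
#' write_metrics_table(rec, tmp)
#' read_metrics_table(tmp)
#' @export
write_metrics_table <- function(records, path) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("no records: refusing to write an empty metrics table.")
  missing <- setdiff(metrics_cols, names(records))
  if (length(missing)) {
    abort(paste0("metrics table is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  readr::write_csv(records[metrics_cols], path)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  check_readable(path)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(metrics_cols, names(tbl))
  if (length(missing)) {
    abort(paste0("malformed metrics table '", path, "': missing column(s) ",
                 paste(missing, collapse = ", "), "."))
  }
  if (nrow(tbl) == 0L) abort(sprintf("no records in metrics table '%s'.", path))
  tbl$patient_id <- as.character(tbl$patient_id)
  tbl$reader_id <- as.character(tbl$reader_id)
  tbl$filter_label <- as.character(tbl$filter_label)
  tbl$n_lesions <- as.integer(tbl$n_lesions)
  tbl[metrics_cols]
}
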