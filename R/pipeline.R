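# File-to-file pipeline stages: simulate -> metrics -> agreement. These
# wrap the in-memory functions for shell-driven use (see inst/cli); all
# results go to files, progress goes to messages (stderr).

as_phantom_config <- function(config) {
  if (inherits(config, "phantom_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    check_readable(config)
    lst <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        abort("reading YAML configs requires the 'yaml' package.")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    config <- lst
  }
  if (!is.list(config)) abort("`config` must be a phantom_config, a list or a file path.")
  unknown <- setdiff(names(config), names(formals(phantom_config)))
  if (length(unknown)) {
    abort(paste0("unknown phantom config field(s): ",
                 paste(unknown, collapse = ", "), "."))
  }
  do.call(phantom_config, config)
}

#' Pipeline stage: simulate a phantom cohort to disk
#'
#' @param config A [phantom_config()], a list of its fields, or the path
#'   to a YAML/JSON file with those fields.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @seealso [generate_cohort()]
#' @export
run_simulate <- function(config, dir) {
  res <- generate_cohort(as_phantom_config(config), dir)
  message("wrote cohort manifest: ", res$manifest)
  invisible(res$manifest)
}

#' Pipeline stage: biomarkers for every patient of a cohort
#'
#' Reads each patient's SUV volume and the two reader masks named in the
#' cohort manifest, verifies grid compatibility, and writes one metrics row
#' per patient x reader x filter variant. Relative paths in the manifest
#' are resolved against the manifest's directory. On any failure no output
#' file is left behind.
#'
#' @param manifest Path to a `cohort.csv` (columns `patient_id, suv_path,
#'   mask_a_path, mask_b_path`) or an equivalent data frame.
#' @param out_csv Output CSV path for the metrics table.
#' @param connectivity Lesion connectivity (6, 18 or 26).
#' @param min_volume_cm3 Small-lesion exclusion threshold for the filtered
#'   variant.
#' @param variants Which filter variants to emit: any subset of
#'   `c("all", "filtered")`.
#' @return The metrics tibble, invisibly.
#' @export
run_metrics <- function(manifest, out_csv, connectivity = 26,
                        min_volume_cm3 = 3,
                        variants = c("all", "filtered")) {
  variants <- match.arg(variants, several.ok = TRUE)
  base <- "."
  if (is.character(manifest)) {
    check_readable(manifest)
    base <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE,
                                progress = FALSE)
  }
  manifest <- as_tibble(manifest)
  need <- setdiff(c("patient_id", "suv_path", "mask_a_path", "mask_b_path"),
                  names(manifest))
  if (length(need)) {
    abort(paste0("cohort manifest is missing column(s): ",
                 paste(need, collapse = ", "), "."))
  }
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))

  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    pid <- manifest$patient_id[i]
    suv <- read_suv_volume(resolve(manifest$suv_path[i]), patient_id = pid)
    masks <- list(
      read_mask(resolve(manifest$mask_a_path[i]), reader_id = "A",
                patient_id = pid),
      read_mask(resolve(manifest$mask_b_path[i]), reader_id = "B",
                patient_id = pid))
    purrr::map(masks, function(m) {
      stop_unless_compatible(suv, m)
      dplyr::bind_rows(
        if ("all" %in% variants)
          compute_patient_metrics(suv, m, connectivity),
        if ("filtered" %in% variants)
          compute_patient_metrics(suv, m, connectivity,
                                  min_volume_cm3 = min_volume_cm3))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  write_metrics_table(rows, out_csv)
  message("wrote ", nrow(rows), " metric rows to ", out_csv)
  invisible(rows)
}

report_json <- function(reports) {
  purrr::map(reports, function(rep) {
    list(filter_label = rep$filter_label, n = rep$n, readers = rep$readers,
         metrics = purrr::map(rep$metrics, function(m) {
           m$contingency <- as.vector(m$contingency) # column-major 2x2
           m
         }))
  })
}

#' Pipeline stage: agreement reports from a metrics table
#'
#' Runs [agreement_study()] for every requested filter variant present in
#' the metrics table and writes a JSON report (full precision) plus a flat
#' CSV (one row per metric x variant).
#'
#' @param metrics Path to a metrics CSV (see [read_metrics_table()]) or an
#'   equivalent data frame.
#' @param out_dir Output directory for `agreement.json` and
#'   `agreement.csv`.
#' @param filters Filter labels to analyse; default all labels in the data.
#' @param pooled_median Passed to [agreement_study()].
#' @return Invisibly, a named list of `agreement_report` objects.
#' @export
run_agreement <- function(metrics, out_dir, filters = NULL,
                          pooled_median = TRUE) {
  if (is.character(metrics)) metrics <- read_metrics_table(metrics)
  metrics <- as_tibble(metrics)
  filters <- filters %||% unique(metrics$filter_label)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- purrr::set_names(
    purrr::map(filters, function(f) {
      agreement_study(metrics, filter = f, pooled_median = pooled_median)
    }), filters)
  flat <- purrr::map(reports, tidy) |> dplyr::bind_rows()
  readr::write_csv(flat, file.path(out_dir, "agreement.csv"))
  jsonlite::write_json(report_json(reports),
                       file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote agreement reports for variant(s): ",
          paste(filters, collapse = ", "))
  invisible(reports)
}
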