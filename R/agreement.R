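# Inter-reader agreement statistics for paired biomarker readings.
#
# Conventions pinned for reproducibility: quantiles use the type-7
# (linear interpolation) definition, SD uses the n-1 denominator
# everywhere, limits of agreement are bias +/- 1.96 x SD of the paired
# differences, and the Spearman CI uses the Fisher z transform with
# standard error 1/sqrt(n - 3).

#' Descriptive statistics for one metric vector
#'
#' @param values Numeric vector, length >= 1.
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `iqr`, `min`,
#'   `max`. Median and IQR use type-7 quantiles; `sd` uses the n-1
#'   denominator.
#' @export
descriptives <- function(values) {
  if (length(values) == 0L) abort("`values` must contain at least one value.")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  tibble(n = length(values), mean = mean(values), sd = sd(values),
         median = median(values), iqr = q[2] - q[1],
         min = min(values), max = max(values))
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' The point estimate is the Pearson correlation of average ranks (ties get
#' average ranks). The two-sided confidence interval is obtained on the
#' Fisher z scale with standard error `1/sqrt(n - 3)` and back-transformed;
#' the p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param values_a,values_b Paired numeric vectors (same length, n >= 4).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `rho`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
spearman_with_ci <- function(values_a, values_b, conf_level = 0.95) {
  n <- length(values_a)
  if (length(values_b) != n) abort("paired vectors must have equal length.")
  if (n < 4L) abort("Spearman correlation with a CI needs n >= 4 pairs.")
  if (sd(values_a) == 0 || sd(values_b) == 0) {
    abort("rank correlation is undefined for a constant vector.")
  }
  rho <- cor(values_a, values_b, method = "spearman")
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(atanh(rho) + c(-1, 1) * zcrit * se)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, ci_low = ci[1], ci_high = ci[2], p_value = p, n = n)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as `values_a - values_b`; the bias is their mean
#' and the limits of agreement are `bias +/- 1.96 x SD` of the differences
#' (n-1 denominator).
#'
#' @inheritParams spearman_with_ci
#' @return A one-row tibble: `bias`, `loa_halfwidth`, `loa_low`,
#'   `loa_high`, `n`.
#' @export
bland_altman <- function(values_a, values_b) {
  n <- length(values_a)
  if (length(values_b) != n) abort("paired vectors must have equal length.")
  if (n < 2L) abort("Bland-Altman analysis needs n >= 2 pairs.")
  d <- values_a - values_b
  bias <- mean(d)
  hw <- 1.96 * sd(d)
  tibble(bias = bias, loa_halfwidth = hw,
         loa_low = bias - hw, loa_high = bias + hw, n = n)
}

#' Median-split dichotomization of two readings
#'
#' Classifies each patient's value from each reading as below vs above a
#' median cutoff and cross-tabulates the two readings. By default the
#' cutoff is the median of the pooled 2n values of both readings (a single
#' shared cutoff); with `pooled = FALSE` each reading is split by its own
#' median. A value is "below" iff it is strictly less than the cutoff;
#' values equal to the cutoff count as "above".
#'
#' @inheritParams spearman_with_ci
#' @param pooled Use one cutoff from the pooled values (default) rather
#'   than per-reading medians.
#' @return A list with `cutoff` (scalar, or length-2 vector when
#'   `pooled = FALSE`) and `table`, a 2x2 integer matrix with rows =
#'   reading A (below/above) and columns = reading B.
#' @export
dichotomize_by_median <- function(values_a, values_b, pooled = TRUE) {
  n <- length(values_a)
  if (length(values_b) != n) abort("paired vectors must have equal length.")
  if (n < 2L) abort("median split needs n >= 2 pairs.")
  lv <- c("below", "above")
  if (pooled) {
    cutoff <- median(c(values_a, values_b))
    cut_a <- cut_b <- cutoff
  } else {
    cutoff <- c(a = median(values_a), b = median(values_b))
    cut_a <- cutoff[["a"]]
    cut_b <- cutoff[["b"]]
  }
  cls_a <- factor(ifelse(values_a < cut_a, "below", "above"), levels = lv)
  cls_b <- factor(ifelse(values_b < cut_b, "below", "above"), levels = lv)
  tab <- unclass(table(reading_a = cls_a, reading_b = cls_b))
  list(cutoff = cutoff, table = tab)
}

check_2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2L, 2L)) || any(t < 0) || anyNA(t)) {
    abort("expected a 2x2 table of non-negative counts.")
  }
  if (sum(t) == 0) abort("agreement is undefined for an empty table.")
  t
}

#' Percentage agreement of a 2x2 classification table
#'
#' @param t A 2x2 matrix of counts, rows = reading A classes, columns =
#'   reading B classes.
#' @return Observed agreement as a percentage in `[0, 100]`.
#' @examples
#' percent_agreement(matrix(c(56, 3, 2, 56), 2)) # 95.7
#' @export
percent_agreement <- function(t) {
  t <- check_2x2(t)
  100 * sum(diag(t)) / sum(t)
}

#' Cohen's kappa of a 2x2 classification table
#'
#' Chance-corrected agreement `(P0 - Pe) / (1 - Pe)` where `P0` is the
#' observed agreement fraction and `Pe` the expected agreement from the row
#' and column marginals. A fully concentrated table with `Pe = 1` and
#' perfect observed agreement returns 1; `Pe = 1` with imperfect agreement
#' is an error.
#'
#' @inheritParams percent_agreement
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(matrix(c(56, 3, 2, 56), 2)) # 0.91
#' @export
cohen_kappa <- function(t) {
  t <- check_2x2(t)
  n <- sum(t)
  p0 <- sum(diag(t)) / n
  pe <- sum(rowSums(t) * colSums(t)) / n^2
  if (pe >= 1 - 1e-12) {
    if (p0 >= 1 - 1e-12) return(1)
    abort("kappa is undefined: expected agreement is 1 but observed agreement is not.")
  }
  (p0 - pe) / (1 - pe)
}

#' Full two-reader agreement analysis of a patient metrics table
#'
#' Assembles the paired per-patient vectors for MTV, TLG and Dmax from a
#' long metrics table (one row per patient x reader for the requested
#' filter variant) and runs the complete agreement battery per metric:
#' descriptives, Spearman correlation with CI, Bland-Altman bias and limits
#' of agreement, pooled median split, percentage agreement and Cohen's
#' kappa. The lexicographically first reader id is treated as Reading A.
#'
#' @param data A metrics data frame with the columns of
#'   [read_metrics_table()]; exactly two distinct `reader_id` values.
#' @param filter Which `filter_label` variant to analyse (default `"all"`).
#' @param pooled_median Passed to [dichotomize_by_median()].
#' @param conf_level Confidence level for the Spearman CI.
#' @return An object of class `agreement_report`; see [tidy.agreement_report()],
#'   [glance.agreement_report()] and [autoplot.agreement_report()].
#' @examples
#' cfg <- phantom_config(n_patients = 6, seed = 7, grid_shape = c(28, 28, 36),
#'                       spacing_mm = c(4, 4, 4), lesion_count_mean = 3,
#'                       radius_range_mm = c(5, 12))
#' simulate_metrics(cfg) |> agreement_study(filter = "all")
#' @export
agreement_study <- function(data, filter = "all", pooled_median = TRUE,
                            conf_level = 0.95) {
  data <- as_tibble(data)
  need <- setdiff(metrics_cols, names(data))
  if (length(need)) {
    abort(paste0("metrics data is missing column(s): ",
                 paste(need, collapse = ", "), "."))
  }
  data <- data[data$filter_label == filter, ]
  if (nrow(data) == 0L) {
    abort(sprintf("no rows with filter_label = '%s'.", filter))
  }
  readers <- sort(unique(data$reader_id))
  if (length(readers) != 2L) {
    abort(sprintf("agreement analysis needs exactly two readers (found: %s).",
                  paste(readers, collapse = ", ")))
  }
  counts <- table(data$patient_id, data$reader_id)
  bad <- rownames(counts)[rowSums(counts == 1L) != 2L]
  if (length(bad)) {
    abort(paste0("patients without exactly one record per reader: ",
                 paste(bad, collapse = ", "), "."))
  }

  wide <- list(
    MTV = "mtv_cm3", TLG = "tlg", Dmax = "dmax_cm"
  )
  a_rows <- data[data$reader_id == readers[1], ]
  b_rows <- data[data$reader_id == readers[2], ]
  b_rows <- b_rows[match(a_rows$patient_id, b_rows$patient_id), ]

  pairs <- purrr::imap(wide, function(col, metric) {
    tibble(metric = metric, patient_id = a_rows$patient_id,
           value_a = a_rows[[col]], value_b = b_rows[[col]])
  }) |> dplyr::bind_rows()

  metrics <- purrr::imap(wide, function(col, metric) {
    a <- a_rows[[col]]
    b <- b_rows[[col]]
    da <- descriptives(a)
    db <- descriptives(b)
    sp <- spearman_with_ci(a, b, conf_level)
    ba <- bland_altman(a, b)
    ds <- dichotomize_by_median(a, b, pooled = pooled_median)
    list(metric = metric, n = length(a),
         median_a = da$median, iqr_a = da$iqr,
         median_b = db$median, iqr_b = db$iqr,
         spearman_rho = sp$rho, rho_ci_low = sp$ci_low,
         rho_ci_high = sp$ci_high, p_value = sp$p_value,
         bias = ba$bias, loa_halfwidth = ba$loa_halfwidth,
         cutoff = ds$cutoff, contingency = ds$table,
         percent_agreement = percent_agreement(ds$table),
         kappa = cohen_kappa(ds$table))
  })

  structure(
    list(filter_label = filter, readers = readers, n = nrow(a_rows),
         pooled_median = pooled_median, metrics = metrics, pairs = pairs),
    class = "agreement_report"
  )
}
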