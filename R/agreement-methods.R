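#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a two-reader agreement report
#'
#' @param x An `agreement_report` from [agreement_study()].
#' @param ... Unused.
#' @return One row per metric (MTV, TLG, Dmax) with the full-precision
#'   statistics: medians and IQRs per reading, Spearman rho with CI and
#'   p-value, Bland-Altman bias and limits-of-agreement halfwidth, the
#'   median cutoff(s), the four contingency cells (`n_below_below` is
#'   reading A below x reading B below, etc.), percentage agreement and
#'   Cohen's kappa.
#' @export
tidy.agreement_report <- function(x, ...) {
  purrr::map(x$metrics, function(m) {
    cut <- m$cutoff
    tibble(
      metric = m$metric, filter_label = x$filter_label, n = m$n,
      median_a = m$median_a, iqr_a = m$iqr_a,
      median_b = m$median_b, iqr_b = m$iqr_b,
      spearman_rho = m$spearman_rho, rho_ci_low = m$rho_ci_low,
      rho_ci_high = m$rho_ci_high, p_value = m$p_value,
      bias = m$bias, loa_halfwidth = m$loa_halfwidth,
      cutoff_a = unname(cut[1]), cutoff_b = unname(cut[length(cut)]),
      n_below_below = m$contingency[1, 1],
      n_below_above = m$contingency[1, 2],
      n_above_below = m$contingency[2, 1],
      n_above_above = m$contingency[2, 2],
      percent_agreement = m$percent_agreement, kappa = m$kappa
    )
  }) |> dplyr::bind_rows()
}

#' Glance at a two-reader agreement report
#'
#' @inheritParams tidy.agreement_report
#' @return A one-row tibble with the cohort size, filter variant and the
#'   headline rho and kappa per metric.
#' @export
glance.agreement_report <- function(x, ...) {
  m <- x$metrics
  tibble(
    n = x$n, filter_label = x$filter_label,
    readers = paste(x$readers, collapse = "/"),
    rho_mtv = m$MTV$spearman_rho, rho_tlg = m$TLG$spearman_rho,
    rho_dmax = m$Dmax$spearman_rho,
    kappa_mtv = m$MTV$kappa, kappa_tlg = m$TLG$kappa,
    kappa_dmax = m$Dmax$kappa
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Two-reader agreement (%d patients, readers %s, lesions: %s)\n",
    x$n, paste(x$readers, collapse = " vs "), x$filter_label))
  for (m in x$metrics) {
    cat(sprintf(
      "  %-4s rho %.2f (95%% CI %.2f-%.2f)  bias %.3g +/- %.3g  agreement %.1f%%  kappa %.2f\n",
      m$metric, m$spearman_rho, m$rho_ci_low, m$rho_ci_high,
      m$bias, m$loa_halfwidth, m$percent_agreement, m$kappa))
  }
  invisible(x)
}

#' Plot a two-reader agreement report
#'
#' `type = "bland_altman"` draws per-metric Bland-Altman panels (difference
#' vs mean of the two readings, with bias and limits-of-agreement lines);
#' `type = "scatter"` draws reading A vs reading B with the identity line
#' and the pooled median cutoff.
#'
#' @param object An `agreement_report`.
#' @param type `"bland_altman"` or `"scatter"`.
#' @param ... Unused.
#' @return A ggplot object faceted by metric.
#' @export
autoplot.agreement_report <- function(object,
                                      type = c("bland_altman", "scatter"),
                                      ...) {
  type <- match.arg(type)
  pairs <- object$pairs
  pairs$metric <- factor(pairs$metric, levels = c("MTV", "TLG", "Dmax"))
  stats <- tidy(object)
  stats$metric <- factor(stats$metric, levels = levels(pairs$metric))
  if (type == "bland_altman") {
    pairs <- dplyr::mutate(pairs,
                           avg = (.data$value_a + .data$value_b) / 2,
                           diff = .data$value_a - .data$value_b)
    lines <- tidyr::pivot_longer(
      dplyr::transmute(stats, metric = .data$metric, bias = .data$bias,
                       loa_low = .data$bias - .data$loa_halfwidth,
                       loa_high = .data$bias + .data$loa_halfwidth),
      -"metric", names_to = "which", values_to = "y")
    ggplot2::ggplot(pairs, ggplot2::aes(.data$avg, .data$diff)) +
      ggplot2::geom_hline(data = lines,
                          ggplot2::aes(yintercept = .data$y,
                                       linetype = .data$which == "bias"),
                          colour = "grey40", show.legend = FALSE) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::facet_wrap(~metric, scales = "free") +
      ggplot2::labs(x = "Mean of readings A and B",
                    y = "Reading A - Reading B") +
      ggplot2::theme_bw()
  } else {
    ggplot2::ggplot(pairs, ggplot2::aes(.data$value_b, .data$value_a)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_vline(data = stats,
                          ggplot2::aes(xintercept = .data$cutoff_b),
                          colour = "grey60", linetype = 2) +
      ggplot2::geom_hline(data = stats,
                          ggplot2::aes(yintercept = .data$cutoff_a),
                          colour = "grey60", linetype = 2) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::facet_wrap(~metric, scales = "free") +
      ggplot2::labs(x = "Reading B", y = "Reading A") +
      ggplot2::theme_bw()
  }
}

#' @rdname autoplot.agreement_report
#' @param report An `agreement_report`.
#' @export
plot_bland_altman <- function(report) autoplot(report, type = "bland_altman")

#' @rdname autoplot.agreement_report
#' @export
plot_reader_scatter <- function(report) autoplot(report, type = "scatter")
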