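#' Scatter plot of a fatigue index against the daily risk index
#'
#' @param records analysis records ([build_records()]).
#' @param x fatigue column, e.g. `"lf_score_post_prev"` or `"vas_pre"`.
#' @return A ggplot object (scatter with least-squares line and the
#'   Pearson r / p annotation).
#' @export
plot_risk_correlation <- function(records, x = "lf_score_post_prev") {
  use <- filter(records, .data$analysis_ready)
  cr <- correlate(use[[x]], use$r_1hr)
  ggplot2::ggplot(use, ggplot2::aes(x = .data[[x]], y = .data$r_1hr)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(
      x = x, y = expression(R["1hr"] ~ "(events/hour)"),
      subtitle = sprintf("r = %.2f, p = %.3g, n = %d", cr$r, cr$p, cr$n)
    ) +
    ggplot2::theme_minimal()
}

#' Box plot of a fatigue index for high- vs low-risk days
#'
#' Days are split at the median daily risk index (ties go low).
#'
#' @param records analysis records.
#' @param value fatigue column compared between groups.
#' @return A ggplot object annotated with the Welch p-value.
#' @export
plot_group_comparison <- function(records, value = "lf_score_post_prev") {
  use <- filter(records, .data$analysis_ready,
                is.finite(.data[[value]]), is.finite(.data$r_1hr))
  comp <- median_split_test(use, value)
  use$group <- factor(ifelse(use$r_1hr > comp$threshold, "high risk", "low risk"),
                      levels = c("low risk", "high risk"))
  ggplot2::ggplot(use, ggplot2::aes(x = .data$group, y = .data[[value]])) +
    ggplot2::geom_boxplot(width = 0.5, outlier.alpha = 0.4) +
    ggplot2::labs(
      x = NULL, y = value,
      subtitle = sprintf("Welch t = %.2f, p = %.3g (split at %.2f events/h)",
                         comp$t, comp$p, comp$threshold)
    ) +
    ggplot2::theme_minimal()
}
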