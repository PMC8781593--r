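# Diagnostic figures: prevalence curves, burden percentile curves, and a
# rate-ratio forest plot.

#' Plot an ARI prevalence curve
#'
#' Daily curves are drawn as a line over day of life; monthly curves as
#' columns over calendar months (seasonality).
#'
#' @param object An `"ari_prevalence"` tibble from [prevalence_by_day()] or
#'   [prevalence_by_month()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ari_prevalence <- function(object, ...) {
  if (object$axis[1] == "month") {
    df <- data.frame(month = factor(object$month, levels = month.abb),
                     proportion = object$proportion)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data$proportion)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "Proportion of child-days in ARI episode",
                    title = "ARI prevalence by calendar month") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$proportion)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::labs(x = "Day of life", y = "Proportion of children in ARI episode",
                    title = "ARI prevalence by age") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.ari_prevalence
#' @param curve An `"ari_prevalence"` tibble.
#' @export
plot_prevalence <- function(curve, ...) autoplot.ari_prevalence(curve, ...)

#' Plot cumulative distributions of per-child symptom days
#'
#' One ECDF step curve per measure (overall and per-symptom totals).
#'
#' @param curves Tibble from [percentile_curves()].
#' @param measures Optional subset of measures to draw.
#' @return A ggplot.
#' @export
plot_burden_cdf <- function(curves, measures = NULL) {
  if (!is.null(measures)) curves <- curves[curves$measure %in% measures, ]
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$days, y = .data$cdf,
                                       colour = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Days with symptom in first two years",
                  y = "Cumulative fraction of children", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of Poisson rate ratios
#'
#' @param object An `"ari_rr_fit"`.
#' @param ... Unused.
#' @return A ggplot (crude and adjusted estimates side by side when both
#'   were fitted).
#' @export
autoplot.ari_rr_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[!df$is_reference, ]
  df$label <- paste(df$covariate, df$level, sep = ": ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label,
                                   colour = .data$model)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Rate ratio (95% CI, log scale)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
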