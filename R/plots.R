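# ggplot2 visualisations

#' Forest plot of a pooled meta-analysis
#'
#' Per-study estimates with 95% intervals and the pooled estimate with its
#' scenario interval, on the analysis scale.
#'
#' @param object A `meta_pool` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_pool <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$informative, ]
  zc <- qnorm(1 - object$spec$alpha / 2)
  df <- tibble::tibble(
    label = c(td$study_id, "Pooled"),
    est = c(td$yi, object$estimate),
    lo = c(td$yi - zc * td$sei, object$ci_lo),
    hi = c(td$yi + zc * td$sei, object$ci_hi),
    pooled = c(rep(FALSE, nrow(td)), TRUE)
  )
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$est, y = .data$label,
                                   colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi),
                             show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("black", "firebrick")) +
    ggplot2::labs(
      x = paste0("Effect (",
                 if (object$spec$measure %in% c("OR", "RR"))
                   paste0("log ", object$spec$measure)
                 else "risk difference", ")"),
      y = NULL,
      title = paste0("Scenario ", object$spec$scenario, " (",
                     object$spec$measure, ")")
    ) +
    ggplot2::theme_minimal()
}

#' P-value trail of a fragility search
#'
#' The two-sided p-value after each applied event-status modification,
#' with the significance level marked.
#'
#' @param object A `fragility` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fragility <- function(object, ...) {
  alpha <- if (!is.null(object$spec$alpha)) object$spec$alpha else 0.05
  df <- tibble::tibble(step = c(0L, seq_along(object$trail)),
                       p = c(object$p0, object$trail))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$p)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Event-status modifications applied",
                  y = "Two-sided p-value",
                  title = if (object$attainable)
                    paste0("Fragility index = ", object$fi)
                  else "Fragility index not attainable") +
    ggplot2::theme_minimal()
}

#' Histogram of fragility indices across a corpus
#'
#' @param results A [run_scenarios()] tibble.
#' @param log_x Show the FI axis on a log10 scale (counts above 1000 are
#'   truncated from the plot, not from any summary).
#' @return A ggplot faceted by scenario and measure.
#' @export
plot_fi_distribution <- function(results, log_x = TRUE) {
  df <- dplyr::filter(results, !is.na(.data$fi))
  if (log_x) df <- dplyr::filter(df, .data$fi <= 1000)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fi)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_grid(measure ~ scenario) +
    ggplot2::labs(x = "Fragility index", y = "Meta-analyses") +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Paired FI differences between two scenarios
#'
#' @param results A [run_scenarios()] tibble.
#' @param scenario_a,scenario_b,measure Passed to [paired_differences()].
#' @return A ggplot bar chart of the sign of the per-MA FI difference.
#' @export
plot_paired_differences <- function(results, scenario_a, scenario_b,
                                    measure = "OR") {
  pd <- paired_differences(results, scenario_a, scenario_b,
                           measure = measure)
  pd$sign <- factor(sign(pd$fi_diff), levels = c(-1, 0, 1),
                    labels = c(paste0("FI(", scenario_a, ") < FI(",
                                      scenario_b, ")"),
                               "equal",
                               paste0("FI(", scenario_a, ") > FI(",
                                      scenario_b, ")")))
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$sign)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Meta-analyses",
                  title = paste0(scenario_a, " vs ", scenario_b, " (",
                                 measure, ")")) +
    ggplot2::theme_minimal()
}
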