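#' Plot the daily outcome series of a simulation
#'
#' Line-and-ribbon display of the per-day mean dietary diversity and
#' quality-index scores with their 95\% confidence bands, faceted by
#' indicator and coloured by group; an optional autonomous baseline is
#' overlaid for comparison.
#'
#' @param object A `meal_simulation`.
#' @param baseline Optional second `meal_simulation` (typically the
#'   autonomous policy) drawn in a second colour scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meal_simulation <- function(object, baseline = NULL, ...) {
  lab <- function(sim) {
    d <- sim$daily
    d$policy <- sim$policy
    d
  }
  dat <- lab(object)
  if (!is.null(baseline)) dat <- bind_rows(dat, lab(baseline))
  dat$indicator <- factor(dat$indicator, c("quality", "dds"),
                          c("diet-quality index", "dietary diversity score"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$mean,
                                    colour = .data$policy,
                                    fill = .data$policy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(indicator ~ group, scales = "free_y") +
    ggplot2::labs(x = "day", y = "daily mean (95% CI)",
                  colour = "policy", fill = "policy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Side-by-side outcome series for recommended vs autonomous policies
#'
#' @param result Recommended-policy `meal_simulation`.
#' @param baseline Autonomous-policy `meal_simulation`.
#' @return A ggplot object.
#' @export
plot_outcome_series <- function(result, baseline) {
  autoplot.meal_simulation(result, baseline = baseline)
}

#' Plot the comparison table as a dumbbell chart
#'
#' One row per group and indicator, showing the autonomous and recommended
#' means joined by a segment.
#'
#' @param comparison An `outcome_comparison`.
#' @return A ggplot object.
#' @export
plot_outcome_comparison <- function(comparison) {
  dat <- as_tibble(comparison) %>%
    mutate(label = paste(.data$group, .data$indicator, sep = " / "))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$autonomous_mean,
                                       xend = .data$recommended_mean,
                                       y = .data$label, yend = .data$label),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$autonomous_mean,
                                     y = .data$label, colour = "autonomous")) +
    ggplot2::geom_point(ggplot2::aes(x = .data$recommended_mean,
                                     y = .data$label,
                                     colour = "recommended")) +
    ggplot2::labs(x = "mean score", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
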