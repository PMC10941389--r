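# ggplot2 visualisations for the main result types.

#' Plot one animal's daily series with its smoothing and trend
#'
#' Shows observed daily feed consumption, the moving-median smooth and the
#' fitted linear age trend; runs of consecutive negative residuals are the
#' stretches where the smooth dips below the trend line.
#'
#' @param daily Daily tibble filtered to one animal.
#' @param window Moving-median window. Default 5.
#' @return A ggplot object.
#' @export
plot_daily_series <- function(daily, window = 5) {
  rs <- residual_series(daily, window = window)
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$age_days)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fcd_kg), colour = "grey60",
                        size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed,
                                    colour = "moving median")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted,
                                    colour = "linear trend")) +
    ggplot2::scale_colour_manual(
      values = c("moving median" = "forestgreen",
                 "linear trend" = "firebrick"), name = NULL) +
    ggplot2::labs(x = "age (days)", y = "feed consumption (kg/day)") +
    ggplot2::theme_minimal()
}

#' Density plot of the resilience indicators by breed
#'
#' @param object Tibble from [resilience_indicators()].
#' @param ... Unused.
#' @return A ggplot object (facetted per indicator).
#' @export
plot_indicator_distributions <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("animal_id", "breed", "lag1", "lnvar", "maxarea", "summin")],
    cols = c("lag1", "lnvar", "maxarea", "summin"),
    names_to = "indicator", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     colour = .data$breed)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~indicator, scales = "free") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal()
}

#' ROC curves of a PLS-DA evaluation
#'
#' @param object A `plsda_evaluation`.
#' @param ... Unused.
#' @return A ggplot object with one one-vs-rest ROC curve per class.
#' @export
autoplot.plsda_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Posterior distributions of a microbiability fit
#'
#' Trace and density of the microbiability draws.
#'
#' @param object A `microbiability_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.microbiability_fit <- function(object, ...) {
  d <- dplyr::mutate(object$draws, draw = dplyr::row_number())
  long <- tidyr::pivot_longer(d, cols = -"draw", names_to = "parameter",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = NULL) +
    ggplot2::theme_minimal()
}
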