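# ggplot2 displays for the fit classes and for scenario results.

#' Plot weighted selection frequencies
#'
#' Lollipop plot of the weighted frequency of every ever-selected variable
#' with the alpha-threshold as a dashed line; selected variables are
#' highlighted.
#'
#' @param object A [wss()] fit.
#' @param top Show at most this many variables (default 40), by decreasing
#'   frequency.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wss_fit
#' @export
autoplot.wss_fit <- function(object, top = 40, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$weighted_frequency > 0 | .data$selected) |>
    dplyr::slice_head(n = top)
  thr <- glance(object)$threshold
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$weighted_frequency),
    y = .data$weighted_frequency, colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = stats::reorder(.data$variable, .data$weighted_frequency),
                                       y = 0, yend = .data$weighted_frequency)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "weighted selection frequency",
                  colour = "selected",
                  title = sprintf("Weighted stability selection (B = %d, alpha = %g)",
                                  object$B, object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot complementary-pairs selection frequencies
#'
#' @param object A [cpss()] fit.
#' @param top Show at most this many variables (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cpss_fit
#' @export
autoplot.cpss_fit <- function(object, top = 40, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$frequency > 0 | .data$selected) |>
    dplyr::slice_head(n = top)
  ggplot2::ggplot(td, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$frequency),
    y = .data$frequency, colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = stats::reorder(.data$variable, .data$frequency),
                                       y = 0, yend = .data$frequency)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$pi_thr, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "simultaneous selection frequency",
                  colour = "selected",
                  title = sprintf("Stability selection (B = %d, q = %d, pi_thr = %g)",
                                  object$B, object$q, object$pi_thr)) +
    ggplot2::theme_minimal()
}

#' Boxplots of scenario results by method
#'
#' Displays the per-replicate metrics of a [run_scenario()] table as
#' boxplots, one panel per metric.
#'
#' @param results A [run_scenario()] tibble.
#' @param metrics Metrics to show (default the per-replicate four).
#' @return A ggplot object.
#' @export
plot_scenario_results <- function(results,
                                  metrics = c("tpr", "ppv", "n_selected",
                                              "auc_validation")) {
  dd <- dplyr::filter(results, .data$metric %in% metrics,
                      !is.na(.data$replicate), !is.na(.data$value))
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
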