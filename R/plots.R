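#' Plot a flight session's velocity trace
#'
#' Cleaned per-circuit velocities against circuit index, with excluded-window
#' boundaries implicit in the gaps.
#'
#' @param metrics A one-row metrics tibble from [compute_metrics()] /
#'   [process_session()].
#' @return A ggplot object.
#' @export
plot_session_velocity <- function(metrics) {
  stopifnot(nrow(metrics) == 1, "per_circuit" %in% names(metrics))
  pc <- metrics$per_circuit[[1]]
  ggplot2::ggplot(pc, ggplot2::aes(x = .data$circuit_index,
                                   y = .data$velocity_mps)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::labs(x = "circuit", y = "velocity (m/s)",
                  title = paste("Flight session", metrics$bee_id)) +
    ggplot2::theme_minimal()
}

#' Plot cohort attrition through the filter cascade
#'
#' @param object A `mill_cascade`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mill_cascade
#' @export
autoplot.mill_cascade <- function(object, ...) {
  d <- object$counts %>%
    tidyr::pivot_longer(c("control", "pesticide"),
                        names_to = "treatment", values_to = "n") %>%
    dplyr::mutate(step = factor(.data$step, levels = rev(cascade_steps)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$step,
                                  fill = .data$treatment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "bees remaining", y = NULL,
                  title = "Filter-cascade attrition") +
    ggplot2::theme_minimal()
}

#' Plot binned velocity trajectories by treatment
#'
#' Mean binned velocity per treatment over the trajectory window with
#' standard-error ribbons; the per-bee repeated-measures structure behind
#' [fit_velocity_trajectory()].
#'
#' @param binned_long A long table from [binned_velocity_table()].
#' @return A ggplot object.
#' @export
plot_velocity_trajectory <- function(binned_long) {
  d <- binned_long %>%
    dplyr::filter(!is.na(.data$mean_velocity_mps)) %>%
    dplyr::group_by(.data$treatment, .data$bin, .data$circuit_mid) %>%
    dplyr::summarise(
      v = mean(.data$mean_velocity_mps),
      se = stats::sd(.data$mean_velocity_mps) / sqrt(dplyr::n()),
      .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$circuit_mid, y = .data$v,
                                  colour = .data$treatment,
                                  fill = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$v - .data$se,
                                      ymax = .data$v + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "circuit", y = "mean velocity (m/s)",
                  title = "Binned velocity trajectory") +
    ggplot2::theme_minimal()
}

#' Plot an endurance metric against body size by treatment
#'
#' @param analysis_set A joined analysis tibble (e.g.
#'   `apply_cascade(...)$analysis_set`).
#' @param metric Column to plot on the y axis.
#' @return A ggplot object.
#' @export
plot_endurance <- function(analysis_set, metric = "total_distance_m") {
  ggplot2::ggplot(analysis_set,
                  ggplot2::aes(x = .data$its_mm, y = .data[[metric]],
                               colour = .data$treatment)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "intertegular span (mm)", y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
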