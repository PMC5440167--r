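#' Plot a connectivity matrix as a heatmap
#'
#' @param object A [connectivity_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.connectivity_table <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pn_id, y = .data$orn_id,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "synapses") +
    ggplot2::labs(x = "PN", y = "ORN") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a voltage trace
#'
#' @param object A `voltage_trace` from [simulate_epsp()].
#' @param ... Unused.
#' @return A ggplot of voltage against time for each recorded compartment.
#' @export
autoplot.voltage_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "compartment", values_to = "v")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$v,
                                     color = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_classic()
}

#' Plot classification accuracy against odor spike count
#'
#' One line per PN (detection) or per odor side (lateralization), colored by
#' wiring mode, mirroring the accuracy-versus-spike-surplus presentation of
#' the decoding experiments.
#'
#' @param object A `task_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.task_result <- function(object, ...) {
  group_col <- if ("pn_id" %in% names(object)) "pn_id" else "odor_side"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$condition, y = .data$accuracy,
                               color = .data$wiring,
                               group = interaction(.data[[group_col]],
                                                   .data$wiring))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(real = "#2166ac",
                                           equalized = "#1b7837")) +
    ggplot2::labs(x = "odor spike count", y = "classification accuracy") +
    ggplot2::ylim(0.4, 1) +
    ggplot2::theme_classic()
}
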