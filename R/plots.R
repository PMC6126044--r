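#' Plot a recalcitrance fit
#'
#' Solubilization rate against unutilized carbohydrate with the fitted
#' line; the x-intercept is the recalcitrant concentration `C0 fr`.
#'
#' @param object A `recalcitrance_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recalcitrance_fit
#' @export
autoplot.recalcitrance_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
    ggplot2::aes(x = .data$c_unutilized, y = .data$rate)) +
    ggplot2::geom_abline(slope = object$k,
      intercept = -object$k * object$c0 * object$f_r, linetype = 2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Unutilized carbohydrate C (g/L)",
      y = "Solubilization rate r (g/L/day)",
      title = sprintf("r = k (C - C0 fr): k = %.3f /day, fr = %.1f%%",
        object$k, 100 * object$f_r)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated reactor time course
#'
#' Accessible and recalcitrant pools and measured FCS over time.
#'
#' @param sim Output of [simulate_reactor()].
#' @return A ggplot.
#' @export
plot_reactor_timecourse <- function(sim) {
  long <- tidyr::pivot_longer(
    sim[, c("time", "c_accessible", "c_recalcitrant", "fcs_measured")],
    -"time", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pathway completeness per track
#'
#' Tile display of the completeness fraction and status of each marker set
#' in each organism track.
#'
#' @param pathways Output of [pathway_completeness()].
#' @return A ggplot.
#' @export
plot_pathway_completeness <- function(pathways) {
  ggplot2::ggplot(pathways,
    ggplot2::aes(x = .data$set_id, y = .data$track_id,
      fill = .data$fraction)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$status), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
      limits = c(0, 1)) +
    ggplot2::labs(x = "Marker set", y = "Track", fill = "Fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
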