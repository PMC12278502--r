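# ggplot2 figures for campaign interpretation: convergence, objective plane
# with Pareto front, and the partial-dependence panel.

#' Plot batch-wise hypervolume convergence
#'
#' @param convergence Output of [hv_convergence()] (optionally with
#'   `Strategy`/`Replicate` columns from [benchmark_optimizer()]).
#' @return A ggplot object.
#' @export
plot_convergence <- function(convergence) {
  p <- ggplot2::ggplot(convergence,
                       ggplot2::aes(x = Batch, y = TotalHV))
  if ("Replicate" %in% names(convergence)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(group = interaction(Strategy, Replicate),
                   colour = Strategy), alpha = 0.5)
  } else {
    p <- p + ggplot2::geom_line(colour = "steelblue") +
      ggplot2::geom_point(colour = "steelblue")
  }
  p + ggplot2::labs(x = "Batch", y = "Total hypervolume (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot the objective plane with the Pareto front highlighted
#'
#' @param front A `glyco_front` from [pareto_front()].
#' @param selectivity_label Axis label for the selectivity objective.
#' @return A ggplot object.
#' @export
plot_front <- function(front, selectivity_label = "Selectivity (%)") {
  ggplot2::ggplot(front$points,
                  ggplot2::aes(x = yield, y = selectivity)) +
    ggplot2::geom_point(ggplot2::aes(colour = on_front), size = 2) +
    ggplot2::geom_step(data = front$front, direction = "vh",
                       colour = "firebrick") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50"),
                                 name = "Pareto front") +
    ggplot2::labs(x = "Yield (%)", y = selectivity_label) +
    ggplot2::theme_minimal()
}

#' Plot a partial-dependence panel
#'
#' One facet per (parameter, objective) pair, mirroring the standard
#' trend-reading layout: rows of objectives, columns of parameters. Discrete
#' parameters are drawn at their level codes and connected (the connecting
#' line is a visual guide only; between-level values carry no physical
#' meaning).
#'
#' @param pdp A `glyco_pdp` data frame ([partial_dependence_panel()]).
#' @return A ggplot object.
#' @export
plot_partial_dependence <- function(pdp) {
  ggplot2::ggplot(pdp, ggplot2::aes(x = Grid, y = Response)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = pdp[!is.na(pdp$Level), ],
                        colour = "steelblue", size = 1) +
    ggplot2::facet_grid(Objective ~ Parameter, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Predicted objective (%)") +
    ggplot2::theme_minimal()
}
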