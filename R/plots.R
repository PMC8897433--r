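#' Plot smoothed expansion/contraction curves
#'
#' Shows the two smoothed phase curves over gap size with the area between
#' them (the extent of hysteresis) shaded, in the conventional styling:
#' dashed orange expansion, solid green contraction.
#'
#' @param object A `phase_curves` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_curves
#' @export
autoplot.phase_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("expansion", "contraction"),
                              names_to = "phase", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gap)) +
    ggplot2::geom_ribbon(
      data = as_tibble(object),
      ggplot2::aes(ymin = pmin(.data$expansion, .data$contraction),
                   ymax = pmax(.data$expansion, .data$contraction)),
      fill = "grey80", inherit.aes = TRUE
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value, colour = .data$phase,
                                    linetype = .data$phase), linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = c(expansion = "#E69F00",
                                            contraction = "#2E8B57")) +
    ggplot2::scale_linetype_manual(values = c(expansion = "dashed",
                                              contraction = "solid")) +
    ggplot2::labs(x = "gap size (mm)",
                  y = attr(object, "metric") %||% "value") +
    ggplot2::theme_minimal()
}

#' Plot a simulated bridge trajectory
#'
#' @param object A `bridge_trajectory` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot of the ant count over gap intervals, coloured by phase.
#' @method autoplot bridge_trajectory
#' @export
autoplot.bridge_trajectory <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$interval, y = .data$n_ants,
                               colour = .data$phase)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "gap interval", y = "ants in bridge") +
    ggplot2::theme_minimal()
}

#' Plot the mean response of a simulation experiment
#'
#' Mean ant count against gap size for the expansion and contraction phases
#' across all simulations of an experiment.
#'
#' @param object A `bridge_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bridge_experiment
#' @export
autoplot.bridge_experiment <- function(object, ...) {
  mc <- object$mean_curve[object$mean_curve$phase %in%
                            c("expansion", "contraction"), ]
  ggplot2::ggplot(mc, ggplot2::aes(x = .data$gap, y = .data$mean_n,
                                   colour = .data$phase,
                                   linetype = .data$phase)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::scale_colour_manual(values = c(expansion = "#E69F00",
                                            contraction = "#2E8B57")) +
    ggplot2::scale_linetype_manual(values = c(expansion = "dashed",
                                              contraction = "solid")) +
    ggplot2::labs(x = "gap size (mm)", y = "mean ants in bridge",
                  title = sprintf("%s model, %d simulations",
                                  object$model$family, object$n_sims)) +
    ggplot2::theme_minimal()
}

#' Plot a resampling null distribution
#'
#' Density of the resampled null means with the central-95% tails shaded and
#' the observed mean marked.
#'
#' @param object A `resample_result` from [resample_null()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot resample_result
#' @export
autoplot.resample_result <- function(object, ...) {
  df <- tibble(null_mean = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_mean)) +
    ggplot2::geom_density(fill = "grey85", colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(object$q_low, object$q_high),
                        linetype = "dotted", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#B2182B",
                        linewidth = 1) +
    ggplot2::labs(
      x = sprintf("mean %s in %g s before %s events (%s)",
                  object$signal, object$window, object$kind, object$phase),
      y = "null density"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
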