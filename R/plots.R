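#' Plot an orientation layout
#'
#' Positions colored by feed-forward preferred orientation; a map layout shows
#' the smooth pinwheel structure, a salt-and-pepper layout shows no spatial
#' order.
#'
#' @param object An `orientation_layout`.
#' @param population Which population to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot orientation_layout
#' @export
autoplot.orientation_layout <- function(object, population = "E", ...) {
  dat <- filter(as_tibble(object), .data$population == !!population)
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y, colour = .data$theta_deg)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradientn(
      colours = c("#d7191c", "#fdae61", "#ffffbf", "#abd9e9", "#2c7bb6", "#d7191c"),
      limits = c(0, 180), name = "PO (deg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = paste0("feed-forward preferred orientations (",
                                 attr(object, "layout_mode"), ")"))
}

#' Plot per-neuron tuning summaries
#'
#' OSI histogram per population.
#'
#' @param object A `tuning_result`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tuning_result
#' @export
autoplot.tuning_result <- function(object, bins = 20, ...) {
  dat <- filter(as_tibble(object), !is.na(.data$osi))
  ggplot2::ggplot(dat, ggplot2::aes(.data$osi)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, length.out = bins + 1),
                            fill = "grey35") +
    ggplot2::facet_wrap(~population, scales = "free_y") +
    ggplot2::labs(x = "orientation selectivity index", y = "neurons")
}

#' Plot a functional-connectivity cosine fit
#'
#' Bin means of the synaptic efficacy (or its change) against the wrapped
#' preferred-orientation difference, with the fitted
#' `a0 + 2 a1 cos(pi x / 90)` overlaid.
#'
#' @param object A `cosine_fit` from [bin_and_fit_dw()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cosine_fit
#' @export
autoplot.cosine_fit <- function(object, ...) {
  curve <- tibble(x = seq(0, 90, length.out = 181)) %>%
    mutate(y = object$a0 + 2 * object$a1 * cos(pi * .data$x / 90))
  ggplot2::ggplot(object$bins, ggplot2::aes(.data$bin_mid, .data$mean_value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, ggplot2::aes(.data$x, .data$y),
                       colour = "darkgreen") +
    ggplot2::labs(x = "preferred-orientation difference (deg)",
                  y = if (identical(object$value, "dw")) "mean weight change"
                      else "mean synaptic efficacy",
                  title = sprintf("a0 = %.3g, a1 = %.3g", object$a0, object$a1))
}

#' Plot the balanced ring solution
#'
#' Reconstructed rate profiles of both populations over the ring.
#'
#' @param object A `balanced_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot balanced_solution
#' @export
autoplot.balanced_solution <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$rates, c("nu_e", "nu_i"),
                             names_to = "population", values_to = "rate") %>%
    mutate(population = dplyr::if_else(.data$population == "nu_e", "E", "I"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$theta_deg, .data$rate,
                                    colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "preferred orientation (deg)",
                  y = "balanced rate (I_ext / G units)")
}

#' Plot an input decomposition
#'
#' Excitatory and inhibitory input components and their sum for a probed
#' neuron; in the balanced state the components are large and opposite while
#' the net input stays near the threshold scale.
#'
#' @param probe A probe tibble from [input_decomposition()].
#' @param v_t Threshold to draw as a reference line (mV).
#' @return A ggplot.
#' @export
plot_input_decomposition <- function(probe, v_t = 30) {
  dat <- tidyr::pivot_longer(probe, c("exc_mv", "inh_mv", "net_mv"),
                             names_to = "component", values_to = "mv")
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_ms, .data$mv,
                                    colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(0, v_t), linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = "input (mV via R_m)")
}
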