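#' Firing rates per neuron per stimulus angle
#'
#' Spike count in the half-open window `\[t_start, t_end)` divided by the
#' window length, in Hz. Neurons that never fired are included with rate 0.
#'
#' @param spikes A `spike_data` tibble from [run_protocol()].
#' @param window Optional `c(t_start, t_end)` in ms; defaults to
#'   `(t_transient, t_total)` recorded on the spike data.
#' @return A tibble with `angle_deg`, `population`, `neuron`, `rate_hz`;
#'   attribute `angles`.
#' @export
firing_rates <- function(spikes, window = NULL) {
  window <- window %||% c(attr(spikes, "t_transient"), attr(spikes, "t_total"))
  if (diff(window) <= 0) abort("empty rate window")
  n_e <- attr(spikes, "n_e"); n_i <- attr(spikes, "n_i")
  angles <- attr(spikes, "angles") %||% sort(unique(spikes$angle_deg))
  grid <- tidyr::expand_grid(
    angle_deg = angles,
    bind_rows(tibble(population = "E", neuron = seq_len(n_e)),
              tibble(population = "I", neuron = seq_len(n_i)))
  )
  counts <- spikes %>%
    filter(.data$time_ms >= window[1], .data$time_ms < window[2]) %>%
    group_by(.data$angle_deg, .data$population, .data$neuron) %>%
    summarise(n_sp = dplyr::n(), .groups = "drop")
  out <- grid %>%
    left_join(counts, by = c("angle_deg", "population", "neuron")) %>%
    mutate(rate_hz = dplyr::coalesce(.data$n_sp, 0L) / diff(window) * 1000) %>%
    select(-"n_sp")
  structure(out, angles = angles, class = class(tibble()))
}

#' Orientation selectivity index of a tuning curve
#'
#' Ratio of the first to the zeroth Fourier component of the firing rate over
#' equispaced stimulus orientations:
#' `sqrt((sum f cos 2theta)^2 + (sum f sin 2theta)^2) / sum f`.
#' 0 for a flat curve, 1 for a delta-function curve; undefined (NA) when all
#' rates are zero.
#'
#' @param rates Firing rates, one per angle.
#' @param angles_deg Stimulus orientations in degrees (>= 3, equispaced on
#'   \[0, 180)).
#' @return Scalar in \[0, 1\], or NA.
#' @export
osi <- function(rates, angles_deg = seq(0, 160, by = 20)) {
  stopifnot(length(rates) == length(angles_deg), length(rates) >= 3)
  f <- sum(rates)
  if (f == 0) return(NA_real_)
  th <- 2 * angles_deg * pi / 180
  sqrt(sum(rates * cos(th))^2 + sum(rates * sin(th))^2) / f
}

#' Preferred orientation from the population vector
#'
#' `PO = atan2(sum f sin 2theta, sum f cos 2theta) / 2`, mapped into
#' \[0, 180) degrees. Undefined (NA) when the vector is zero.
#'
#' @inheritParams osi
#' @return Scalar in \[0, 180) degrees, or NA.
#' @export
preferred_orientation <- function(rates, angles_deg = seq(0, 160, by = 20)) {
  stopifnot(length(rates) == length(angles_deg), length(rates) >= 3)
  th <- 2 * angles_deg * pi / 180
  s <- sum(rates * sin(th)); c <- sum(rates * cos(th))
  if (s == 0 && c == 0) return(NA_real_)
  wrap_orientation(atan2(s, c) / 2 * 180 / pi)
}

#' Tuning summary per neuron
#'
#' Collapses a rate table into one row per neuron with the stimulus-averaged
#' rate, the orientation selectivity index and the population-vector preferred
#' orientation. Neurons with zero rate at every angle get NA for both.
#'
#' @param rates A rate tibble from [firing_rates()].
#' @return A tibble of class `tuning_result` with `population`, `neuron`,
#'   `mean_rate`, `osi`, `po_deg`.
#' @export
compute_tuning <- function(rates) {
  th <- 2 * rates$angle_deg * pi / 180
  out <- rates %>%
    mutate(.c = .data$rate_hz * cos(th), .s = .data$rate_hz * sin(th)) %>%
    group_by(.data$population, .data$neuron) %>%
    summarise(
      mean_rate = mean(.data$rate_hz),
      .csum = sum(.data$.c), .ssum = sum(.data$.s), .f = sum(.data$rate_hz),
      .groups = "drop"
    ) %>%
    mutate(
      osi = dplyr::if_else(.data$.f > 0,
                           sqrt(.data$.csum^2 + .data$.ssum^2) / .data$.f,
                           NA_real_),
      po_deg = dplyr::if_else(.data$.f > 0,
                              wrap_orientation(atan2(.data$.ssum, .data$.csum) / 2 * 180 / pi),
                              NA_real_)
    ) %>%
    select("population", "neuron", "mean_rate", "osi", "po_deg")
  structure(out, class = c("tuning_result", class(tibble())))
}

#' Population summary of tuning
#'
#' Mean rate and mean OSI per population. Silent neurons (zero rate at every
#' angle, hence undefined OSI) are excluded from the OSI mean by default and
#' reported in `n_silent`; with `include_silent = TRUE` they enter the mean
#' with OSI 0.
#'
#' @param tuning A `tuning_result` tibble.
#' @param include_silent Count silent neurons as OSI 0?
#' @return A tibble with `population`, `n`, `n_silent`, `mean_rate`,
#'   `mean_osi`.
#' @export
population_summary <- function(tuning, include_silent = FALSE) {
  tuning %>%
    group_by(.data$population) %>%
    summarise(
      n = dplyr::n(),
      n_silent = sum(is.na(.data$osi)),
      mean_rate = mean(.data$mean_rate),
      mean_osi = if (include_silent) {
        mean(dplyr::coalesce(.data$osi, 0))
      } else {
        mean(.data$osi, na.rm = TRUE)
      },
      .groups = "drop"
    )
}

#' OSI histogram
#'
#' @param tuning A `tuning_result` tibble.
#' @param bins Number of bins on \[0, 1\].
#' @return A tibble with `population`, `bin_lo`, `bin_hi`, `bin_mid`, `count`.
#' @export
osi_histogram <- function(tuning, bins = 20L) {
  breaks <- seq(0, 1, length.out = bins + 1)
  tuning %>%
    filter(!is.na(.data$osi)) %>%
    group_by(.data$population) %>%
    reframe({
      h <- graphics::hist(pmin(.data$osi, 1 - 1e-12), breaks = breaks,
                          right = FALSE, plot = FALSE)
      tibble(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
             bin_mid = h$mids, count = h$counts)
    })
}

# internal: unweighted least squares of bin means against
# F(x) = a0 + 2 a1 cos(pi x / 90), x in degrees on [0, 90]
fit_cosine_bins <- function(x_deg, value, bin_width = 10) {
  breaks <- seq(0, 90, by = bin_width)
  bin <- cut(x_deg, breaks = breaks, include.lowest = TRUE, right = FALSE)
  bins <- tibble(x = x_deg, value = value, bin = bin) %>%
    group_by(.data$bin) %>%
    summarise(mean_value = mean(.data$value), n = dplyr::n(), .groups = "drop") %>%
    mutate(bin_mid = head(breaks, -1)[as.integer(.data$bin)] + bin_width / 2)
  if (nrow(bins) < length(breaks) - 1) {
    warn(sprintf("%d empty bin(s) excluded from the cosine fit",
                 length(breaks) - 1 - nrow(bins)))
  }
  basis <- 2 * cos(pi * bins$bin_mid / 90)
  fit <- lm(mean_value ~ basis, data = bins)
  structure(
    list(a0 = unname(coef(fit)[1]), a1 = unname(coef(fit)[2]),
         bins = select(bins, "bin_mid", "mean_value", "n"),
         residual_ss = sum(fit$residuals^2),
         n_points = length(x_deg)),
    class = "cosine_fit"
  )
}

#' Functional-connectivity cosine fit of synaptic weights
#'
#' For every edge of the requested block, pairs the (final) normalized
#' efficacy with the wrapped difference of the preferred orientations of its
#' endpoints, averages in 10-degree bins over \[0, 90\], and fits
#' `F(x) = a0 + 2 a1 cos(pi x / 90)` by unweighted least squares on the bin
#' means. `a0` estimates the change of the mean connectivity mode, `a1` the
#' modulated (functional-connectivity) mode.
#'
#' @param graph A `connectivity_graph` (typically after [apply_plasticity()]).
#' @param po_deg Preferred orientations: numeric vector in layout row order or
#'   a tibble with `population`, `neuron`, `po_deg`.
#' @param block Which block to analyse, e.g. `"EE"` (post, pre).
#' @param value `"w"` for the final efficacy, `"dw"` for the change from 1.
#' @param bin_width Bin width in degrees.
#' @return A `cosine_fit` object with: elements
#'   `a0`, `a1`, `bins`, `residual_ss`. Has \[tidy()] and [glance()] methods
#'   and an [ggplot2::autoplot()] method.
#' @export
bin_and_fit_dw <- function(graph, po_deg, block = "EE",
                           value = c("w", "dw"), bin_width = 10) {
  value <- match.arg(value)
  n_e <- attr(graph, "n_e"); n_i <- attr(graph, "n_i")
  geom <- attr(graph, "geometry")
  if (is.data.frame(po_deg)) {
    po_deg <- left_join(as_tibble(geom)[, c("population", "neuron")],
                        po_deg[, c("population", "neuron", "po_deg")],
                        by = c("population", "neuron"))$po_deg
  }
  stopifnot(length(po_deg) == n_e + n_i)
  a <- substr(block, 1, 1); b <- substr(block, 2, 2)
  edges <- filter(graph, .data$post_pop == a, .data$pre_pop == b)
  gpost <- edges$post + ifelse(a == "I", n_e, 0L)
  gpre <- edges$pre + ifelse(b == "I", n_e, 0L)
  dpo <- orientation_difference(po_deg[gpost], po_deg[gpre])
  y <- if (value == "w") edges$w else edges$w - 1
  out <- fit_cosine_bins(dpo, y, bin_width)
  out$block <- block
  out$value <- value
  out
}

#' @method tidy cosine_fit
#' @export
tidy.cosine_fit <- function(x, ...) {
  tibble(term = c("a0", "a1"), estimate = c(x$a0, x$a1))
}

#' @method glance cosine_fit
#' @export
glance.cosine_fit <- function(x, ...) {
  tibble(a0 = x$a0, a1 = x$a1, residual_ss = x$residual_ss,
         n_bins = nrow(x$bins), n_points = x$n_points)
}

#' @method print cosine_fit
#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf("cosine fit a0 + 2 a1 cos(pi x / 90): a0 = %.4g, a1 = %.4g (%d bins, %d points)\n",
              x$a0, x$a1, nrow(x$bins), x$n_points))
  invisible(x)
}
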