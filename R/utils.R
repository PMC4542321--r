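#' Wrap an orientation to \[0, 180) degrees
#'
#' Orientations are axial quantities: an angle and the same angle plus 180
#' degrees describe the same grating. All user-facing angles in the package
#' live on \[0, 180).
#'
#' @param theta_deg Numeric vector of angles in degrees.
#' @return Numeric vector wrapped into \[0, 180).
#' @export
wrap_orientation <- function(theta_deg) {
  theta_deg %% 180
}

#' Wrapped difference between two preferred orientations
#'
#' Uses the double-angle metric: orientations live on a half-circle, so the
#' largest possible difference is 90 degrees.
#'
#' @param a_deg,b_deg Numeric vectors of orientations in degrees.
#' @return Absolute wrapped difference in degrees, in \[0, 90\].
#' @export
orientation_difference <- function(a_deg, b_deg) {
  d <- abs(a_deg - b_deg) %% 180
  pmin(d, 180 - d)
}

#' Circular correlation of two sets of orientations
#'
#' Fisher-Lee circular correlation computed on doubled angles, the natural
#' embedding for axial data. Returns a value in \[-1, 1\]; values near 1 mean
#' the two orientation assignments agree up to a rotation.
#'
#' @param a_deg,b_deg Numeric vectors of orientations in degrees (same length).
#' @return Scalar correlation.
#' @export
circular_correlation <- function(a_deg, b_deg) {
  stopifnot(length(a_deg) == length(b_deg))
  keep <- is.finite(a_deg) & is.finite(b_deg)
  a <- 2 * a_deg[keep] * pi / 180
  b <- 2 * b_deg[keep] * pi / 180
  ma <- atan2(mean(sin(a)), mean(cos(a)))
  mb <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - ma)
  sb <- sin(b - mb)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

#' Coefficient of variation of interspike intervals
#'
#' Pools interspike intervals per neuron and reports the mean CV over neurons
#' with at least `min_spikes` spikes. CV(ISI) well above 0 (conventionally
#' above 0.5) is the signature of irregular, fluctuation-driven firing in the
#' balanced state.
#'
#' @param spikes A spike tibble with columns `population`, `neuron`, `time_ms`
#'   (a single stimulus condition).
#' @param min_spikes Minimum spikes per neuron to contribute a CV estimate.
#' @return Tibble with columns `population`, `n_neurons`, `cv_isi`.
#' @export
cv_isi <- function(spikes, min_spikes = 3L) {
  spikes %>%
    group_by(.data$population, .data$neuron) %>%
    summarise(
      n_sp = dplyr::n(),
      cv = if (dplyr::n() >= min_spikes) {
        isi <- diff(sort(.data$time_ms))
        sd(isi) / mean(isi)
      } else NA_real_,
      .groups = "drop"
    ) %>%
    group_by(.data$population) %>%
    summarise(
      n_neurons = sum(!is.na(.data$cv)),
      cv_isi = mean(.data$cv, na.rm = TRUE),
      .groups = "drop"
    )
}

# internal: derive per-task integer seeds from a master seed, reproducibly and
# independently of the caller's RNG state
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
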