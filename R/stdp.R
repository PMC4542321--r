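#' Single-pair STDP weight change
#'
#' The multiplicative pair rule. For a pre/post spike pair with
#' `delta_t = t_post - t_pre` (ms) and current normalized efficacy `w`:
#' potentiation `a_plus * exp(-delta_t/tau_plus) * (2 - w)` for `delta_t > 0`,
#' depression `a_minus * exp(delta_t/tau_minus) * w` for `delta_t < 0`
#' (`a_minus < 0`), and no change for exactly simultaneous spikes. The
#' multiplicative factors make updates vanish as `w` approaches the bounds 0
#' and 2.
#'
#' @param w Normalized efficacy in \[0, 2\] (vectorized).
#' @param delta_t `t_post - t_pre` in ms (vectorized).
#' @param params A `balnet_config` list (uses `a_plus`, `a_minus`,
#'   `tau_plus`, `tau_minus`).
#' @return The weight change `dw` (same length as the inputs).
#' @export
stdp_update <- function(w, delta_t, params = default_params()) {
  if (any(w < 0 | w > 2)) abort("w must lie in [0, 2]")
  dplyr::case_when(
    delta_t > 0 ~ params$a_plus * exp(-delta_t / params$tau_plus) * (2 - w),
    delta_t < 0 ~ params$a_minus * exp(delta_t / params$tau_minus) * w,
    TRUE ~ 0
  )
}

#' Integral of the STDP window
#'
#' `alpha = a_plus * tau_plus + a_minus * tau_minus` (ms). Its sign decides
#' whether uncorrelated pre/post activity potentiates (`alpha > 0`) or
#' depresses on average; the defaults give `alpha = 0.204` ms.
#'
#' @param params A `balnet_config` list.
#' @return Scalar (ms).
#' @export
stdp_alpha <- function(params = default_params()) {
  params$a_plus * params$tau_plus + params$a_minus * params$tau_minus
}

#' Apply STDP to one synapse over full spike trains
#'
#' All-to-all pairing: every pre/post spike pair across the whole history
#' contributes, implemented online with two exponential traces (exact for
#' exponential windows). Updates are applied with the weight value current at
#' the triggering spike and clipped to \[0, 2\]. With `freeze = TRUE` the
#' multiplicative factors are held at `w0` and the accumulated (unclipped)
#' change is returned instead -- the linearized drift used by the mean-field
#' analysis.
#'
#' @param pre_times,post_times Sorted spike times (ms).
#' @param w0 Initial efficacy in \[0, 2\].
#' @param params A `balnet_config` list.
#' @param freeze Hold the multiplicative factors at `w0`?
#' @return A list with `w` (final efficacy) and `dw` (total change).
#' @export
stdp_pair <- function(pre_times, post_times, w0 = 1,
                      params = default_params(), freeze = FALSE) {
  if (w0 < 0 || w0 > 2) abort("w0 must lie in [0, 2]")
  if (is.unsorted(pre_times) || is.unsorted(post_times)) {
    abort("spike times must be sorted")
  }
  stdp_pair_cpp(as.numeric(pre_times), as.numeric(post_times), w0,
                params$a_plus, params$a_minus,
                params$tau_plus, params$tau_minus, 2, freeze)
}

#' Mean-field STDP drift
#'
#' Predicted mean weight change per second for a synapse between two neurons
#' with mean rates `nu_post_hz`, `nu_pre_hz`, tuning-curve selectivities
#' `xi_post`, `xi_pre` (each in \[0, 0.5\]) and preferred-orientation difference
#' `dpo_deg`, after averaging over the stimulus orientation:
#' `alpha * nu_post * nu_pre * (1 + 2 xi_post xi_pre cos(2 dPO))`.
#' The modulated part is quadratic in the selectivities, which is why more
#' selective networks develop more functional connectivity under STDP.
#'
#' @param nu_post_hz,nu_pre_hz Stimulus-averaged rates (Hz).
#' @param xi_post,xi_pre Selectivities in \[0, 0.5\].
#' @param dpo_deg Preferred-orientation difference (degrees).
#' @param alpha STDP window integral (ms), e.g. [stdp_alpha()].
#' @return Predicted mean `dw` per second (vectorized over `dpo_deg`).
#' @export
mean_field_dw <- function(nu_post_hz, nu_pre_hz, xi_post, xi_pre,
                          dpo_deg, alpha = stdp_alpha()) {
  stopifnot(xi_post >= 0, xi_post <= 0.5, xi_pre >= 0, xi_pre <= 0.5)
  # alpha [ms] * nu [1/ms]^2 = drift per ms; report per second
  alpha * (nu_post_hz / 1000) * (nu_pre_hz / 1000) * 1000 *
    (1 + 2 * xi_post * xi_pre * cos(2 * dpo_deg * pi / 180))
}

#' Rate-based Monte-Carlo of the STDP drift vs preferred-orientation difference
#'
#' Simulates independent Poisson pre/post pairs whose rates are cosine-tuned
#' to the stimulus (`nu = nu0 (1 + 2 xi cos(2(theta - PO)))`), presents the
#' stimulus protocol segment by segment, accumulates the STDP weight change of
#' each pair, and bins the result against the preferred-orientation
#' difference. With `freeze = TRUE` (drift at `w0 = 1`, the linearized
#' regime) the binned curve is the Monte-Carlo counterpart of
#' [mean_field_dw()].
#'
#' @param n_pairs Number of neuron pairs.
#' @param nu0_hz Stimulus-averaged rate of every neuron (Hz).
#' @param xi Selectivity of every neuron.
#' @param t_per_angle_ms Exposure per stimulus orientation (ms).
#' @param angles Stimulus orientations (degrees); permute to test
#'   protocol-order invariance.
#' @param params A `balnet_config` list (STDP constants).
#' @param freeze Accumulate the linearized drift at `w = 1` instead of the
#'   full multiplicative update.
#' @param seed Integer seed.
#' @return A list with `pairs` (tibble: `dpo_deg`, `dw`), `fit` (a
#'   `cosine_fit` over 10-degree bins) and `dw_per_s` (mean drift per second).
#' @export
stdp_drift_experiment <- function(n_pairs = 500, nu0_hz = 10, xi = 0.3,
                                  t_per_angle_ms = 20000,
                                  angles = seq(0, 160, by = 20),
                                  params = default_params(),
                                  freeze = TRUE, seed = 1L) {
  set.seed(seed)
  po_pre <- runif(n_pairs, 0, 180)
  dpo <- runif(n_pairs, 0, 180)
  po_post <- wrap_orientation(po_pre + dpo)
  poisson_train <- function(po) {
    # one continuous session: segments of constant rate, one per angle
    trains <- lapply(seq_along(angles), function(s) {
      rate <- nu0_hz / 1000 * (1 + 2 * xi * cos(2 * (angles[s] - po) * pi / 180))
      n <- stats::rpois(1, rate * t_per_angle_ms)
      sort(runif(n, 0, t_per_angle_ms)) + (s - 1) * t_per_angle_ms
    })
    unlist(trains)
  }
  dw <- vapply(seq_len(n_pairs), function(i) {
    stdp_pair(poisson_train(po_pre[i]), poisson_train(po_post[i]),
              w0 = 1, params = params, freeze = freeze)$dw
  }, numeric(1))
  pairs <- tibble(dpo_deg = orientation_difference(po_post, po_pre), dw = dw)
  list(
    pairs = pairs,
    fit = fit_cosine_bins(pairs$dpo_deg, pairs$dw),
    dw_per_s = mean(dw) / (length(angles) * t_per_angle_ms / 1000)
  )
}

#' First-order mean-field effect of STDP on the connectivity Fourier modes
#'
#' In the linearized regime the mean connectivity mode grows as
#' `dJ0 = alpha * nu_post * nu_pre` per unit time while the modulated mode
#' grows as `dJ1 = alpha * nu_post * nu_pre * xi_post * xi_pre` -- quadratic
#' in the selectivities. Because balanced-state selectivity is proportional to
#' `J(0)/J(1)`, the first-order relative change of selectivity is
#' `dJ0/J0 - dJ1/J1`; whether STDP helps therefore depends on how modulated
#' the connectivity already is.
#'
#' @param nu_post_hz,nu_pre_hz Mean rates (Hz).
#' @param xi_post,xi_pre Selectivities (cosine tuning gives values in
#'   \[0, 0.5\]; measured OSI up to 1 is accepted).
#' @param alpha STDP window integral (ms).
#' @return A tibble with `d_j0_per_s`, `d_j1_per_s` and their ratio
#'   `d_j1_over_d_j0` (`= xi_post * xi_pre`).
#' @export
stdp_theory <- function(nu_post_hz, nu_pre_hz, xi_post, xi_pre,
                        alpha = stdp_alpha()) {
  # cosine tuning caps xi at 0.5, but measured OSI values (which may exceed
  # that for sharper-than-cosine curves) are accepted as proxies
  stopifnot(xi_post >= 0, xi_post <= 1, xi_pre >= 0, xi_pre <= 1)
  base <- alpha * (nu_post_hz / 1000) * (nu_pre_hz / 1000) * 1000
  tibble(
    d_j0_per_s = base,
    d_j1_per_s = base * xi_post * xi_pre,
    d_j1_over_d_j0 = xi_post * xi_pre
  )
}
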