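#' Default model parameters
#'
#' Returns the full parameter set of the layer 2/3 network model as a named
#' list. Units are fixed to \{mV, ms, nA, MOhm\} so that `r_m * I` is in mV and
#' the printed values below can be used verbatim.
#'
#' * `tau` (ms), `r_m` (MOhm), `v_t`, `v_reset` (mV): leaky integrate-and-fire
#'   membrane constants; threshold 30 mV, reset 0 mV.
#' * `g_ee`, `g_ei`, `g_ie`, `g_ii`: recurrent coupling magnitudes `G_AB`
#'   (signed; inhibitory-presynaptic couplings negative). The per-synapse
#'   efficacy used in the simulation is `G_AB / sqrt(K)` (nA ms), the balanced
#'   1/sqrt(K) scaling.
#' * `g_el`, `g_il` (nA ms): feed-forward synaptic efficacies.
#' * `tau_syn_e`, `tau_syn_i` (ms): synaptic time constants of excitatory and
#'   inhibitory presynaptic kernels (the long excitatory constant folds NMDA
#'   into the AMPA kernel).
#' * `k`: mean recurrent in-degree per presynaptic population; `k_al`:
#'   feed-forward synapse count.
#' * `sigma`: Gaussian footprint of the connection probability, as a fraction
#'   of the patch size `m`.
#' * `fr_l` (Hz): mean layer 4 rate; `rho_e`, `rho_i`: feed-forward input
#'   modulation (input OSI), at most 0.5.
#' * `i_back_e`, `i_back_i` (nA): background current scale; the actual
#'   current is `sqrt(k) * i_back`.
#' * `a_plus`, `a_minus`, `tau_plus`, `tau_minus`: STDP amplitudes (unitless)
#'   and window time constants (ms); `a_minus < 0`.
#' * `n_e`, `n_i`: population sizes (both must be perfect squares); `m`:
#'   linear patch size (nominal mm).
#' * `dt` (ms), `t_total`, `t_transient` (ms), `angles` (degrees): integration
#'   step and stimulus protocol.
#'
#' @return A named list of class `balnet_config`.
#' @export
default_params <- function() {
  structure(list(
    tau = 20, r_m = 38.3, v_t = 30, v_reset = 0,
    g_ee = 32, g_ei = -96, g_ie = 96, g_ii = -128,
    g_el = 1.65, g_il = 1.65,
    tau_syn_e = 25, tau_syn_i = 4,
    k = 500, k_al = 250,
    sigma = 0.2,
    fr_l = 15,
    rho_e = 0.06, rho_i = 0.06,
    i_back_e = 0.12, i_back_i = 0.12,
    a_plus = 0.0128, a_minus = -0.0045,
    tau_plus = 30, tau_minus = 40,
    n_e = 8100, n_i = 2025, m = 1,
    dt = 0.05, t_total = 20000, t_transient = 100,
    angles = seq(0, 160, by = 20),
    layout = "random",
    seed = 1L
  ), class = "balnet_config")
}

#' Rescale the connectivity degree, keeping the balanced operating point
#'
#' Changes the recurrent in-degree `k` while keeping the network at the same
#' balanced operating point: the feed-forward synapse count tracks the
#' recurrent one (`k_al = k / 2`, the default ratio), and the feed-forward
#' efficacy follows the same 1/sqrt(K) scaling as the recurrent couplings,
#' `g_al = G_AL / sqrt(k_al)` with `G_AL = 1.65 * sqrt(250)` fixed by the
#' default values. With this convention every input component (feed-forward,
#' recurrent, background) grows as sqrt(K) while the leading-order balanced
#' rates are unchanged, which is the regime in which K-scaling comparisons
#' are meaningful.
#'
#' @param params A `balnet_config` list.
#' @param k New mean recurrent in-degree.
#' @return The modified parameter list.
#' @export
scale_connectivity <- function(params, k) {
  stopifnot(k > 0)
  g_al_ref <- 1.65 * sqrt(250)
  params$k <- k
  params$k_al <- k / 2
  params$g_el <- g_al_ref / sqrt(params$k_al)
  params$g_il <- g_al_ref / sqrt(params$k_al)
  params
}

#' Load a configuration file
#'
#' Reads a YAML configuration. Keys not present fall back to
#' [default_params()]; unknown keys and type mismatches are rejected with the
#' offending key named.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return A named list of class `balnet_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- default_params()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (key in names(raw)) {
    want <- defaults[[key]]
    got <- raw[[key]]
    if (is.numeric(want) && !is.numeric(got)) {
      abort(sprintf("config key '%s': expected numeric, got %s", key, class(got)[1]))
    }
    if (is.character(want) && !is.character(got)) {
      abort(sprintf("config key '%s': expected character, got %s", key, class(got)[1]))
    }
    if (key == "angles") got <- as.numeric(got)
    defaults[[key]] <- got
  }
  defaults
}

#' Save a configuration file
#'
#' @param params A `balnet_config` list.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' A short digest identifying a configuration
#'
#' Hash of the canonical YAML serialization; embedded in output tables so a
#' result can be traced back to the exact parameter set that produced it.
#'
#' @param params A `balnet_config` list.
#' @return A character scalar.
#' @export
config_digest <- function(params) {
  txt <- yaml::as.yaml(unclass(params))
  # small FNV-1a style rolling hash; no external digest dependency
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Experiment presets
#'
#' Returns a ready-made configuration plus a run plan for the package's
#' standard experiments. `scale = "full"` uses the published network sizes and
#' run lengths (overnight-scale jobs); `scale = "desk"` shrinks the network
#' about 9-fold (`n_e = 900`, `n_i = 225`), sets `k = 100` via
#' [scale_connectivity()] and shortens runs to 5 s. Desk-scale outputs are
#' flagged and should be read directionally, not compared with full-scale
#' numbers.
#'
#' @param name One of `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`, `"fig8"`,
#'   `"fig9"`, `"reduced"`.
#' @param scale `"full"` or `"desk"`.
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @return A list with elements `config` (a `balnet_config`), `plan` (a tibble
#'   of runs), `scaled` (logical) and `seeds` (integer vector, one per run).
#' @export
preset <- function(name = c("fig3", "fig4", "fig5", "fig6", "fig8", "fig9", "reduced"),
                   scale = c("full", "desk"), seed = 1L) {
  name <- tryCatch(match.arg(name), error = function(e) {
    abort(paste0("unknown preset; available: fig3, fig4, fig5, fig6, fig8, fig9, reduced"))
  })
  scale <- match.arg(scale)
  cfg <- default_params()
  desk <- scale == "desk"
  if (desk) {
    cfg$n_e <- 900; cfg$n_i <- 225
    cfg <- scale_connectivity(cfg, 100)
    cfg$t_total <- 5000
  }
  plan <- switch(name,
    fig3 = {
      if (!desk) { cfg$n_e <- 16129; cfg$n_i <- 4096 }
      ks <- if (desk) c(100, 400) else c(250, 1000)
      tibble(run = paste0("k", ks), layout = "random", k = ks,
             stdp = FALSE, eps_ce = NA_real_, eps_ci = NA_real_,
             note = "input decomposition on one probed neuron")
    },
    fig4 = tibble(run = c("map", "salt_and_pepper"), layout = c("map", "random"),
                  k = cfg$k, stdp = FALSE, eps_ce = NA_real_, eps_ci = NA_real_,
                  note = "OSI distribution of the excitatory population"),
    fig5 = tibble(run = c("map_pre", "map_post", "sp_pre", "sp_post"),
                  layout = c("map", "map", "random", "random"),
                  k = cfg$k, stdp = c(FALSE, TRUE, FALSE, TRUE),
                  eps_ce = NA_real_, eps_ci = NA_real_,
                  note = "OSI before/after STDP"),
    fig6 = tibble(run = c("sp_stdp", "map_stdp"), layout = c("random", "map"),
                  k = cfg$k, stdp = TRUE, eps_ce = NA_real_, eps_ci = NA_real_,
                  note = "weight change vs preferred-orientation difference, cosine fit"),
    fig8 = {
      eps_ce <- c(seq(0, 0.44, by = 0.11), rep(0.44, 5))
      eps_ci <- c(rep(0.22, 5), seq(0.11, 0.55, by = 0.11))
      tibble(run = sprintf("ce%.2f_ci%.2f", eps_ce, eps_ci), layout = "random",
             k = cfg$k, stdp = FALSE, eps_ce = eps_ce, eps_ci = eps_ci,
             note = "stable-regime reconnection grids")
    },
    fig9 = {
      eps_ci <- seq(0.01, 0.09, by = 0.02)
      tibble(run = sprintf("ce0.44_ci%.2f", eps_ci), layout = "random",
             k = cfg$k, stdp = FALSE, eps_ce = 0.44, eps_ci = eps_ci,
             note = "unstable-regime reconnection grid")
    },
    reduced = tibble(run = "meanfield", layout = NA_character_, k = cfg$k,
                     stdp = FALSE, eps_ce = 0.44, eps_ci = 0.22,
                     note = "analytic ring model: rates, selectivity, stability")
  )
  seeds <- derive_seeds(seed, nrow(plan))
  steps <- cfg$t_total / cfg$dt * length(cfg$angles) * (cfg$n_e + cfg$n_i) * nrow(plan)
  inform(sprintf(
    "preset '%s' (%s): %d run(s), ~%.1e neuron-steps total%s",
    name, scale, nrow(plan), steps,
    if (desk) " [desk scale: directional results only]" else ""
  ))
  list(config = cfg, plan = plan, scaled = desk, seeds = seeds)
}
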