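#' Feed-forward input current
#'
#' Constant (in time) layer 4 drive to every neuron for a grating of
#' orientation `theta_stim_deg`:
#' `I = g_AL * K_AL * fr_L * (1 + 2 rho_A cos(2 (theta_stim - theta_i)))`,
#' with the layer 4 rate converted to spikes/ms so the result is in nA.
#'
#' @param layout An `orientation_layout` tibble (needs `theta_deg`).
#' @param theta_stim_deg Stimulus orientation (degrees).
#' @param params A `balnet_config` list.
#' @return Numeric vector of currents (nA), one per layout row.
#' @export
feedforward_current <- function(layout, theta_stim_deg, params = default_params()) {
  if (params$rho_e > 0.5 || params$rho_i > 0.5) {
    abort("input modulation rho must be <= 0.5 to keep the drive nonnegative")
  }
  g_al <- ifelse(layout$population == "E", params$g_el, params$g_il)
  rho <- ifelse(layout$population == "E", params$rho_e, params$rho_i)
  d <- (theta_stim_deg - layout$theta_deg) * pi / 180
  g_al * params$k_al * (params$fr_l / 1000) * (1 + 2 * rho * cos(2 * d))
}

#' Background current
#'
#' The unmodulated drive from other cortical areas: `sqrt(K) * I_back_A`,
#' representing K excitatory inputs whose strength scales as 1/sqrt(K).
#'
#' @param params A `balnet_config` list.
#' @return Named numeric vector `c(E = ..., I = ...)` in nA.
#' @export
background_current <- function(params = default_params()) {
  c(E = sqrt(params$k) * params$i_back_e,
    I = sqrt(params$k) * params$i_back_i)
}

#' Simulate one stimulus condition
#'
#' Integrates the network for `t_total` ms at a single stimulus orientation
#' with forward Euler (step `params$dt`), optionally with STDP switched on for
#' the first `t_plastic` ms, and optionally probing the input decomposition of
#' one neuron or accumulating time-averaged input components for every neuron.
#'
#' @param graph A `connectivity_graph`.
#' @param layout The matching `orientation_layout`.
#' @param theta_stim_deg Stimulus orientation (degrees).
#' @param params A `balnet_config` list.
#' @param t_total Run length in ms (default `params$t_total`).
#' @param seed Integer seed (initial membrane potentials).
#' @param stdp Apply the plasticity rule to excitatory-presynaptic weights?
#' @param t_plastic Plasticity window in ms (default: the whole run).
#' @param probe Optional `list(population =, neuron =)` naming one neuron
#'   whose input components are recorded each `probe_every` steps.
#' @param probe_every Probe subsampling (steps).
#' @param avg_input Record time-averaged excitatory/inhibitory input
#'   components for every neuron (averaged after `t_transient`)?
#' @param t_transient Start of the averaging window for `avg_input` (ms).
#' @param v_init Optional initial membrane potentials (layout row order).
#' @return A list of class `sim_result`: `spikes` (tibble `population`,
#'   `neuron`, `time_ms`), `graph` (with final weights; identical to the input
#'   graph unless `stdp`), `v` (final membrane potentials in layout row
#'   order), and when requested `probe` (tibble with `time_ms`, `exc_mv`,
#'   `inh_mv`, `net_mv`) and `inputs` (per-neuron tibble with `exc_mv`,
#'   `inh_mv`, `net_mv` time averages).
#' @export
simulate_trial <- function(graph, layout, theta_stim_deg,
                           params = default_params(), t_total = NULL,
                           seed = NULL, stdp = FALSE, t_plastic = NULL,
                           probe = NULL, probe_every = 1L,
                           avg_input = FALSE, t_transient = NULL,
                           v_init = NULL) {
  n_e <- attr(graph, "n_e"); n_i <- attr(graph, "n_i")
  stopifnot(nrow(layout) == n_e + n_i)
  t_total <- t_total %||% params$t_total
  t_transient <- t_transient %||% params$t_transient
  if (params$dt > 0.05 + 1e-12) {
    warn("dt above the 0.05 ms default; accuracy is not guaranteed")
  }
  csr <- as_csr(graph)
  i_ff <- feedforward_current(layout, theta_stim_deg, params)
  i_back <- background_current(params)[layout$population]
  sqk <- sqrt(params$k)
  n_steps <- as.integer(round(t_total / params$dt))
  plastic_steps <- if (stdp) {
    as.integer(round((t_plastic %||% t_total) / params$dt))
  } else 0L
  probe_idx <- -1L
  if (!is.null(probe)) {
    row <- which(layout$population == probe$population & layout$neuron == probe$neuron)
    if (length(row) != 1) abort("probe does not name a simulated neuron")
    probe_idx <- as.integer(row - 1L)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- lif_run_cpp(
    n_e, n_i, csr$ptr, csr$post, csr$w, i_ff, i_back,
    params$tau, params$r_m, params$v_t, params$v_reset,
    params$tau_syn_e, params$tau_syn_i,
    params$g_ee / sqk, params$g_ei / sqk, params$g_ie / sqk, params$g_ii / sqk,
    params$dt, n_steps,
    stdp, params$a_plus, params$a_minus, params$tau_plus, params$tau_minus,
    2, plastic_steps,
    probe_idx, as.integer(probe_every),
    avg_input, as.integer(round(t_transient / params$dt)),
    v_init
  )
  pop <- ifelse(res$spike_id <= n_e, "E", "I")
  spikes <- tibble(
    population = pop,
    neuron = as.integer(res$spike_id - ifelse(pop == "I", n_e, 0L)),
    time_ms = res$spike_t
  )
  out <- list(
    spikes = spikes,
    graph = if (stdp) set_weights(graph, csr, res$w) else graph,
    v = res$v
  )
  if (probe_idx >= 0) {
    out$probe <- tibble(
      time_ms = res$probe_t,
      exc_mv = params$r_m * res$probe_exc,
      inh_mv = params$r_m * res$probe_inh
    ) %>% mutate(net_mv = .data$exc_mv + .data$inh_mv)
  }
  if (avg_input && !is.null(res$avg_exc)) {
    out$inputs <- tibble(
      population = layout$population,
      neuron = layout$neuron,
      exc_mv = params$r_m * res$avg_exc,
      inh_mv = params$r_m * res$avg_inh
    ) %>% mutate(net_mv = .data$exc_mv + .data$inh_mv)
  }
  structure(out, class = "sim_result")
}

#' Run the full stimulus protocol
#'
#' One independent run per stimulus orientation (default 9 angles, 0 to 160
#' degrees in steps of 20), with per-run seeds derived deterministically from
#' the master seed. Weights are held fixed.
#'
#' @param graph A `connectivity_graph`.
#' @param layout The matching `orientation_layout`.
#' @param params A `balnet_config` list.
#' @param angles Stimulus orientations in degrees.
#' @param t_total,t_transient Run length and discarded initial window (ms).
#' @param seed Master seed.
#' @return A tibble of class `spike_data` with columns `angle_deg`,
#'   `population`, `neuron`, `time_ms` and a logical `transient` flag;
#'   attributes `n_e`, `n_i`, `t_total`, `t_transient`, `config_digest`.
#' @export
run_protocol <- function(graph, layout, params = default_params(),
                         angles = params$angles, t_total = NULL,
                         t_transient = NULL, seed = 1L) {
  t_total <- t_total %||% params$t_total
  t_transient <- t_transient %||% params$t_transient
  stopifnot(t_transient < t_total)
  seeds <- derive_seeds(seed, length(angles))
  runs <- lapply(seq_along(angles), function(i) {
    tr <- simulate_trial(graph, layout, angles[i], params,
                         t_total = t_total, seed = seeds[i])
    mutate(tr$spikes, angle_deg = angles[i], .before = 1)
  })
  out <- bind_rows(runs) %>% mutate(transient = .data$time_ms <= t_transient)
  structure(out,
            n_e = attr(graph, "n_e"), n_i = attr(graph, "n_i"),
            t_total = t_total, t_transient = t_transient,
            angles = angles, config_digest = config_digest(params),
            class = c("spike_data", class(tibble())))
}

#' Train the network with STDP at a single orientation
#'
#' Runs the network at the training orientation with the multiplicative STDP
#' rule active for `t_plastic` ms (the plastic phase of the protocol: the
#' published runs use the first 2/3 of a 20 s simulation, i.e. 13.33 s), then
#' returns the graph with the final weights frozen. Tuning is measured
#' afterwards with [run_protocol()] on the returned graph.
#'
#' @param graph A `connectivity_graph` (weights at 1 for a naive network).
#' @param layout The matching `orientation_layout`.
#' @param params A `balnet_config` list (STDP constants `a_plus`, `a_minus`,
#'   `tau_plus`, `tau_minus` are taken from here).
#' @param theta_train_deg The single training orientation (degrees).
#' @param t_plastic Duration of the plastic phase (ms).
#' @param seed Integer seed.
#' @return The `connectivity_graph` with updated excitatory-presynaptic
#'   weights; the training spikes are attached as attribute
#'   `training_spikes`.
#' @export
apply_plasticity <- function(graph, layout, params = default_params(),
                             theta_train_deg = 0, t_plastic = 40000 / 3,
                             seed = 1L) {
  tr <- simulate_trial(graph, layout, theta_train_deg, params,
                       t_total = t_plastic, seed = seed,
                       stdp = TRUE, t_plastic = t_plastic)
  g <- tr$graph
  attr(g, "training_spikes") <- tr$spikes
  attr(g, "theta_train_deg") <- theta_train_deg
  g
}

#' Excitatory/inhibitory input decomposition of one neuron
#'
#' Records the time course of the excitatory input component
#' (`R_m * (I_L4 + I_rec,E + I_back)`), the inhibitory component
#' (`R_m * I_rec,I`) and their sum for a single probed neuron. In the balanced
#' state the two components are each several times the 30 mV threshold and
#' grow as sqrt(K), while their sum stays of the order of the threshold.
#'
#' @param graph,layout Network and layout.
#' @param population,neuron The probed neuron.
#' @param theta_stim_deg Stimulus orientation (degrees).
#' @param params A `balnet_config` list.
#' @param t_total Run length (ms).
#' @param seed Integer seed.
#' @param probe_every Record every this many steps.
#' @return Tibble with `time_ms`, `exc_mv`, `inh_mv`, `net_mv`.
#' @export
input_decomposition <- function(graph, layout, population = "E", neuron = 1L,
                                theta_stim_deg = 0, params = default_params(),
                                t_total = 1000, seed = 1L, probe_every = 10L) {
  tr <- simulate_trial(graph, layout, theta_stim_deg, params,
                       t_total = t_total, seed = seed,
                       probe = list(population = population, neuron = neuron),
                       probe_every = probe_every)
  tr$probe
}
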