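# small two-population network fixtures are built by hand so single-neuron
# and single-synapse behaviour can be checked against closed forms

quiet_params <- function() {
  p <- default_params()
  p$g_ee <- 0; p$g_ei <- 0; p$g_ie <- 0; p$g_ii <- 0
  p$i_back_e <- 0; p$i_back_i <- 0
  p$rho_e <- 0; p$rho_i <- 0
  p
}

test_that("feed-forward current matches the closed form", {
  p <- default_params()
  lay <- assign_orientations(build_geometry(4, 4), "random", seed = 1)
  lay$theta_deg <- c(30, 0, 90, 120, 30, 0, 90, 120)
  i_ff <- feedforward_current(lay, 30, p)
  # aligned neuron, defaults: 1.65 * 250 * 0.015 * 1.12 = 6.93 nA
  expect_equal(i_ff[1], 6.93, tolerance = 1e-12)
  expect_equal(i_ff[5], 6.93, tolerance = 1e-12)
  # orthogonal neuron (120 deg vs stimulus 30): factor 0.88
  expect_equal(i_ff[4], 1.65 * 250 * 0.015 * 0.88, tolerance = 1e-12)
  # rho = 0: identical for all neurons at any stimulus
  p0 <- p; p0$rho_e <- 0; p0$rho_i <- 0
  expect_equal(diff(range(feedforward_current(lay, 77, p0))), 0)
  # the cosine averages out exactly over the 9-angle protocol
  avg <- rowMeans(sapply(seq(0, 160, by = 20), feedforward_current, layout = lay, params = p))
  expect_equal(avg, rep(1.65 * 250 * 0.015, 8), tolerance = 1e-12)
  # modulation above 0.5 rejected
  pbad <- p; pbad$rho_e <- 0.6
  expect_error(feedforward_current(lay, 0, pbad), "rho")
})

test_that("background current scales as sqrt(K)", {
  p <- default_params()
  expect_equal(unname(background_current(p)["E"]), sqrt(500) * 0.12, tolerance = 1e-12)
  p$k <- 500; p$i_back_e <- 0.12
  b1 <- background_current(p)
  p$k <- 2000
  expect_equal(unname(background_current(p)["E"] / b1["E"]), 2, tolerance = 1e-12)
  p$k <- 0
  expect_equal(unname(background_current(p)["E"]), 0)
})

test_that("one Euler step follows the update rule exactly", {
  p <- quiet_params()
  # drive R_m * I = 60 mV on every neuron
  p$k_al <- 1; p$fr_l <- 1000; p$g_el <- 60 / p$r_m; p$g_il <- 60 / p$r_m
  lay <- assign_orientations(build_geometry(4, 4), "random", seed = 1)
  geom <- build_geometry(4, 4)
  g <- make_manual_graph(geom, tibble::tibble(
    post_pop = character(), post = integer(), pre_pop = character(),
    pre = integer(), w = numeric()))
  tr <- simulate_trial(g, lay, 0, p, t_total = p$dt, v_init = rep(0, 8))
  # V' = 0 + (0.05/20) * (-0 + 60) = 0.15 mV
  expect_equal(tr$v, rep(0.15, 8), tolerance = 1e-12)
})

test_that("threshold crossing emits a spike and resets within the step", {
  p <- quiet_params()
  p$k_al <- 1; p$fr_l <- 1000; p$g_el <- 60 / p$r_m; p$g_il <- 60 / p$r_m
  lay <- assign_orientations(build_geometry(4, 4), "random", seed = 1)
  g <- make_manual_graph(build_geometry(4, 4), tibble::tibble(
    post_pop = character(), post = integer(), pre_pop = character(),
    pre = integer(), w = numeric()))
  tr <- simulate_trial(g, lay, 0, p, t_total = p$dt,
                       v_init = c(29.9999, rep(0, 7)))
  expect_equal(nrow(tr$spikes), 1)
  expect_equal(tr$spikes$population, "E")
  expect_equal(tr$spikes$neuron, 1L)
  expect_equal(tr$spikes$time_ms, 0.05)
  expect_equal(tr$v[1], 0)
})

test_that("a single synapse produces the exponential kernel of the spike sum", {
  p <- quiet_params()
  p$k <- 400  # per-synapse efficacy g_EE / sqrt(K) = 1.6 nA ms
  p$g_ee <- 32
  p$rho_e <- 0.5; p$rho_i <- 0.5
  p$k_al <- 1; p$fr_l <- 1000
  # drive only neuron E1 (aligned at rho = 0.5 doubles; orthogonal cancels)
  p$g_el <- (31 / p$r_m) / 2; p$g_il <- 0
  lay <- assign_orientations(build_geometry(4, 4), "random", seed = 1)
  lay$theta_deg <- c(0, rep(90, 7))
  g <- make_manual_graph(build_geometry(4, 4), tibble::tibble(
    post_pop = "E", post = 2L, pre_pop = "E", pre = 1L, w = 1))
  tr <- simulate_trial(g, lay, 0, p, t_total = 30,
                       v_init = c(29.9, rep(0, 7)),
                       probe = list(population = "E", neuron = 2L))
  t_spike <- tr$spikes$time_ms[tr$spikes$neuron == 1][1]
  expect_false(is.na(t_spike))
  probe <- dplyr::filter(tr$probe, time_ms > t_spike)
  g_syn <- 32 / sqrt(400)
  # discrete scheme: one-step (dt) transmission latency on the kernel
  want <- p$r_m * g_syn / p$tau_syn_e *
    exp(-(probe$time_ms - t_spike + p$dt) / p$tau_syn_e)
  expect_equal(probe$exc_mv, want, tolerance = 1e-9)
  expect_equal(probe$inh_mv, rep(0, nrow(probe)))
})

test_that("a quiet subthreshold network never spikes", {
  p <- quiet_params()
  p$k_al <- 1; p$fr_l <- 1000; p$g_el <- 20 / p$r_m; p$g_il <- 20 / p$r_m
  lay <- assign_orientations(build_geometry(16, 4), "random", seed = 2)
  g <- make_manual_graph(build_geometry(16, 4), tibble::tibble(
    post_pop = character(), post = integer(), pre_pop = character(),
    pre = integer(), w = numeric()))
  tr <- simulate_trial(g, lay, 0, p, t_total = 500, seed = 3)
  expect_equal(nrow(tr$spikes), 0)
})

test_that("identical seeds give identical rasters; spike times are valid", {
  p <- scale_connectivity(default_params(), 30)
  p$n_e <- 400; p$n_i <- 100
  lay <- assign_orientations(build_geometry(400, 100), "random", seed = 10)
  g <- sample_connectivity(lay, k = 30, sigma = 0.25, seed = 11)
  s1 <- run_protocol(g, lay, p, angles = c(0, 60, 120), t_total = 600,
                     t_transient = 100, seed = 12)
  s2 <- run_protocol(g, lay, p, angles = c(0, 60, 120), t_total = 600,
                     t_transient = 100, seed = 12)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(s1$time_ms > 0 & s1$time_ms <= 600))
  by_neuron <- dplyr::group_by(s1, angle_deg, population, neuron)
  expect_true(all(dplyr::summarise(by_neuron,
    ok = !is.unsorted(time_ms, strictly = TRUE), .groups = "drop")$ok))
})

test_that("halving the time step leaves population rates nearly unchanged", {
  p <- scale_connectivity(default_params(), 30)
  p$n_e <- 400; p$n_i <- 100
  lay <- assign_orientations(build_geometry(400, 100), "random", seed = 14)
  g <- sample_connectivity(lay, k = 30, sigma = 0.25, seed = 15)
  rate_at_dt <- function(dt) {
    p$dt <- dt
    tr <- simulate_trial(g, lay, 0, p, t_total = 20000, seed = 16)
    sp <- dplyr::filter(tr$spikes, time_ms > 100)
    c(E = sum(sp$population == "E") / 400 / 19.9, I = sum(sp$population == "I") / 100 / 19.9)
  }
  r1 <- rate_at_dt(0.05)
  r2 <- rate_at_dt(0.025)
  expect_lt(max(abs(r2 / r1 - 1)), 0.05)
})

test_that("input probes require a simulated neuron", {
  p <- quiet_params()
  lay <- assign_orientations(build_geometry(4, 4), "random", seed = 1)
  g <- make_manual_graph(build_geometry(4, 4), tibble::tibble(
    post_pop = character(), post = integer(), pre_pop = character(),
    pre = integer(), w = numeric()))
  expect_error(
    simulate_trial(g, lay, 0, p, t_total = 1,
                   probe = list(population = "E", neuron = 99L)),
    "probe")
})
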