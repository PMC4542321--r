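# Shared simulation experiments, computed once per test run and reused by
# several test files (the caches live in this helper's environment).
#
# Desk scale: N_E = 1600, N_I = 400, K = 100 (feed-forward scaled with K),
# 9 x 5 s measurement runs, 3 connectivity/layout seeds. Directional claims
# only.
#
# Full scale: the default network (N_E = 8100, N_I = 2025, K = 500) with a
# 9 x 20 s baseline (the published preferred-orientation protocol) and
# 9 x 6.67 s post-reconnection measurements (the published post-reconnection
# window).

.desk_cache <- new.env(parent = emptyenv())
.full_cache <- new.env(parent = emptyenv())

desk_params <- function() {
  p <- scale_connectivity(default_params(), 100)
  p$n_e <- 1600L
  p$n_i <- 400L
  p
}

desk_experiments <- function() {
  if (!exists("res", envir = .desk_cache)) {
    p <- desk_params()
    geom <- build_geometry(p$n_e, p$n_i)
    rows <- list()
    for (seed in 1:3) {
      for (mode in c("random", "map")) {
        lay <- assign_orientations(geom, mode, seed = 100 * seed)
        g <- sample_connectivity(lay, k = p$k, sigma = p$sigma,
                                 seed = 100 * seed + 1)
        before <- run_protocol(g, lay, p, t_total = 5000, t_transient = 100,
                               seed = 100 * seed + 2)
        tun_b <- compute_tuning(firing_rates(before))
        gt <- apply_plasticity(g, lay, p, theta_train_deg = 0,
                               t_plastic = 40000 / 3, seed = 100 * seed + 3)
        after <- run_protocol(gt, lay, p, t_total = 5000, t_transient = 100,
                              seed = 100 * seed + 4)
        tun_a <- compute_tuning(firing_rates(after))
        sb <- population_summary(tun_b)
        sa <- population_summary(tun_a)
        rows[[length(rows) + 1]] <- tibble::tibble(
          seed = seed, layout = mode,
          osi_e_before = sb$mean_osi[sb$population == "E"],
          osi_e_after = sa$mean_osi[sa$population == "E"],
          w_ee_after = mean(gt$w[gt$post_pop == "E" & gt$pre_pop == "E"])
        )
      }
    }
    assign("res", dplyr::bind_rows(rows), envir = .desk_cache)
  }
  get("res", envir = .desk_cache)
}

full_experiment <- function() {
  if (!exists("res", envir = .full_cache)) {
    p <- default_params()
    lay <- assign_orientations(build_geometry(p$n_e, p$n_i), "random", seed = 11)
    th_e <- lay$theta_deg[lay$population == "E"]
    g <- sample_connectivity(lay, k = p$k, sigma = p$sigma, seed = 12)
    baseline <- run_protocol(g, lay, p, t_total = 20000, t_transient = 100,
                             seed = 13)
    tun <- compute_tuning(firing_rates(baseline))
    e_base <- dplyr::filter(tun, population == "E")
    grid <- lapply(c(0, 0.22, 0.44), function(eps_ce) {
      gr <- suppressWarnings(  # inhibitory-block probabilities clamp at K = 500
        reconnect_graph(g, tun, eps_ce = eps_ce, eps_ci = 0.22, seed = 20))
      spr <- run_protocol(gr, lay, p, t_total = 6667, t_transient = 100,
                          seed = 21)
      tun_r <- compute_tuning(firing_rates(spr))
      e_r <- dplyr::filter(tun_r, population == "E")
      tibble::tibble(
        eps_ce = eps_ce,
        osi_e = mean(e_r$osi, na.rm = TRUE),
        osi_i = mean(dplyr::filter(tun_r, population == "I")$osi, na.rm = TRUE),
        po_conservation = circular_correlation(e_base$po_deg, e_r$po_deg),
        rate_e = mean(e_r$mean_rate)
      )
    })
    assign("res", list(
      tuning = tun,
      osi_e_baseline = mean(e_base$osi, na.rm = TRUE),
      rate_e_baseline = mean(e_base$mean_rate),
      corr_po_theta = circular_correlation(e_base$po_deg, th_e),
      grid = dplyr::bind_rows(grid)
    ), envir = .full_cache)
  }
  get("res", envir = .full_cache)
}
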