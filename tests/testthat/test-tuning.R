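angles9 <- seq(0, 160, by = 20)

test_that("firing rates are count over half-open window", {
  set.seed(1)
  df <- data.frame(angle_deg = 0, population = "E", neuron = 1L,
                   time_ms = sort(runif(30, 100, 20000)))
  sp <- make_spike_data(df, n_e = 4, n_i = 1, t_total = 20000, t_transient = 100)
  r <- firing_rates(sp)
  expect_equal(r$rate_hz[r$neuron == 1 & r$population == "E"], 30 / 19.9)
  # silent neurons appear with rate 0
  expect_equal(r$rate_hz[r$neuron == 2 & r$population == "E"], 0)
  expect_equal(nrow(r), 5)
  # half-open window: a spike exactly at the start counts, at the end does not
  sp2 <- make_spike_data(
    data.frame(angle_deg = 0, population = "E", neuron = 1L, time_ms = c(100, 200)),
    n_e = 1, n_i = 1, t_total = 20000, t_transient = 0)
  expect_equal(firing_rates(sp2, window = c(100, 200))$rate_hz[1], 1 / 100 * 1000)
  expect_equal(firing_rates(sp2, window = c(100, 200 + 1e-9))$rate_hz[1],
               2 / (100 + 1e-9) * 1000)
  expect_error(firing_rates(sp2, window = c(200, 200)), "window")
})

test_that("OSI and PO recover planted cosine tuning exactly on the 9-angle grid", {
  f <- 1 + 0.6 * cos(2 * (angles9 - 40) * pi / 180)
  expect_equal(osi(f, angles9), 0.3, tolerance = 1e-12)
  expect_equal(preferred_orientation(f, angles9), 40, tolerance = 1e-10)
  # flat curve and delta curve
  expect_equal(osi(rep(2.5, 9), angles9), 0, tolerance = 1e-12)
  delta <- c(0, 0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(osi(delta, angles9), 1, tolerance = 1e-12)
  expect_equal(preferred_orientation(delta, angles9), 60)
  # symmetric about 0 gives PO 0
  sym <- 1 + 0.4 * cos(2 * angles9 * pi / 180)
  expect_equal(preferred_orientation(sym, angles9), 0, tolerance = 1e-10)
  # adding a constant leaves PO unchanged, scaling leaves OSI unchanged
  expect_equal(preferred_orientation(f + 3, angles9),
               preferred_orientation(f, angles9), tolerance = 1e-10)
  expect_equal(osi(7 * f, angles9), osi(f, angles9), tolerance = 1e-12)
  # all-zero curve is undefined
  expect_true(is.na(osi(rep(0, 9), angles9)))
  expect_true(is.na(preferred_orientation(rep(0, 9), angles9)))
})

test_that("OSI and PO agree with an independent complex-vector oracle", {
  set.seed(2)
  for (i in 1:1000) {
    f <- stats::rgamma(9, shape = 2, rate = 0.5)
    want <- oracle_osi_po(f, angles9)
    expect_equal(osi(f, angles9), want$osi, tolerance = 1e-12)
    expect_equal(preferred_orientation(f, angles9), want$po, tolerance = 1e-10)
  }
})

test_that("compute_tuning matches the scalar definitions row by row", {
  set.seed(3)
  rates <- tidyr::expand_grid(angle_deg = angles9,
                              population = c("E", "I"), neuron = 1:20) %>%
    dplyr::mutate(rate_hz = stats::rgamma(dplyr::n(), 2, 0.5))
  tun <- compute_tuning(rates)
  for (r in sample(nrow(tun), 10)) {
    f <- rates$rate_hz[rates$population == tun$population[r] &
                       rates$neuron == tun$neuron[r]]
    f <- f[order(rates$angle_deg[rates$population == tun$population[r] &
                                 rates$neuron == tun$neuron[r]])]
    expect_equal(tun$osi[r], osi(f, angles9), tolerance = 1e-12)
    expect_equal(tun$po_deg[r], preferred_orientation(f, angles9), tolerance = 1e-10)
  }
})

test_that("population summary handles silent neurons explicitly", {
  tun <- structure(tibble::tibble(
    population = "E", neuron = 1:4, mean_rate = c(2, 3, 0, 1),
    osi = c(0.5, 0.5, NA, 0.5), po_deg = c(10, 20, NA, 30)),
    class = c("tuning_result", class(tibble::tibble())))
  s <- population_summary(tun)
  expect_equal(s$mean_osi, 0.5)
  expect_equal(s$n_silent, 1L)
  s0 <- population_summary(tun, include_silent = TRUE)
  expect_equal(s0$mean_osi, 3 * 0.5 / 4)
  h <- osi_histogram(tun)
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[h$bin_lo == 0.5], 3)
})

test_that("the cosine fit recovers planted bin means exactly", {
  geom <- build_geometry(100, 4)
  mids <- seq(5, 85, by = 10)
  # one postsynaptic neuron per bin mid, PO difference exactly at the mid
  edges <- tibble::tibble(post_pop = "E", post = 1:9, pre_pop = "E",
                          pre = 11:19, w = 0.14 + 2 * 0.016 * cos(pi * mids / 90))
  g <- make_manual_graph(geom, edges)
  po <- rep(0, 104); po[11:19] <- mids
  fit <- bin_and_fit_dw(g, po, block = "EE")
  expect_equal(fit$a0, 0.14, tolerance = 1e-12)
  expect_equal(fit$a1, 0.016, tolerance = 1e-12)
  expect_equal(glance(fit)$n_bins, 9)
  expect_equal(tidy(fit)$estimate, c(0.14, 0.016), tolerance = 1e-12)
  # constant weights give zero modulation
  g2 <- make_manual_graph(geom, dplyr::mutate(edges, w = 0.7))
  fit2 <- bin_and_fit_dw(g2, po, block = "EE")
  expect_equal(fit2$a1, 0, tolerance = 1e-12)
  expect_equal(fit2$a0, 0.7, tolerance = 1e-12)
  # empty bins excluded with a warning
  g3 <- make_manual_graph(geom, edges[1:5, ])
  expect_warning(fit3 <- bin_and_fit_dw(g3, po, block = "EE"), "empty bin")
  expect_equal(nrow(fit3$bins), 5)
})

test_that("orientation helpers wrap on the half-circle", {
  expect_equal(orientation_difference(10, 170), 20)
  expect_equal(orientation_difference(0, 90), 90)
  expect_equal(orientation_difference(179, 1), 2)
  expect_equal(wrap_orientation(c(-10, 190, 360)), c(170, 10, 0))
  expect_equal(circular_correlation(c(10, 50, 120, 170), c(10, 50, 120, 170)), 1,
               tolerance = 1e-12)
  # strong correlation survives a constant rotation
  set.seed(4)
  a <- runif(500, 0, 180)
  expect_gt(circular_correlation(a, wrap_orientation(a + 30)), 0.99)
  b <- runif(500, 0, 180)
  expect_lt(abs(circular_correlation(a, b)), 0.15)
})

test_that("interspike-interval CV distinguishes regular from Poisson trains", {
  reg <- data.frame(population = "E", neuron = 1L, time_ms = seq(10, 5000, by = 50))
  expect_lt(cv_isi(tibble::as_tibble(reg))$cv_isi, 0.01)
  set.seed(5)
  pois <- data.frame(population = "E",
                     neuron = rep(1:20, each = 100),
                     time_ms = as.vector(replicate(20, sort(runif(100, 0, 2e4)))))
  expect_gt(cv_isi(tibble::as_tibble(pois))$cv_isi, 0.8)
})
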