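# Independent oracles and small fixture builders used across the suite.

# Explicit all-pairs STDP oracle: process spike events chronologically; at a
# postsynaptic spike sum exp(-(t - t_pre)/tau_plus) over ALL earlier
# presynaptic spikes; at a presynaptic spike sum exp(-(t - t_post)/tau_minus)
# over all earlier postsynaptic spikes. Multiplicative factors use the weight
# at the triggering spike; simultaneous pre/post spikes do not pair (strict
# inequalities); post-triggered updates are applied first at a tie.
oracle_stdp <- function(pre, post, w0, params, freeze = FALSE) {
  ev <- rbind(data.frame(t = post, kind = 0L), data.frame(t = pre, kind = 1L))
  ev <- ev[order(ev$t, ev$kind), ]
  w <- w0; dw <- 0
  clip <- function(x) min(max(x, 0), 2)
  for (r in seq_len(nrow(ev))) {
    t <- ev$t[r]
    if (ev$kind[r] == 0L) {
      s <- sum(exp(-(t - pre[pre < t]) / params$tau_plus))
      if (freeze) dw <- dw + params$a_plus * s * (2 - w0)
      else w <- clip(w + params$a_plus * s * (2 - w))
    } else {
      s <- sum(exp(-(t - post[post < t]) / params$tau_minus))
      if (freeze) dw <- dw + params$a_minus * s * w0
      else w <- clip(w + params$a_minus * s * w)
    }
  }
  list(w = w, dw = if (freeze) dw else w - w0)
}

# Complex-arithmetic oracle for OSI and preferred orientation
oracle_osi_po <- function(rates, angles_deg) {
  z <- sum(rates * exp(2i * angles_deg * pi / 180))
  f <- sum(rates)
  list(osi = Mod(z) / f, po = (Arg(z) / 2 * 180 / pi) %% 180)
}

# Homogeneous Poisson spike train on [0, t_ms)
poisson_train <- function(rate_hz, t_ms) {
  sort(runif(stats::rpois(1, rate_hz / 1000 * t_ms), 0, t_ms))
}

# Assemble a spike_data tibble from a data frame of spikes (used to test the
# analysis path without running the simulator)
make_spike_data <- function(df, n_e, n_i, t_total, t_transient = 0,
                            angles = sort(unique(df$angle_deg))) {
  structure(tibble::as_tibble(df),
            n_e = n_e, n_i = n_i, t_total = t_total,
            t_transient = t_transient, angles = angles,
            class = c("spike_data", class(tibble::tibble())))
}

# Hand-built connectivity graph over an existing geometry
make_manual_graph <- function(geom, edges, k = 1, sigma = 0.2) {
  structure(tibble::as_tibble(edges),
            geometry = geom, m = attr(geom, "m"), k = k, sigma = sigma,
            k_max = 5L, n_e = attr(geom, "n_e"), n_i = attr(geom, "n_i"),
            n_clamped = 0L, eps_ce = 0, eps_ci = 0, seed = NA_integer_,
            class = c("connectivity_graph", class(tibble::tibble())))
}

# Dense-grid solve of the balance condition on the ring: discretize the
# convolution on `grid` points and solve the 2*grid linear system
# J * nu + I = 0. Band-limited profiles make the system rank-deficient (modes
# the interaction cannot see are unconstrained at leading order); the
# mean-field solution is the minimum-norm one, so use the pseudo-inverse.
oracle_dense_balance <- function(spec, grid = 512L, theta0_deg = 0) {
  theta <- (seq_len(grid) - 0.5) / grid
  offsets <- (0:(grid - 1)) / grid   # theta_i - theta_j on the midpoint grid
  prof <- function(pop) {
    if (!is.null(spec$profile[[pop]])) spec$profile[[pop]](offsets)
    else 1 + spec$eps[[pop]] * cos(2 * pi * offsets)
  }
  circ <- function(vals) {
    idx <- outer(seq_len(grid), seq_len(grid), function(i, j) ((i - j) %% grid) + 1L)
    matrix(vals[idx], grid, grid) / grid
  }
  ce <- circ(prof("e")); ci <- circ(prof("i"))
  g <- spec$g
  big <- rbind(
    cbind(g[["ee"]] * ce, -g[["ei"]] * ci),
    cbind(g[["ie"]] * ce, -g[["ii"]] * ci)
  )
  i_ext <- c(spec$i_ext[["e"]] * (1 + 2 * spec$rho * cos(2 * pi * (theta - theta0_deg / 180))),
             spec$i_ext[["i"]] * (1 + 2 * spec$rho * cos(2 * pi * (theta - theta0_deg / 180))))
  nu <- as.vector(MASS::ginv(big) %*% (-i_ext))
  list(
    theta = theta,
    nu_e = nu[seq_len(grid)],
    nu_i = nu[grid + seq_len(grid)],
    mode = function(v, n) sum(v * exp(-2i * pi * n * theta)) / grid
  )
}
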