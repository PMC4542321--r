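#' Specify a reduced ring model
#'
#' The one-dimensional mean-field counterpart of the layer 2/3 network: two
#' populations of neurons parameterized by the preferred orientation of their
#' feed-forward input, mapped to the ring coordinate `theta in (0, 1\]`
#' (orientation / 180 degrees). Connection probability from population B
#' depends only on the ring distance through the normalized profile
#' `C_B(theta) = 1 + eps_cB cos(2 pi theta)` (`eps_cB = 0` is the
#' salt-and-pepper case: a flat profile in orientation space).
#'
#' Couplings are stored as magnitudes; signed values (inhibitory couplings
#' negative, as in the network defaults) are converted on construction --
#' the excitatory/inhibitory sign structure is applied inside the balance
#' equations.
#'
#' @param g_ee,g_ei,g_ie,g_ii Coupling magnitudes (signs ignored).
#' @param i_ext_e,i_ext_i External input scale per population (the balanced
#'   rates are proportional to these; only ratios matter).
#' @param rho Feed-forward modulation (input OSI), in \[0, 0.5\].
#' @param eps_ce,eps_ci Connectivity modulations of the excitatory and
#'   inhibitory presynaptic profiles, in \[0, 1\].
#' @param n_max Number of Fourier modes retained (all profiles here have
#'   support on modes 0 and 1 only).
#' @param profile_e,profile_i Optional custom normalized profile functions on
#'   (0, 1\] (must integrate to 1); override the cosine profiles.
#' @return A list of class `reduced_model_spec`.
#' @export
reduced_model_spec <- function(g_ee = 32, g_ei = 96, g_ie = 96, g_ii = 128,
                               i_ext_e = 1, i_ext_i = 1, rho = 0.06,
                               eps_ce = 0, eps_ci = 0, n_max = 8,
                               profile_e = NULL, profile_i = NULL) {
  stopifnot(rho >= 0, rho <= 0.5, eps_ce >= 0, eps_ce <= 1,
            eps_ci >= 0, eps_ci <= 1, n_max >= 1)
  structure(list(
    g = c(ee = abs(g_ee), ei = abs(g_ei), ie = abs(g_ie), ii = abs(g_ii)),
    i_ext = c(e = i_ext_e, i = i_ext_i),
    rho = rho, eps = c(e = eps_ce, i = eps_ci), n_max = as.integer(n_max),
    profile = list(e = profile_e, i = profile_i)
  ), class = "reduced_model_spec")
}

# internal: Fourier coefficients of a presynaptic profile, n = 0..n_max.
# Cosine profiles in closed form; custom profiles by quadrature, with the
# normalization (C~(0) = 1) enforced.
profile_fourier <- function(spec, pop, n_max) {
  fn <- spec$profile[[pop]]
  if (is.null(fn)) {
    eps <- spec$eps[[pop]]
    c(1, eps / 2, rep(0, n_max - 1))[seq_len(n_max + 1)]
  } else {
    grid <- 1024L
    theta <- (seq_len(grid) - 0.5) / grid
    vals <- fn(theta)
    if (any(vals < -1e-12)) abort("profile must be nonnegative")
    ctil <- vapply(0:n_max, function(n) {
      sum(vals * exp(-2i * pi * n * theta)) / grid
    }, complex(1))
    if (abs(ctil[1] - 1) > 1e-6) {
      abort("profile is not normalized: its integral over (0, 1] must be 1")
    }
    ctil
  }
}

#' Fourier components of the ring interactions
#'
#' `J~_AB(n) = G_AB * C~_B(n)` for modes `n = 0..n_max`: the interaction a
#' postsynaptic population A receives from B, in the orientation-coordinate
#' Fourier basis. For the cosine profile `1 + eps_cB cos(2 pi theta)` this is
#' `G_AB` at mode 0, `G_AB * eps_cB / 2` at mode 1 and 0 beyond.
#'
#' @param spec A `reduced_model_spec`.
#' @param n_max Number of modes (defaults to the spec's).
#' @return A tibble with columns `n`, `j_ee`, `j_ei`, `j_ie`, `j_ii`
#'   (complex in general, real for the built-in profiles).
#' @export
fourier_interactions <- function(spec, n_max = spec$n_max) {
  ce <- profile_fourier(spec, "e", n_max)
  ci <- profile_fourier(spec, "i", n_max)
  tb <- tibble(
    n = 0:n_max,
    j_ee = spec$g[["ee"]] * ce, j_ei = spec$g[["ei"]] * ci,
    j_ie = spec$g[["ie"]] * ce, j_ii = spec$g[["ii"]] * ci
  )
  if (all(abs(Im(c(tb$j_ee, tb$j_ei, tb$j_ie, tb$j_ii))) < 1e-14)) {
    tb <- mutate(tb, across(c("j_ee", "j_ei", "j_ie", "j_ii"), Re))
  }
  tb
}

# internal: external-input Fourier modes (theta0 = stimulus position on the
# ring in degrees of orientation)
input_fourier <- function(spec, n_max, theta0_deg = 0) {
  phase <- exp(-2i * pi * (theta0_deg / 180))
  sapply(c("e", "i"), function(p) {
    v <- complex(n_max + 1)
    v[1] <- spec$i_ext[[p]]
    if (n_max >= 1) v[2] <- spec$rho * spec$i_ext[[p]] * phase
    v
  })
}

# internal: Eq-25-style feasibility of a positive-rate balanced state
check_feasibility <- function(jf, spec) {
  r_input <- spec$i_ext[["e"]] / spec$i_ext[["i"]]
  r_inh <- Re(jf$j_ei[1]) / Re(jf$j_ii[1])
  r_exc <- Re(jf$j_ee[1]) / Re(jf$j_ie[1])
  list(ok = r_input > r_inh && r_inh > r_exc,
       input_ratio = r_input, inh_ratio = r_inh, exc_ratio = r_exc)
}

#' Balanced-state rates of the ring model
#'
#' Solves the mode-wise 2x2 linear balance system: in the large-K limit the
#' net input must vanish at leading order, which fixes every Fourier mode of
#' the population rates in terms of the interaction and input modes. Rates are
#' in units of `I_ext / G` (only ratios are physical).
#'
#' @param spec A `reduced_model_spec`.
#' @param theta0_deg Stimulus orientation (degrees).
#' @param grid Number of ring positions for the reconstructed rate profiles.
#' @return A list of class `balanced_solution`: `modes` (tibble `n`, `nu_e`,
#'   `nu_i`, complex), `rates` (tibble `theta`, `theta_deg`, `nu_e`, `nu_i`),
#'   `selectivity` (tibble with per-population `nu(1)/nu(0)` magnitudes),
#'   and the `spec`.
#' @export
balanced_rates <- function(spec, theta0_deg = 0, grid = 180L) {
  n_max <- spec$n_max
  jf <- fourier_interactions(spec, n_max)
  feas <- check_feasibility(jf, spec)
  if (!feas$ok) {
    abort(sprintf(paste0(
      "no positive balanced state: need I_ext,E/I_ext,I > J_EI(0)/J_II(0) > ",
      "J_EE(0)/J_IE(0); got %.4g, %.4g, %.4g"),
      feas$input_ratio, feas$inh_ratio, feas$exc_ratio))
  }
  itil <- input_fourier(spec, n_max, theta0_deg)
  nu_e <- complex(n_max + 1); nu_i <- complex(n_max + 1)
  for (n in 0:n_max) {
    r <- n + 1
    jm <- c(ee = jf$j_ee[r], ei = jf$j_ei[r], ie = jf$j_ie[r], ii = jf$j_ii[r])
    ie_n <- itil[r, "e"]; ii_n <- itil[r, "i"]
    if (all(abs(jm) < 1e-14)) {
      if (abs(ie_n) > 1e-14 || abs(ii_n) > 1e-14) {
        abort(sprintf(paste0(
          "mode %d is singular: the interaction has no component at this mode ",
          "but the input does (the salt-and-pepper divergence; selectivity is ",
          "then controlled by connectivity fluctuations, not by the mean-field ",
          "balance)"), n))
      }
      next
    }
    denom <- jm[["ie"]] * jm[["ei"]] - jm[["ee"]] * jm[["ii"]]
    if (abs(denom) < 1e-14) {
      abort(sprintf("mode %d: singular balance matrix", n))
    }
    nu_e[r] <- (jm[["ii"]] * ie_n - jm[["ei"]] * ii_n) / denom
    nu_i[r] <- (jm[["ie"]] * ie_n - jm[["ee"]] * ii_n) / denom
  }
  if (Re(nu_e[1]) <= 0 || Re(nu_i[1]) <= 0) {
    abort("balance equations give non-positive mean rates")
  }
  theta <- (seq_len(grid) - 0.5) / grid
  recon <- function(nu) {
    out <- rep(Re(nu[1]), grid)
    for (n in seq_len(n_max)) {
      out <- out + 2 * Re(nu[n + 1] * exp(2i * pi * n * theta))
    }
    out
  }
  structure(list(
    modes = tibble(n = 0:n_max, nu_e = nu_e, nu_i = nu_i),
    rates = tibble(theta = theta, theta_deg = theta * 180,
                   nu_e = recon(nu_e), nu_i = recon(nu_i)),
    selectivity = tibble(
      population = c("E", "I"),
      ratio = c(Mod(nu_e[2]) / Re(nu_e[1]), Mod(nu_i[2]) / Re(nu_i[1]))
    ),
    spec = spec
  ), class = "balanced_solution")
}

#' Predicted selectivity of the balanced ring
#'
#' In the shared-profile case the activity selectivity is
#' `nu(1)/nu(0) = rho * J_B(0) / J_B(1)`: proportional to the input
#' selectivity and inversely proportional to the modulation of the
#' connectivity. For the cosine profile this is `2 rho / eps_cB` -- more
#' functional connectivity means less selectivity in a stable balanced state.
#'
#' @param spec A `reduced_model_spec`.
#' @return A tibble with `population` and `ratio` (`nu(1)/nu(0)`).
#' @export
selectivity_prediction <- function(spec) {
  jf <- fourier_interactions(spec, max(spec$n_max, 1))
  pred <- function(j0, j1, pop) {
    if (Mod(j1) < 1e-14) {
      abort(sprintf(paste0(
        "population %s: the connectivity profile has no first Fourier mode ",
        "(salt-and-pepper limit); the mean-field selectivity diverges and is ",
        "set by connectivity fluctuations instead"), pop))
    }
    spec$rho * Mod(j0) / Mod(j1)
  }
  tibble(
    population = c("E", "I"),
    ratio = c(pred(jf$j_ee[1] / spec$g[["ee"]], jf$j_ee[2] / spec$g[["ee"]], "E"),
              pred(jf$j_ei[1] / spec$g[["ei"]], jf$j_ei[2] / spec$g[["ei"]], "I"))
  )
}

#' Stability of the balanced state, mode by mode
#'
#' The balanced fixed point is stable only if, for every Fourier mode, the
#' rate-dynamics matrix `A(n) = [[J_EE(n), -J_EI(n)\], [J_IE(n), -J_II(n)\]]`
#' has eigenvalues with non-positive real part, equivalently (strictly)
#' `J_EE(n) - J_II(n) < 0` and `J_IE(n) J_EI(n) - J_EE(n) J_II(n) > 0`.
#' Functional reconnection moves mode 1: too much excitatory modulation
#' relative to inhibitory modulation destabilizes it. Given `eps_ce`, the
#' report includes the smallest `eps_ci` that keeps mode 1 stable, found
#' numerically as the zero crossing of the leading eigenvalue real part.
#'
#' @param spec A `reduced_model_spec`.
#' @param n_max Number of modes to check.
#' @return A list of class `stability_report`: `modes` (tibble with the mode
#'   conditions and leading eigenvalue real part), `feasible` (positive-rate
#'   condition on mode 0 inputs), `eps_ci_min` (boundary value, `NA` if mode 1
#'   cannot be stabilized). Has \[tidy()] and [glance()] methods.
#' @export
stability_report <- function(spec, n_max = spec$n_max) {
  jf <- fourier_interactions(spec, n_max)
  mode_eig <- function(j) {
    a <- matrix(c(Re(j[1]), Re(j[3]), -Re(j[2]), -Re(j[4])), 2, 2)
    max(Re(eigen(a, only.values = TRUE)$values))
  }
  modes <- jf %>%
    mutate(
      trace_ok = Re(.data$j_ee) - Re(.data$j_ii) < 0,
      det_ok = Re(.data$j_ie) * Re(.data$j_ei) - Re(.data$j_ee) * Re(.data$j_ii) > 0,
      max_re_eig = vapply(seq_len(dplyr::n()), function(r) {
        mode_eig(c(.data$j_ee[r], .data$j_ei[r], .data$j_ie[r], .data$j_ii[r]))
      }, numeric(1)),
      stable = .data$max_re_eig <= 1e-12
    )
  feas <- check_feasibility(jf, spec)
  # minimal inhibitory modulation that keeps mode 1 stable at the given eps_ce
  lead_re <- function(eps_ci) {
    s2 <- spec; s2$eps[["i"]] <- eps_ci; s2$profile$i <- NULL
    j <- fourier_interactions(s2, 1)
    mode_eig(c(j$j_ee[2], j$j_ei[2], j$j_ie[2], j$j_ii[2]))
  }
  eps_ci_min <- if (lead_re(0) <= 1e-12) {
    0
  } else if (lead_re(1) > 1e-12) {
    NA_real_
  } else {
    uniroot(lead_re, c(0, 1), tol = 1e-12)$root
  }
  structure(list(modes = modes, feasible = feas, eps_ci_min = eps_ci_min,
                 spec = spec),
            class = "stability_report")
}

#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) x$modes

#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  tibble(feasible = x$feasible$ok, all_stable = all(x$modes$stable),
         eps_ci_min = x$eps_ci_min)
}

#' @method print stability_report
#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("balanced-state stability: feasible = %s, all modes stable = %s\n",
              x$feasible$ok, all(x$modes$stable)))
  unstable <- x$modes$n[!x$modes$stable]
  if (length(unstable) > 0) {
    cat("  unstable mode(s):", paste(unstable, collapse = ", "), "\n")
  }
  cat(sprintf("  eps_ci_min (mode-1 boundary at eps_ce = %.3g): %.6g\n",
              x$spec$eps[["e"]], x$eps_ci_min))
  invisible(x)
}

#' @method tidy balanced_solution
#' @export
tidy.balanced_solution <- function(x, ...) {
  tidyr::pivot_longer(
    mutate(x$modes, nu_e = Mod(.data$nu_e) * sign(Re(.data$nu_e) + (Re(.data$nu_e) == 0)),
           nu_i = Mod(.data$nu_i) * sign(Re(.data$nu_i) + (Re(.data$nu_i) == 0))),
    c("nu_e", "nu_i"), names_to = "population", values_to = "magnitude") %>%
    mutate(population = dplyr::if_else(.data$population == "nu_e", "E", "I"))
}

#' @method glance balanced_solution
#' @export
glance.balanced_solution <- function(x, ...) {
  tibble(
    nu_e_0 = Re(x$modes$nu_e[1]), nu_i_0 = Re(x$modes$nu_i[1]),
    selectivity_e = x$selectivity$ratio[1],
    selectivity_i = x$selectivity$ratio[2]
  )
}

#' @method print balanced_solution
#' @export
print.balanced_solution <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("balanced ring solution: nu_E(0) = %.4g, nu_I(0) = %.4g (units I_ext/G)\n",
              g$nu_e_0, g$nu_i_0))
  cat(sprintf("  activity selectivity nu(1)/nu(0): E = %.4g, I = %.4g\n",
              g$selectivity_e, g$selectivity_i))
  invisible(x)
}
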