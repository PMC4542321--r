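test_that("Fourier interaction components match the closed forms", {
  s <- reduced_model_spec(eps_ce = 0.44, eps_ci = 0.22)
  jf <- fourier_interactions(s, 3)
  expect_equal(jf$j_ee[jf$n == 0], 32)
  expect_equal(jf$j_ee[jf$n == 1], 32 * 0.44 / 2, tolerance = 1e-14)
  expect_equal(jf$j_ee[jf$n == 1], 7.04, tolerance = 1e-12)
  expect_equal(jf$j_ii[jf$n == 1], 128 * 0.22 / 2, tolerance = 1e-14)
  expect_true(all(jf$j_ee[jf$n > 1] == 0))
  # flat (salt-and-pepper) profile: no modulation at any mode
  s0 <- reduced_model_spec()
  jf0 <- fourier_interactions(s0, 4)
  expect_true(all(jf0$j_ee[jf0$n >= 1] == 0))
  # signed couplings are accepted as magnitudes
  ssig <- reduced_model_spec(g_ei = -96, g_ii = -128)
  expect_equal(ssig$g[["ei"]], 96)
  expect_equal(ssig$g[["ii"]], 128)
})

test_that("custom profiles go through quadrature and must be normalized", {
  s <- reduced_model_spec(profile_e = function(th) 1 + 0.44 * cos(2 * pi * th))
  jf <- fourier_interactions(s, 2)
  expect_equal(Re(jf$j_ee[2]), 7.04, tolerance = 1e-10)
  expect_equal(Re(jf$j_ee[3]), 0, tolerance = 1e-10)
  bad <- reduced_model_spec(profile_e = function(th) 2 + cos(2 * pi * th))
  expect_error(fourier_interactions(bad), "normalized")
})

test_that("balanced rates solve the mode-wise system", {
  s <- reduced_model_spec(eps_ce = 0.44, eps_ci = 0.44, rho = 0.06)
  b <- balanced_rates(s)
  # mean-rate ratio from the default couplings: (128 - 96) / (96 - 32) = 1/2
  expect_equal(Re(b$modes$nu_e[1]) / Re(b$modes$nu_i[1]), 0.5, tolerance = 1e-12)
  # cosine profiles and mode-{0,1} input: all modes above 1 vanish
  expect_true(all(Mod(b$modes$nu_e[b$modes$n > 1]) < 1e-15))
  expect_true(all(Mod(b$modes$nu_i[b$modes$n > 1]) < 1e-15))
  # rho = 0: flat activity
  s0 <- reduced_model_spec(eps_ce = 0.3, eps_ci = 0.3, rho = 0)
  b0 <- balanced_rates(s0)
  expect_equal(Mod(b0$modes$nu_e[2]), 0)
  expect_lt(diff(range(b0$rates$nu_e)), 1e-14)
  # salt-and-pepper limit: modulated input with flat interactions is singular
  expect_error(balanced_rates(reduced_model_spec(rho = 0.06)), "salt-and-pepper")
  # infeasible mean inputs are rejected with the failed inequality shown
  expect_error(balanced_rates(reduced_model_spec(eps_ce = 0.3, eps_ci = 0.3,
                                                 i_ext_e = 0.7, i_ext_i = 1)),
               "balanced state")
})

test_that("balanced rates agree with a dense discretized solve", {
  for (pars in list(c(0.44, 0.22), c(0.3, 0.3), c(0.1, 0.4))) {
    s <- reduced_model_spec(eps_ce = pars[1], eps_ci = pars[2], rho = 0.06)
    b <- balanced_rates(s)
    dense <- oracle_dense_balance(s, grid = 512)
    for (n in 0:3) {
      expect_equal(b$modes$nu_e[n + 1], dense$mode(dense$nu_e, n), tolerance = 1e-8)
      expect_equal(b$modes$nu_i[n + 1], dense$mode(dense$nu_i, n), tolerance = 1e-8)
    }
  }
})

test_that("selectivity prediction is 2 rho / eps and scale-free in G", {
  s <- reduced_model_spec(eps_ce = 0.44, eps_ci = 0.22, rho = 0.06)
  pred <- selectivity_prediction(s)
  expect_equal(pred$ratio[pred$population == "E"], 2 * 0.06 / 0.44, tolerance = 1e-14)
  expect_equal(pred$ratio[pred$population == "E"], 0.2727, tolerance = 1e-3)
  expect_equal(pred$ratio[pred$population == "I"], 2 * 0.06 / 0.22, tolerance = 1e-14)
  # the closed-form identity: prediction times eps recovers 2 rho exactly
  for (eps in c(0.11, 0.22, 0.44, 0.88)) {
    se <- reduced_model_spec(eps_ce = eps, eps_ci = 0.22, rho = 0.06)
    expect_equal(selectivity_prediction(se)$ratio[1] * eps, 2 * 0.06,
                 tolerance = 1e-12)
  }
  # doubling eps halves the prediction
  s2 <- reduced_model_spec(eps_ce = 0.88, eps_ci = 0.22, rho = 0.06)
  expect_equal(selectivity_prediction(s2)$ratio[1],
               pred$ratio[pred$population == "E"] / 2, tolerance = 1e-12)
  # independent of the coupling magnitudes for shared profiles
  sg <- reduced_model_spec(g_ee = 64, g_ei = 192, g_ie = 192, g_ii = 256,
                           eps_ce = 0.44, eps_ci = 0.22, rho = 0.06)
  expect_equal(selectivity_prediction(sg)$ratio, pred$ratio, tolerance = 1e-12)
  # flat profile: the mean-field prediction diverges and must signal it
  expect_error(selectivity_prediction(reduced_model_spec()), "salt-and-pepper")
})

test_that("balanced solution ratios are invariant under global G rescaling", {
  s1 <- reduced_model_spec(eps_ce = 0.44, eps_ci = 0.22, rho = 0.06)
  s2 <- reduced_model_spec(g_ee = 32 * 3, g_ei = 96 * 3, g_ie = 96 * 3,
                           g_ii = 128 * 3, eps_ce = 0.44, eps_ci = 0.22, rho = 0.06)
  b1 <- balanced_rates(s1); b2 <- balanced_rates(s2)
  expect_equal(b1$selectivity$ratio, b2$selectivity$ratio, tolerance = 1e-12)
  expect_equal(Re(b2$modes$nu_e[1]) / Re(b1$modes$nu_e[1]), 1 / 3, tolerance = 1e-12)
})

test_that("mode-wise stability conditions and the reconnection boundary", {
  s <- reduced_model_spec(eps_ce = 0.44, eps_ci = 0.22)
  rep_ <- stability_report(s)
  expect_true(rep_$feasible$ok)
  expect_true(all(rep_$modes$stable))
  # the worked boundary: eps_ci_min = eps_ce * G_EE / |G_II| = 0.44 / 4
  expect_equal(rep_$eps_ci_min, 0.11, tolerance = 1e-9)
  expect_equal(rep_$eps_ci_min, 0.44 * 32 / 128, tolerance = 1e-9)
  # just below the boundary mode 1 is unstable
  s_low <- reduced_model_spec(eps_ce = 0.44, eps_ci = 0.03)
  rep_low <- stability_report(s_low)
  expect_false(rep_low$modes$stable[rep_low$modes$n == 1])
  expect_true(rep_low$modes$stable[rep_low$modes$n == 0])
  # flat profiles: nothing to destabilize beyond mode 0, which is feasible
  rep0 <- stability_report(reduced_model_spec())
  expect_true(all(rep0$modes$stable))
  expect_true(rep0$feasible$ok)
  expect_gt(1, rep0$feasible$inh_ratio)            # I ratio 1 > 96/128
  expect_gt(rep0$feasible$inh_ratio, rep0$feasible$exc_ratio)  # 96/128 > 32/96
  expect_equal(rep0$feasible$inh_ratio, 96 / 128)
  expect_equal(rep0$feasible$exc_ratio, 32 / 96)
  expect_equal(glance(rep_)$eps_ci_min, 0.11, tolerance = 1e-9)
})

test_that("the numeric boundary equals the analytic eigenvalue crossing", {
  # independent check: leading eigenvalue of the mode-1 matrix as a function
  # of eps_ci, root found directly on the 2x2 eigenvalues
  lead <- function(eps_ci, eps_ce = 0.44) {
    a <- matrix(c(32 * eps_ce / 2, 96 * eps_ce / 2,
                  -96 * eps_ci / 2, -128 * eps_ci / 2), 2, 2)
    max(Re(eigen(a, only.values = TRUE)$values))
  }
  root <- stats::uniroot(lead, c(1e-6, 1), tol = 1e-14)$root
  s <- reduced_model_spec(eps_ce = 0.44, eps_ci = 0.22)
  expect_equal(stability_report(s)$eps_ci_min, root, tolerance = 1e-10)
})
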