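p_default <- default_parameters()

test_that("recruitment forcing is bias-corrected and periodic", {
  fp <- p_default$sardine
  fp$A <- 0
  expect_equal(recruitment_rate(c(0, 3, 17.2), fp), rep(fp$r_bar, 3))

  for (A in c(0.2, 0.4, 0.6)) {
    fp$A <- A
    m <- integrate(function(t) recruitment_rate(t, fp), 0, fp$p,
                   rel.tol = 1e-10)$value / fp$p
    expect_lt(abs(m - fp$r_bar) / fp$r_bar, 0.01)
  }
  fp$A <- 0.6
  tt <- c(0.3, 4.4, 9)
  expect_equal(recruitment_rate(tt, fp), recruitment_rate(tt + fp$p, fp))
  expect_true(all(recruitment_rate(seq(0, 50, 0.1), fp) > 0))

  fp$p <- 0
  expect_error(recruitment_rate(1, fp), "period")
})

test_that("Type-II predation has shared-denominator buffering", {
  hp <- p_default$halibut
  expect_equal(unname(predation_mortality(1e5, 2e5, 0, hp)), c(0, 0))
  hp2 <- hp
  hp2$alpha_s <- hp2$alpha_a
  P <- predation_mortality(3e5, 3e5, 4e4, hp2)
  expect_equal(P[["Pa"]], P[["Ps"]])
  # Pa strictly decreases as the other prey becomes more abundant
  Xs_grid <- seq(1e5, 1.5e6, length.out = 30)
  Pa <- vapply(Xs_grid,
               function(Xs) predation_mortality(5e5, Xs, 4e4, hp)[["Pa"]],
               numeric(1))
  expect_true(all(diff(Pa) < 0))
})

test_that("halibut recruitment follows the delayed Beverton-Holt", {
  hp <- p_default$halibut
  expect_equal(halibut_recruitment(0, hp), 0)
  sat <- hp$a / hp$b * exp(-hp$M_j * hp$tau)
  expect_equal(halibut_recruitment(1e12, hp), sat, tolerance = 1e-6)
  eps <- 1e-4
  slope <- halibut_recruitment(eps, hp) / eps
  expect_equal(slope, hp$a * exp(-hp$M_j * hp$tau), tolerance = 1e-6)
})

test_that("halibut asymptotic mass tracks relative consumption", {
  hp <- p_default$halibut
  pp <- p_default$pelican
  expect_equal(halibut_asymptotic_mass(pp$Xa_o, pp$Xs_o, hp), hp$w_inf0)
  hp0 <- hp
  hp0$gamma_w <- 0
  expect_equal(halibut_asymptotic_mass(1e4, 1e4, hp0),
               halibut_asymptotic_mass(1e6, 1e6, hp0))
  Xa_grid <- seq(0, 2e6, length.out = 40)
  w <- vapply(Xa_grid,
              function(Xa) halibut_asymptotic_mass(Xa, 3e5, hp),
              numeric(1))
  expect_true(all(diff(w) >= 0))
})

test_that("the depletion index is normalized and linear", {
  pp <- p_default$pelican
  expect_equal(pelican_depletion(pp$Xa_o, pp$Xs_o, pp), 1)
  expect_equal(pelican_depletion(0, 0, pp), pp$Gamma_other)
  d1 <- pelican_depletion(1e5, 3e5, pp)
  d2 <- pelican_depletion(2e5, 3e5, pp)
  d3 <- pelican_depletion(3e5, 3e5, pp)
  expect_equal(d3 - d2, d2 - d1)
  pp$Xa_o <- 0
  expect_error(pelican_depletion(1e5, 3e5, pp), "baseline")
})

test_that("the prey-response scalar rises from theta1 and saturates", {
  th <- c(0.3, 0.12, 0.5)
  expect_equal(prey_response(0.3, th), 0)
  expect_equal(prey_response(0.1, th), 0)
  expect_equal(prey_response(1e9, th), 1, tolerance = 1e-6)
  d <- seq(0.3, 3, length.out = 200)
  expect_true(all(diff(prey_response(d, th)) >= 0))
  expect_true(all(prey_response(d, th) >= 0 & prey_response(d, th) <= 1))
  # theta2 = 0 decouples the vital rate: response is 1 above theta1
  expect_equal(prey_response(0.31, c(0.3, 0, 0.5)), 1)
  expect_error(prey_response(1, c(1.2, 0.1, 0.5)), "range")
  expect_error(prey_response(1, c(0.3, 0.1, 1.5)), "range")
})

test_that("Pelican reproduction and the density-dependence exponent", {
  pp <- p_default$pelican
  beta <- 0.5 * exp(-pp$Mbar * pp$tau_bp)
  expect_equal(pelican_reproduction(pp$K_bp, 1, pp), beta * pp$K_bp)
  expect_equal(pelican_reproduction(70, 0, pp), 0)
  expect_error(pelican_reproduction(-1, 0.5, pp))
  # z is selected so *total* net productivity (recruitment minus adult
  # mortality at saturated prey response) peaks at 60% of K_bp
  N <- seq(1, 2 * pp$K_bp, length.out = 4001)
  G <- vapply(N, function(n) pelican_reproduction(n, 1, pp), numeric(1)) -
    pp$Mbar * N
  expect_equal(N[which.max(G)] / pp$K_bp, 0.6, tolerance = 0.01)
})

test_that("Pelican mortality rises as the survival scalar falls", {
  pp <- p_default$pelican
  expect_equal(pelican_mortality_rate(1e6, pp), pp$Mbar,
               tolerance = 1e-5)
  # depletion at which the survival scalar is exp(-1) adds exactly 1
  d_star <- uniroot(function(d) prey_response(d, pp$theta_s) - exp(-1),
                    c(pp$theta_s[1] + 1e-9, 50), tol = 1e-12)$root
  expect_equal(pelican_mortality_rate(d_star, pp), pp$Mbar + 1,
               tolerance = 1e-6)
  d <- seq(0, 3, length.out = 100)
  M <- vapply(d, pelican_mortality_rate, numeric(1), pp = pp)
  expect_true(all(diff(M) <= 0))
  # the survival-scalar floor keeps mortality finite at zero prey
  expect_lt(pelican_mortality_rate(0, pp), Inf)
})

test_that("derivative surfaces vanish at empty states and at the
           unfished steady state", {
  p <- apply_forcing(p_default, "constant")
  zero <- setNames(rep(0, 7), c("Xa", "Na", "Xs", "Ns", "Xh", "Nh", "Nbp"))
  fd <- forage_derivatives(zero, 0, 0, 0, p)
  expect_equal(unname(fd$anchovy), c(0, 0))
  expect_equal(unname(fd$sardine), c(0, 0))
  expect_equal(unname(halibut_derivatives(zero, 0, 0, 0, p)), c(0, 0))
  expect_equal(pelican_derivative(zero, 0,
                                  c(Xa = 0, Xs = 0, Nbp = 0), p), 0)

  eq <- c(Xa = p$anchovy$X0, Na = p$anchovy$N0,
          Xs = p$sardine$X0, Ns = p$sardine$N0,
          Xh = p$halibut$X0, Nh = p$halibut$N0, Nbp = 100)
  fd <- forage_derivatives(eq, 0, 0, 0, p)
  expect_equal(unname(fd$anchovy), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(fd$sardine), c(0, 0), tolerance = 1e-8)
  hd <- halibut_derivatives(eq, 0, eq[["Xh"]], 0, p)
  expect_equal(unname(hd) / c(eq[["Xh"]], eq[["Nh"]]), c(0, 0),
               tolerance = 1e-10)

  # Pelican equilibrium found by root-finding is a fixed point
  pp <- p$pelican
  Nstar <- uniroot(function(n) {
    st <- eq; st[["Nbp"]] <- n
    pelican_derivative(st, 0, c(Xa = eq[["Xa"]], Xs = eq[["Xs"]],
                                Nbp = n), p)
  }, c(50, 200), tol = 1e-10)$root
  st <- eq; st[["Nbp"]] <- Nstar
  expect_equal(pelican_derivative(st, 0,
                                  c(Xa = eq[["Xa"]], Xs = eq[["Xs"]],
                                    Nbp = Nstar), p) / Nstar, 0,
               tolerance = 1e-8)
  # removing all forage forces decline
  gone <- eq; gone[["Xa"]] <- 0; gone[["Xs"]] <- 0
  expect_lt(pelican_derivative(gone, 0,
                               c(Xa = 0, Xs = 0, Nbp = 100), p), 0)
  expect_error(forage_derivatives(replace(eq, 1, -1), 0, 0, 0, p),
               "non-negative")
})

test_that("unfished constant-forcing simulation stays on the fixed
           point and mean mass lies between recruit and asymptotic mass", {
  sc <- fw_scenario(regime = "OA_all", forcing = "constant", T = 60)
  tr <- simulate(sc, fw_policy(), T = 60, dt = 0.5)
  for (v in c("Xa", "Na", "Xs", "Ns", "Xh", "Nh")) {
    expect_lt(max(abs(tr[[v]] / tr[[v]][1] - 1)), 1e-5)
  }
  p <- sc$params
  mbar_a <- tr$Xa / tr$Na
  expect_true(all(mbar_a > p$anchovy$w_r & mbar_a < p$anchovy$w_inf))
  # restarting from a perturbed state relaxes mean mass back into range
  p2 <- p
  p2$anchovy$N0 <- p$anchovy$X0 / p$anchovy$w_inf  # mean mass at w_inf
  tr2 <- simulate(p2, fw_policy(), T = 80, dt = 0.5)
  m_end <- tail(tr2$Xa / tr2$Na, 1)
  expect_gt(m_end, p$anchovy$w_r)
  expect_lt(m_end, p$anchovy$w_inf)
})

test_that("forced unfished forage cycles with the forcing period", {
  sc <- fw_scenario(regime = "OA_all", forcing = "synchronous", T = 150)
  tr <- simulate(sc, fw_policy(), T = 150, dt = 0.25)
  x <- tr$Xs
  peaks <- which(diff(sign(diff(x))) == -2) + 1
  peak_t <- tr$t[peaks]
  peak_t <- peak_t[peak_t > 20]  # discard the initial transient
  expect_gt(length(peak_t), 3)
  expect_equal(diff(peak_t), rep(sc$params$sardine$p,
                                 length(peak_t) - 1),
               tolerance = 0.02)
})

test_that("integration is reproducible, convergent and non-negative", {
  sc <- fw_scenario(regime = "OA_all", forcing = "synchronous", T = 40)
  pol <- policy_registry()$open_access()
  tr1 <- simulate(sc, pol, dt = 0.25, rtol = 1e-6)
  tr2 <- simulate(sc, pol, dt = 0.25, rtol = 1e-6)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  # refining the tolerance barely moves the terminal state
  tr3 <- simulate(sc, pol, dt = 0.25, rtol = 1e-7)
  end1 <- unlist(tail(tr1, 1)[, 2:8])
  end3 <- unlist(tail(tr3, 1)[, 2:8])
  expect_lt(max(abs(end1 - end3) / pmax(abs(end3), 1)), 1e-3)
  # heavy constant fishing cannot push states negative
  hard <- policy_registry()$constant_F(2, 2, 2)
  trh <- simulate(sc, hard, dt = 0.25, rtol = 1e-6)
  expect_true(all(as.matrix(trh[, 2:8]) >= 0))
})

test_that("compiled and R right-hand sides agree", {
  sc <- fw_scenario(regime = "OA_all", forcing = "anti_synchronous",
                    T = 30)
  pols <- list(policy_registry()$open_access(),
               policy_registry()$hcr(),
               policy_registry()$hockey_stick(),
               fw_policy(sardine = list(t = c(0, 10, 30),
                                        E = c(500, 0, 800))))
  for (pol in pols) {
    withr::with_options(list(forageweb.compiled = TRUE), {
      trC <- simulate(sc, pol, dt = 0.5, rtol = 1e-8)
    })
    withr::with_options(list(forageweb.compiled = FALSE), {
      trR <- simulate(sc, pol, dt = 0.5, rtol = 1e-8)
    })
    mism <- max(abs(as.matrix(trC[, 2:8]) - as.matrix(trR[, 2:8])) /
                  pmax(abs(as.matrix(trR[, 2:8])), 1))
    expect_lt(mism, 1e-6)
  }
})

test_that("open access never exceeds the unfished trajectory and
           halibut benefits from more prey", {
  sc <- fw_scenario(regime = "OA_all", forcing = "synchronous", T = 50)
  un <- simulate(sc, fw_policy(), dt = 0.25)
  oa <- simulate(sc, policy_registry()$open_access(), dt = 0.25)
  expect_true(all(oa$Xa <= un$Xa * (1 + 1e-8)))
  expect_true(all(oa$Xs <= un$Xs * (1 + 1e-8)))

  # doubling forage abundance weakly raises the halibut equilibrium
  p2 <- sc$params
  for (sp in c("anchovy", "sardine")) {
    p2[[sp]]$X0 <- 2 * p2[[sp]]$X0
    p2[[sp]]$N0 <- 2 * p2[[sp]]$N0
  }
  base <- simulate(fw_scenario(params = default_parameters(),
                               forcing = "constant", T = 80),
                   fw_policy(), dt = 0.5)
  rich <- simulate(fw_scenario(params = p2, forcing = "constant", T = 80),
                   fw_policy(), dt = 0.5)
  expect_gt(tail(rich$Xh, 1), tail(base$Xh, 1))
})

test_that("trajectory accessors and writers round-trip", {
  sc <- fw_scenario(regime = "OA_all", forcing = "constant", T = 10)
  tr <- simulate(sc, policy_registry()$open_access(), dt = 0.1)
  f <- state_accessor(tr)
  expect_equal(f(-3), f(0))  # constant initial history
  mid <- f(5.05)
  expect_true(all(mid >= 0))
  expect_equal(unname(mid["Xa"]),
               approx(tr$t, tr$Xa, xout = 5.05)$y, tolerance = 1e-3)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$Xs, tr$Xs)
  expect_named(back, c("t", "Xa", "Na", "Xs", "Ns", "Xh", "Nh", "Nbp",
                       "Ea", "Es", "Eh", "Fa", "Fs", "Fh"))
})
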