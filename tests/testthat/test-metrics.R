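fake_traj <- function(t, Nbp, Ea = 0, Es = 0, Eh = 0) {
  tibble::tibble(t = t, Xa = 1, Na = 1, Xs = 1, Ns = 1, Xh = 1, Nh = 1,
                 Nbp = Nbp, Ea = Ea, Es = Es, Eh = Eh,
                 Fa = 0, Fs = 0, Fh = 0)
}

test_that("long-run levels and Pelican gains", {
  t <- seq(0, 50, 0.5)
  tr <- fake_traj(t, Nbp = 100 + 0 * t)
  expect_equal(longrun_level(tr, "Nbp"), 100)
  expect_equal(longrun_pelican_gain(tr, tr), 0)
  tr130 <- fake_traj(t, Nbp = 130 + 0 * t)
  expect_equal(longrun_pelican_gain(tr130, tr), 30)
  # ratio algebra: gain(R vs OA) = -gain(OA vs R)/(1 + gain(OA vs R))
  g <- longrun_pelican_gain(tr130, tr) / 100
  ginv <- longrun_pelican_gain(tr, tr130) / 100
  expect_equal(g, -ginv / (1 + ginv))
  expect_error(longrun_pelican_gain(tr, fake_traj(t, 0 * t)), "zero")
})

test_that("Pelican life-years integrate the index", {
  t <- seq(0, 50, 0.25)
  expect_equal(pelican_life_years(fake_traj(t, 100 + 0 * t)), 5000)
  # additivity over subintervals
  tr <- fake_traj(t, Nbp = 80 + 20 * sin(t / 5))
  half1 <- fake_traj(t[t <= 25], Nbp = 80 + 20 * sin(t[t <= 25] / 5))
  half2 <- fake_traj(t[t >= 25], Nbp = 80 + 20 * sin(t[t >= 25] / 5))
  expect_equal(pelican_life_years(half1) + pelican_life_years(half2),
               pelican_life_years(tr))
  # quadrature refinement
  t2 <- seq(0, 50, 0.025)
  tr2 <- fake_traj(t2, Nbp = 80 + 20 * sin(t2 / 5))
  expect_lt(abs(pelican_life_years(tr) - pelican_life_years(tr2)) /
              pelican_life_years(tr2), 1e-4)
})

test_that("elasticity follows the positive-gain convention", {
  expect_equal(elasticity(100, 90, 1000, 1100), 1)
  expect_equal(elasticity(100, 95, 1000, 1100), 0.5)
  # invariant to currency and index rescaling
  expect_equal(elasticity(1e6, 0.9e6, 5e4, 5.5e4),
               elasticity(100, 90, 1000, 1100))
  expect_error(elasticity(100, 90, 1000, 1000), "undefined")
  expect_error(elasticity(-5, -10, 1000, 1100), "positive")
})

test_that("crossing times locate the floor violation and the policy
           divergence", {
  t <- seq(0, 40, 0.5)
  unc <- fake_traj(t, Nbp = 100 - t, Es = 50 + 0 * t)
  same <- unc
  ct <- crossing_times(unc, same, floor = -10)
  expect_identical(ct$T_cross, Inf)
  expect_identical(ct$T_change, Inf)
  # floor above the initial level crosses immediately
  expect_equal(crossing_times(unc, same, floor = 150)$T_cross, 0)
  # divergence inserted at t = 5
  con <- unc
  con$Es <- ifelse(t >= 5, 60, 50)
  ct <- crossing_times(unc, con, floor = 70)
  expect_equal(ct$T_change, 5)
  expect_equal(ct$T_cross, 30.5)  # first grid point strictly below
  expect_lt(ct$T_change, ct$T_cross)
  expect_error(crossing_times(unc, con[1:10, ], floor = 1), "common")
})

test_that("scaled trajectories start at one", {
  sc <- fw_scenario(regime = "OA_all", forcing = "constant", T = 5)
  tr <- simulate(sc, policy_registry()$open_access(), dt = 0.5)
  sct <- scale_trajectory(tr)
  expect_setequal(unique(sct$series),
                  c("anchovy", "sardine", "halibut", "pelican"))
  expect_true(all(sct$value[sct$t == 0] == 1))
})

test_that("the regime sweep summarizes into one row per cell", {
  regimes <- c("OA_all", optimization_regimes(), "Moratorium_all")
  forcings <- c("constant", "synchronous", "anti_synchronous")
  results <- list()
  for (f in forcings) {
    sc <- fw_scenario(regime = "OA_all", forcing = f, T = 10)
    for (r in regimes) {
      # cheap stand-in sweep: simulate each regime's implied policy
      # (optimized species closed) rather than solving it
      results[[paste0(r, "/", f)]] <-
        simulate(sc, regime_policy(r), dt = 0.5)
    }
  }
  tab <- summary_report(results, window = 2)
  expect_equal(nrow(tab), 27)
  expect_setequal(unique(tab$regime), regimes)
  # OA cells have (near) zero profit for every species
  oa <- tab[tab$regime == "OA_all", ]
  expect_true(all(abs(oa$npv_anchovy) < 1e-6))
  expect_true(all(abs(oa$npv_sardine) < 1e-6))
  # gains are zero against itself
  expect_true(all(abs(tab$pelican_gain_vs_OA[tab$regime == "OA_all"])
                  < 1e-10))
  # a missing cell is reported as NA, not dropped
  results2 <- results[1:5]
  results2[["A+S/constant"]] <- NULL
  results2[["missing/constant"]] <- NULL
  tab2 <- summary_report(c(results2, list("X+Y/constant" = NULL)),
                         window = 2)
  expect_true(any(is.na(tab2$J)))
})

test_that("tidiers summarize solutions", {
  sc <- fw_scenario(regime = "Moratorium_all", forcing = "constant",
                    T = 10)
  sol <- solve_regime(sc, solver_control(dt_final = 0.5))
  td <- tidy(sol)
  expect_equal(nrow(td), 3)
  expect_true(all(td$role == "closed"))
  gl <- glance(sol)
  expect_equal(gl$J, 0)
  expect_identical(gl$status, "converged")
})
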