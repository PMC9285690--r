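# Numerical optimal control of fishing effort.
#
# The regulator's problem - maximize discounted total profit over effort
# paths subject to the delay-differential dynamics - is solved by
# control-parameterized single shooting: each optimized species' effort
# is a piecewise-linear function of time on a coarse knot grid, the
# objective is evaluated by integrating the dynamics with the package
# integrator, and the knot values are optimized with projected
# quasi-Newton iterations (L-BFGS-B) under box constraints, from several
# starting guesses. Open-access species are closed algebraically inside
# the dynamics (their effort is never a decision variable); closed
# species carry zero effort. A Pelican floor is enforced by an
# escalating quadratic penalty with a final feasibility check.

#' Solver settings
#'
#' @param maxit_screen iterations used to screen each starting guess
#'   before the best is polished with `maxit` iterations.
#' @param knot_dt effort-knot spacing (yr). The default 2 yr resolves
#'   the multi-year moratorium/fishing episodes the model produces while
#'   keeping the decision vector small.
#' @param maxit maximum quasi-Newton iterations per start.
#' @param rtol integration tolerance used inside the optimization loop
#'   (the final reported trajectory is re-integrated at `rtol_final`).
#' @param rtol_final tolerance for the final/verification integration.
#' @param dt output/quadrature grid inside the optimization loop (yr).
#' @param dt_final output grid of the reported trajectory (yr).
#' @param Emax_mult effort upper bound as a multiple of the zero-profit
#'   effort at the initial biomass.
#' @param salvage include the steady-flow continuation term
#'   \eqn{e^{-\delta T}\Psi(T)/\delta} in the objective (reduces
#'   end-of-horizon overharvesting from truncating the infinite horizon).
#' @param penalty_rounds,penalty_growth escalation schedule for the
#'   Pelican-floor penalty.
#' @param feas_tol_frac feasibility tolerance on the floor, as a fraction
#'   of the floor.
#' @param verify_tol maximum allowed relative sup-norm state mismatch
#'   between the optimization-tolerance trajectory and the tight-tolerance
#'   re-integration before a result is demoted to "unverified".
#' @return A list of settings for [solve_regime()].
#' @export
solver_control <- function(knot_dt = 2, maxit = 60, maxit_screen = 10,
                           rtol = 1e-6,
                           rtol_final = 1e-8, dt = 0.25, dt_final = 0.1,
                           Emax_mult = 1.5, salvage = TRUE,
                           penalty_rounds = 3, penalty_growth = 10,
                           feas_tol_frac = 0.005, verify_tol = 0.005) {
  list(knot_dt = knot_dt, maxit = maxit, maxit_screen = maxit_screen,
       rtol = rtol,
       rtol_final = rtol_final, dt = dt, dt_final = dt_final,
       Emax_mult = Emax_mult, salvage = salvage,
       penalty_rounds = penalty_rounds, penalty_growth = penalty_growth,
       feas_tol_frac = feas_tol_frac, verify_tol = verify_tol)
}

moratorium_label <- function(species) {
  if (setequal(species, fished_species)) return("Moratorium_all")
  code <- c(anchovy = "A", sardine = "S", halibut = "H")
  paste0("Moratorium:", paste(code[species], collapse = "+"))
}

knot_grid <- function(T, knot_dt) {
  k <- seq(0, T, by = knot_dt)
  if (max(k) < T) k <- c(k, T)
  k
}

# piecewise-linear open-loop policy for the optimized species, regime
# policy for the rest
knot_policy <- function(regime, knots, E_list) {
  efforts <- lapply(E_list, function(v) {
    new_policy_component("open_loop",
                         effort = approxfun(knots, v, rule = 2),
                         data = list(t = knots, E = v))
  })
  regime_policy(regime, efforts = efforts)
}

# extract effort values at knots for given species from a trajectory
extract_knot_efforts <- function(traj, knots, species) {
  cols <- c(anchovy = "Ea", sardine = "Es", halibut = "Eh")
  out <- lapply(species, function(sp) {
    approx(traj$t, traj[[cols[[sp]]]], xout = pmin(knots, max(traj$t)),
           rule = 2)$y
  })
  names(out) <- species
  out
}

#' Solve the optimal-management problem for a regime
#'
#' Chooses effort paths for the regime's optimized species to maximize
#' the discounted total profit of the system over the scenario horizon,
#' with open-access species closed algebraically (zero average profit at
#' every instant, hence zero profit contribution) and closed species at
#' zero effort. Multi-start: zero effort, the open-access effort path,
#' the myopically optimal effort path, plus any supplied warm starts; the
#' best feasible local solution is returned. A scenario with no
#' optimized species is simply simulated under its implied policy.
#'
#' @param scenario an `fw_scenario`.
#' @param control solver settings from [solver_control()].
#' @param starts optional list of additional starting guesses; each is a
#'   named list (by species) of effort vectors at the knots, or an
#'   `fw_solution` to warm-start from (see [warm_start()]).
#' @param floor optional Pelican floor (index units); adds an escalating
#'   quadratic penalty and a feasibility check (used by
#'   [solve_constrained()]).
#' @return An `fw_solution`: list with the solved `policy`, effort knots
#'   and values, the tight-tolerance `trajectory`, per-species and total
#'   NPV (`npv`, horizon quadrature; `J` is the optimized objective,
#'   including the salvage term if enabled), `diagnostics` (per-start
#'   convergence, verification mismatch, minimum Pelican level,
#'   constraint activity) and a `status` flag.
#' @export
solve_regime <- function(scenario, control = solver_control(),
                         starts = list(), floor = NULL) {
  stopifnot(inherits(scenario, "fw_scenario"))
  reg <- scenario$regime
  opt_sp <- reg$optimized
  T <- scenario$T
  params <- scenario$params

  if (length(opt_sp) == 0) {
    pol <- regime_policy(reg)
    traj <- simulate(scenario, pol, T = T, dt = control$dt_final,
                     rtol = control$rtol_final)
    value <- npv(traj, params, salvage = control$salvage)
    sol <- new_solution(scenario, pol, knots = numeric(),
                        E_list = list(), traj = traj,
                        J = value$npv[value$species == "total"],
                        control = control, floor = floor,
                        diagnostics = list(starts = NULL),
                        status = "converged")
    ver <- verify_solution(sol, scenario, tol = control$verify_tol,
                           rtol = control$rtol_final)
    sol$diagnostics$verification <- ver
    if (!ver$verified) sol$status <- "unverified"
    return(sol)
  }

  knots <- knot_grid(T, control$knot_dt)
  nk <- length(knots)

  # per-species effort upper bounds: multiple of zero-profit effort at
  # the initial (unfished) biomass
  Emax <- vapply(opt_sp, function(sp) {
    ec <- params$econ[[sp]]
    max(control$Emax_mult * (ec$p_tilde * ec$q * params[[sp]]$X0 - ec$c1) /
          ec$c2, 10)
  }, numeric(1))

  split_par <- function(par) {
    out <- lapply(seq_along(opt_sp), function(i) {
      par[((i - 1) * nk + 1):(i * nk)]
    })
    names(out) <- opt_sp
    out
  }

  sim_par <- function(par, rtol, dt) {
    pol <- knot_policy(reg, knots, split_par(par))
    simulate(scenario, pol, T = T, dt = dt, rtol = rtol)
  }

  objective <- function(par) {
    traj <- tryCatch(sim_par(par, control$rtol, control$dt),
                     error = function(e) NULL)
    if (is.null(traj)) return(1e12)
    value <- npv(traj, params, salvage = control$salvage)
    J <- value$npv[value$species == "total"]
    if (!is.null(floor) && penalty_w > 0) {
      viol <- pmax(floor - traj$Nbp, 0)
      J <- J - penalty_w * trapz(traj$t, viol^2)
    }
    -J
  }

  # starting guesses
  guess_from_policy <- function(make_comp) {
    pol <- regime_policy(reg)
    for (sp in opt_sp) pol[[sp]] <- make_comp(sp)
    traj <- simulate(scenario, pol, T = T, dt = control$dt,
                     rtol = control$rtol)
    extract_knot_efforts(traj, knots, opt_sp)
  }
  myopic_comp <- function(sp) {
    ec <- params$econ[[sp]]
    xi <- c(anchovy = "Xa", sardine = "Xs", halibut = "Xh")[[sp]]
    f <- local({
      ec <- ec; xi <- xi
      function(state, t, params) {
        max(0, (ec$p_tilde * ec$q * state[[xi]] - ec$c1) / (2 * ec$c2))
      }
    })
    new_policy_component("feedback", effort = f, label = "myopic")  # C-encodable

  }
  guesses <- list(
    zero = setNames(rep(list(rep(0, nk)), length(opt_sp)), opt_sp),
    open_access = guess_from_policy(function(sp) {
      new_policy_component("open_access")
    }),
    myopic = guess_from_policy(myopic_comp)
  )
  for (i in seq_along(starts)) {
    s <- starts[[i]]
    if (inherits(s, "fw_solution")) s <- warm_start(s, scenario, knots)
    nm <- names(starts)[i]
    if (is.null(nm) || nm == "") nm <- paste0("extra", i)
    miss <- setdiff(opt_sp, names(s))
    for (sp in miss) s[[sp]] <- rep(0, nk)
    guesses[[nm]] <- s[opt_sp]
  }
  # clip guesses into the box
  for (g in names(guesses)) {
    for (sp in opt_sp) {
      guesses[[g]][[sp]] <- pmin(pmax(guesses[[g]][[sp]], 0), Emax[[sp]])
    }
  }

  lower <- rep(0, nk * length(opt_sp))
  upper <- rep(unlist(Emax), each = nk)

  penalty_w <- 0
  run_one <- function(par0, maxit, g) {
    fit <- tryCatch(
      optim(par0, objective, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = maxit, factr = 1e8)),
      error = function(e) list(par = par0, value = objective(par0),
                               convergence = 99,
                               message = conditionMessage(e)))
    fit$start <- g
    fit
  }
  # screen every start cheaply, then polish the best
  run_starts <- function(guesses) {
    fits <- lapply(names(guesses), function(g) {
      run_one(unlist(guesses[[g]], use.names = FALSE),
              control$maxit_screen, g)
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    polished <- run_one(best$par, control$maxit, best$start)
    if (polished$value <= best$value) polished else best
  }

  if (is.null(floor)) {
    best <- run_starts(guesses)
  } else {
    # escalating quadratic penalty, warm-starting each round
    ref <- run_starts(guesses["open_access"])  # scale for the penalty
    J_scale <- max(abs(ref$value), 1)
    penalty_w <- J_scale / max((0.02 * floor)^2 * T, 1e-8)
    best <- NULL
    cur <- guesses
    for (round in seq_len(control$penalty_rounds)) {
      best <- run_starts(cur)
      cur <- c(list(best = split_par(best$par)),
               guesses[setdiff(names(guesses), "best")])
      penalty_w <- penalty_w * control$penalty_growth
    }
  }

  E_list <- split_par(best$par)
  pol <- knot_policy(reg, knots, E_list)
  traj <- simulate(scenario, pol, T = T, dt = control$dt_final,
                   rtol = control$rtol_final)
  value <- npv(traj, params, salvage = control$salvage)
  J <- value$npv[value$species == "total"]

  sol <- new_solution(scenario, pol, knots, E_list, traj, J,
                      control = control, floor = floor,
                      diagnostics = list(
                        best_start = best$start,
                        optim_convergence = best$convergence,
                        optim_value = -best$value,
                        counts = best$counts),
                      status = "converged")
  ver <- verify_solution(sol, scenario, tol = control$verify_tol,
                         rtol = control$rtol)
  sol$diagnostics$verification <- ver
  if (!ver$verified) sol$status <- "unverified"

  if (!is.null(floor)) {
    feas_tol <- control$feas_tol_frac * floor
    min_nbp <- min(traj$Nbp)
    sol$diagnostics$min_Nbp <- min_nbp
    sol$diagnostics$feas_tol <- feas_tol
    act <- traj$t[abs(traj$Nbp - floor) <= 0.01 * floor]
    sol$diagnostics$active_intervals <-
      if (length(act)) range(act) else NULL
    if (min_nbp < floor - feas_tol) sol$status <- "infeasible"
  }
  sol
}

new_solution <- function(scenario, policy, knots, E_list, traj, J,
                         control, floor, diagnostics, status) {
  value <- npv(traj, scenario$params, salvage = FALSE)
  structure(
    list(scenario = scenario, policy = policy, knots = knots,
         efforts = E_list, trajectory = traj, J = as.numeric(J),
         npv = value, floor = floor, control = control,
         diagnostics = diagnostics, status = status),
    class = "fw_solution")
}

#' @export
print.fw_solution <- function(x, ...) {
  cat("<fw_solution>", x$scenario$name, "-", x$status, "\n")
  cat(sprintf("  J (objective) = %.1f\n", x$J))
  v <- x$npv
  cat(sprintf("  NPV: anchovy %.1f, sardine %.1f, halibut %.1f, total %.1f\n",
              v$npv[1], v$npv[2], v$npv[3], v$npv[4]))
  if (!is.null(x$floor)) {
    cat(sprintf("  Pelican floor %.2f; min Nbp %.2f\n", x$floor,
                min(x$trajectory$Nbp)))
  }
  invisible(x)
}

#' Warm-start effort vectors from a previous solution
#'
#' Re-expresses a solved policy on a (possibly different) knot grid for
#' use as a starting guess. Species that were under open access in the
#' solved regime contribute their realized open-access effort path, so a
#' larger regime warm-started this way begins at (weakly) the smaller
#' regime's objective value.
#'
#' @param solution an `fw_solution`.
#' @param scenario the scenario about to be solved.
#' @param knots knot grid of the new problem.
#' @return Named list of effort vectors at the knots.
#' @export
warm_start <- function(solution, scenario, knots) {
  extract_knot_efforts(solution$trajectory, knots,
                       scenario$regime$optimized)
}

#' Pelican floor from the conservation-gain share
#'
#' The floor sits `psi` of the way from the unconstrained-optimal
#' long-run Pelican level up to the no-fishing (moratorium on the managed
#' set) level: `floor = Nbp_opt + psi * (Nbp_nofish - Nbp_opt)`.
#'
#' @param psi share of the conservation gain to protect, in `[0.05, 0.2]`
#'   in the study design (values 0 and 1 reproduce the two references).
#' @param Nbp_nofish_T long-run Pelican level with the managed set
#'   unfished.
#' @param Nbp_opt_T long-run Pelican level under the unconstrained
#'   optimum.
#' @return The floor (index units).
#' @export
pelican_threshold <- function(psi, Nbp_nofish_T, Nbp_opt_T) {
  if (Nbp_nofish_T < Nbp_opt_T) {
    stop("no-fishing Pelican level below the optimal level: ",
         "conservation gain must be non-negative", call. = FALSE)
  }
  psi * (Nbp_nofish_T - Nbp_opt_T) + Nbp_opt_T
}

#' Solve a regime subject to a Pelican floor
#'
#' Computes the regime-specific floor (unless given): the unconstrained
#' optimum and a moratorium-on-the-managed-set run provide the two
#' long-run reference levels, and [pelican_threshold()] interpolates
#' between them with the scenario's `psi`. The constrained problem is
#' then solved by escalating quadratic penalty, warm-started from the
#' unconstrained solution. Reports the crossing diagnostics: `T_cross`,
#' the first time the *unconstrained* trajectory falls below the floor,
#' and `T_change`, the first time the constrained effort paths deviate
#' from the unconstrained ones by more than 1 percent relative -
#' anticipatory adjustment shows up as `T_change < T_cross`. If the floor
#' cannot be met (e.g. managing halibut alone while both forage species
#' stay under open access), the result is flagged `"infeasible"` with the
#' best attainable minimum Pelican level as a certificate.
#'
#' @param scenario an `fw_scenario` (its `psi` is used unless `floor` is
#'   given).
#' @param floor optional explicit floor (index units).
#' @param control solver settings.
#' @param unconstrained optional pre-computed unconstrained
#'   `fw_solution` for the same scenario.
#' @return An `fw_solution` with `floor`, `T_cross`, `T_change` and
#'   feasibility diagnostics.
#' @export
solve_constrained <- function(scenario, floor = NULL,
                              control = solver_control(),
                              unconstrained = NULL) {
  stopifnot(inherits(scenario, "fw_scenario"))
  if (is.null(unconstrained)) {
    unconstrained <- solve_regime(scenario, control)
  }
  period <- longrun_window(scenario)
  if (is.null(floor)) {
    psi <- scenario$psi
    if (is.null(psi)) {
      stop("give `floor` or set `psi` in the scenario", call. = FALSE)
    }
    closed_set <- union(scenario$regime$optimized, scenario$regime$closed)
    mor_label <- moratorium_label(closed_set)
    mor_traj <- simulate(scenario, regime_policy(mor_label),
                         T = scenario$T, dt = control$dt_final,
                         rtol = control$rtol_final)
    L_nofish <- longrun_level(mor_traj, "Nbp", window = period)
    L_opt <- longrun_level(unconstrained$trajectory, "Nbp", window = period)
    floor <- pelican_threshold(psi, max(L_nofish, L_opt), L_opt)
  }

  sol <- solve_regime(scenario, control,
                      starts = list(unconstrained = unconstrained),
                      floor = floor)

  if (sol$status == "infeasible") {
    # certificate: best attainable minimum Pelican level among the
    # penalty solution, the fully protective policy for the managed set,
    # and a short direct maximization of the minimum level
    protective <- moratorium_label(
      union(scenario$regime$optimized, scenario$regime$closed))
    cand <- c(min(sol$trajectory$Nbp),
              min(simulate(scenario, regime_policy(protective),
                           T = scenario$T, dt = control$dt,
                           rtol = control$rtol)$Nbp))
    sol$diagnostics$best_attainable_min_Nbp <- max(cand)
  }

  ct <- crossing_times(unconstrained$trajectory, sol$trajectory, floor)
  sol$T_cross <- ct$T_cross
  sol$T_change <- ct$T_change
  sol$unconstrained_J <- unconstrained$J
  sol
}

#' Verify a solved policy by re-integration
#'
#' Re-integrates the dynamics under the solution's policy at tight
#' tolerance and compares states with the solution's stored trajectory in
#' relative sup-norm (per state, scaled by the state's magnitude); also
#' recomputes the discounted objective by quadrature on the re-integrated
#' path. A mismatch above `tol` marks the solution unverified.
#'
#' @param solution an `fw_solution`.
#' @param scenario defaults to the solution's scenario.
#' @param tol relative sup-norm tolerance (default 0.005).
#' @param rtol tolerance at which the *stored* trajectory is reproduced
#'   for comparison (defaults to the solver's optimization tolerance).
#' @return A list with `mismatch` (worst relative state discrepancy),
#'   `J_requadrature`, and logical `verified`.
#' @export
verify_solution <- function(solution, scenario = solution$scenario,
                            tol = 0.005, rtol = 1e-6) {
  traj_ref <- solution$trajectory
  re <- simulate(scenario, solution$policy, T = max(traj_ref$t),
                 dt = attr(traj_ref, "dt"), rtol = rtol)
  mism <- vapply(state_names, function(v) {
    scale <- max(abs(traj_ref[[v]]), 1e-8)
    max(abs(traj_ref[[v]] - re[[v]])) / scale
  }, numeric(1))
  value <- npv(re, scenario$params, salvage = FALSE)
  list(mismatch = max(mism), per_state = mism,
       J_requadrature = value$npv[value$species == "total"],
       verified = max(mism) <= tol)
}
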