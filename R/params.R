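# Calibration and parameter-set construction.
#
# Units used throughout: biomass in metric tons (t), fish numbers in
# millions of individuals, individual mass in grams (so X [t] = N [1e6] *
# w [g]), time in years, the Pelican population as an index (initial =
# 100), effort in nominal vessel-year units and currency in arbitrary
# units (results are reported as ratios and percent differences).

#' Default stand-in calibration for the food-web model
#'
#' Builds a complete, internally consistent parameter set for the
#' four-species model. The calibration is a documented STAND-IN: the
#' published appendix tables behind the original analysis are not shipped,
#' so the numbers here are chosen by closed-form steady-state algebra so
#' that (a) the unfished system under constant recruitment forcing is an
#' exact fixed point at the design biomasses (anchovy 800,000 t, sardine
#' 600,000 t, halibut 40,000 t), (b) halibut predation is a small share
#' (a few percent) of forage mortality, i.e. weak top-down control, and
#' (c) the Pelican diet is sardine-dominant. Use [load_config()] to
#' substitute an external calibration field-by-field.
#'
#' Fields that are *derived* by the steady-state algebra rather than set
#' directly: forage `r_bar` (mean per-capita recruitment, set to balance
#' natural plus predation mortality at the unfished state), forage and
#' halibut initial numbers `N0` (initial biomass over equilibrium mean
#' mass), the halibut Beverton-Holt `a` (to close the halibut steady
#' state), the baseline relative consumption `f_base`, and the Pelican
#' density-dependence exponent `z` (chosen numerically so total net
#' productivity peaks at 60 percent of `K_bp`, see [solve_z()]).
#'
#' The Pelican initial index `N0 = 100` and the sardine harvest-guideline
#' constants in `policy` are fixed by the management setting being
#' emulated; everything else is STAND-IN.
#'
#' @return An object of class `fw_params`: a named list with components
#'   `anchovy`, `sardine` (forage parameters), `halibut`, `pelican`,
#'   `econ` (per-fishery price/cost/catchability plus shared discount rate
#'   `delta`), `policy` (harvest-control-rule constants) and `settings`.
#' @examples
#' p <- default_parameters()
#' p$pelican$N0
#' p$policy$hcr_share
#' @export
default_parameters <- function() {
  # design targets: unfished long-run biomasses (t)
  Xa_o <- 8e5
  Xs_o <- 6e5
  Xh_o <- 4e4

  halibut <- list(
    a = NA_real_,        # derived below (millions of recruits / t / yr)
    b = 1e-4,            # Beverton-Holt saturation (1/t)
    M_j = 0.3,           # pre-recruit mortality (1/yr)
    tau = 4,             # recruitment delay (yr)
    kappa = 0.15,        # metabolic/growth rate (1/yr)
    w_r = 1500,          # recruit mass (g)
    w_inf0 = 9000,       # asymptotic mass at baseline prey (g)
    Cmax = 3,            # max specific consumption (1/yr)
    alpha_a = 7.5e-7,    # search/capture rate on anchovy (1/t 1/yr)
    alpha_s = 1e-6,      # search/capture rate on sardine (1/t 1/yr)
    Y = 2,               # other-prey availability term (1/yr)
    gamma_w = 1,         # consumption -> asymptotic-mass exponent
    M = 0.25,            # adult natural mortality (1/yr)
    f_base = NA_real_,   # derived: relative consumption at baseline prey
    X0 = Xh_o, N0 = NA_real_
  )

  # baseline functional response and predation mortalities at the
  # unfished design point
  D <- halibut$Cmax + halibut$alpha_a * Xa_o + halibut$alpha_s * Xs_o + halibut$Y
  halibut$f_base <- (halibut$alpha_a * Xa_o + halibut$alpha_s * Xs_o + halibut$Y) / D
  P_a <- halibut$Cmax * halibut$alpha_a * Xh_o / D
  P_s <- halibut$Cmax * halibut$alpha_s * Xh_o / D

  forage <- function(M, P, w_r, w_inf, kappa, eta, X0) {
    r_bar <- M + P  # numbers equilibrium: recruitment balances mortality
    m_bar <- (r_bar * w_r + kappa * w_inf) / (r_bar + kappa)
    list(
      r_bar = r_bar,   # derived mean per-capita recruitment (1/yr)
      A = 0.3,         # recruitment amplitude under variability forcing
      p = 25,          # recruitment period (yr)
      s = 0,           # phase start (degrees)
      w_r = w_r, w_inf = w_inf, kappa = kappa, M = M, eta = eta,
      X0 = X0, N0 = X0 / m_bar
    )
  }
  anchovy <- forage(M = 0.6, P = P_a, w_r = 8, w_inf = 30, kappa = 0.4,
                    eta = 1, X0 = Xa_o)
  sardine <- forage(M = 0.4, P = P_s, w_r = 20, w_inf = 90, kappa = 0.3,
                    eta = 1, X0 = Xs_o)

  # halibut steady state: mean mass from the biomass balance, then the
  # Beverton-Holt slope that reproduces it
  m_h <- (halibut$M * halibut$w_r + halibut$kappa * halibut$w_inf0) /
    (halibut$kappa + halibut$M)
  halibut$N0 <- Xh_o / m_h
  R_star <- halibut$M * halibut$N0
  halibut$a <- R_star * exp(halibut$M_j * halibut$tau) *
    (1 + halibut$b * Xh_o) / Xh_o

  pelican <- list(
    Mbar = 0.18,                   # adult mortality, prey abundant (1/yr)
    tau_bp = 4,                    # age at maturation (yr)
    Phi = 3,                       # maximum-productivity factor (>= 1)
    K_bp = 100,                    # index at which all females fledge one chick
    z = NA_real_,                  # derived: productivity peak at 0.6 K_bp
    theta_r = c(0.3, 0.12, 0.5),   # reproduction prey-response (theta1,2,3)
    theta_s = c(0.1, 0.04, 0.5),   # survival prey-response (theta1,2,3)
    Gamma_a = 0.3, Gamma_s = 0.5, Gamma_other = 0.2,  # baseline diet
    Xa_o = Xa_o, Xs_o = Xs_o,      # unfished long-run forage means (t)
    N0 = 100,                      # index: 100 percent of current level
    phi_floor = 1e-6               # survival-scalar floor (finite mortality)
  )
  pelican$z <- solve_z(pelican$Mbar, pelican$tau_bp, pelican$Phi)

  econ <- list(
    anchovy = list(p_tilde = 0.12, q = 5e-4, c1 = 12.0, c2 = 0.036),
    sardine = list(p_tilde = 0.15, q = 5e-4, c1 = 13.5, c2 = 0.026),
    halibut = list(p_tilde = 8.00, q = 5e-4, c1 = 48.0, c2 = 0.140),
    delta = 0.05
  )

  policy <- list(
    hcr_cutoff = 150000, hcr_cap = 200000, hcr_share = 0.87,
    hcr_f0 = 0.0465824, hcr_f1 = 0.06224328,
    hs_lower = 0.4, hs_upper = 0.8, hs_fmax_mult = 0.5
  )

  settings <- list(
    kappa_in_numbers_loss = FALSE,  # growth does not remove individuals
    lagged_reproduction_prey = TRUE # phi_r evaluated at lagged depletion
  )

  out <- structure(
    list(anchovy = anchovy, sardine = sardine, halibut = halibut,
         pelican = pelican, econ = econ, policy = policy,
         settings = settings),
    class = "fw_params")
  validate_params(out)
  out
}

#' Pelican density-dependence exponent
#'
#' Finds the exponent `z` of the density-dependent fledging multiplier
#' `1 + (Phi - 1) * (1 - (N/K)^z)` such that total net productivity
#' (recruitment minus adult mortality, with the prey-response scalar at
#' one) is greatest at `peak` times `K_bp`.
#'
#' @param Mbar adult mortality rate when prey are abundant (1/yr).
#' @param tau_bp age at maturation (yr).
#' @param Phi maximum-productivity factor (>= 1).
#' @param peak location of the productivity maximum as a fraction of
#'   `K_bp` (default 0.6).
#' @return The exponent `z` (scalar).
#' @export
solve_z <- function(Mbar, tau_bp, Phi, peak = 0.6) {
  beta <- 0.5 * exp(-Mbar * tau_bp)
  # d/dN of N * (beta * (1 + (Phi-1)(1 - u^z)) - Mbar) at u = peak
  dG <- function(z) {
    u <- peak^z
    beta * (1 + (Phi - 1) * (1 - u)) - beta * (Phi - 1) * z * u - Mbar
  }
  # prefer the compensatory (z > 1) root when it exists
  grid <- c(1, 2, 5, 10, 25, 50)
  for (i in seq_len(length(grid) - 1)) {
    if (dG(grid[i]) * dG(grid[i + 1]) < 0) {
      return(uniroot(dG, c(grid[i], grid[i + 1]), tol = 1e-10)$root)
    }
  }
  if (dG(1e-3) * dG(1) < 0) {
    return(uniroot(dG, c(1e-3, 1), tol = 1e-10)$root)
  }
  stop("no exponent z places the productivity peak at ", peak,
       " * K_bp for these Pelican vital rates", call. = FALSE)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of an `fw_params` object (rate
#' non-negativity, recruit mass below asymptotic mass, diet fractions
#' summing to one, prey-response parameter ranges, positive quadratic
#' effort costs, ordered hockey-stick knots). Errors name the offending
#' field.
#'
#' @param params an `fw_params` object.
#' @return `params`, invisibly, if all invariants hold.
#' @export
validate_params <- function(params) {
  fail <- function(field, msg) {
    stop("invalid parameter `", field, "`: ", msg, call. = FALSE)
  }
  need_nonneg <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
      fail(field, "must be a non-negative number")
    }
  }
  for (sp in c("anchovy", "sardine")) {
    fp <- params[[sp]]
    for (f in c("r_bar", "A", "w_r", "w_inf", "kappa", "M", "eta",
                "X0", "N0")) {
      need_nonneg(fp[[f]], paste0(sp, "$", f))
    }
    if (fp$p <= 0) fail(paste0(sp, "$p"), "recruitment period must be > 0")
    if (fp$w_r > fp$w_inf) {
      fail(paste0(sp, "$w_r"), "recruit mass exceeds asymptotic mass")
    }
  }
  hp <- params$halibut
  for (f in c("a", "b", "M_j", "tau", "kappa", "w_r", "w_inf0", "Cmax",
              "alpha_a", "alpha_s", "Y", "M", "X0", "N0")) {
    need_nonneg(hp[[f]], paste0("halibut$", f))
  }
  if (hp$w_r > hp$w_inf0) {
    fail("halibut$w_r", "recruit mass exceeds asymptotic mass")
  }
  pp <- params$pelican
  for (f in c("Mbar", "tau_bp", "K_bp", "z", "Gamma_a", "Gamma_s",
              "Gamma_other", "Xa_o", "Xs_o", "N0")) {
    need_nonneg(pp[[f]], paste0("pelican$", f))
  }
  if (pp$Phi < 1) fail("pelican$Phi", "must be >= 1")
  dietsum <- pp$Gamma_a + pp$Gamma_s + pp$Gamma_other
  if (abs(dietsum - 1) > 1e-8) {
    fail("pelican$Gamma_a/Gamma_s/Gamma_other",
         sprintf("diet fractions must sum to 1 (got %.6f)", dietsum))
  }
  for (th in c("theta_r", "theta_s")) {
    v <- pp[[th]]
    if (length(v) != 3) fail(paste0("pelican$", th), "must have length 3")
    if (v[1] < 0 || v[1] >= 1) {
      fail(paste0("pelican$", th, "[1]"), "must lie in [0, 1)")
    }
    if (v[2] < 0 || v[2] >= 1 || v[3] <= 0 || v[3] >= 1) {
      fail(paste0("pelican$", th),
           "steepness parameters must lie in [0, 1) and (0, 1)")
    }
  }
  for (sp in c("anchovy", "sardine", "halibut")) {
    ec <- params$econ[[sp]]
    for (f in c("p_tilde", "q", "c1", "c2")) {
      need_nonneg(ec[[f]], paste0("econ$", sp, "$", f))
    }
    if (ec$c2 <= 0) {
      fail(paste0("econ$", sp, "$c2"),
           "quadratic effort cost must be > 0 for an interior optimum")
    }
  }
  need_nonneg(params$econ$delta, "econ$delta")
  pc <- params$policy
  for (f in names(pc)) need_nonneg(pc[[f]], paste0("policy$", f))
  if (pc$hs_lower >= pc$hs_upper) {
    fail("policy$hs_lower", "hockey-stick lower knot must be below upper")
  }
  invisible(params)
}

#' Load a calibration from a YAML config file
#'
#' Reads a structured YAML file and overrides the default calibration
#' field-by-field, so an external parameterization (e.g. published
#' appendix values) can be substituted verbatim. Sections and keys must
#' match the structure of [default_parameters()] (`anchovy`, `sardine`,
#' `halibut`, `pelican`, `econ` with per-species subsections plus
#' `delta`, `policy`, `settings`); unknown sections or keys are rejected.
#' The merged set is validated before being returned.
#'
#' @param path path to a YAML config file. An empty file yields the
#'   defaults unchanged.
#' @param base parameter set to override (default [default_parameters()]).
#' @return An `fw_params` object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("econ:\n  delta: 0.10", cfg)
#' load_config(cfg)$econ$delta
#' @export
load_config <- function(path, base = default_parameters()) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a keyed YAML mapping", call. = FALSE)
  merged <- merge_strict(unclass(base), cfg, path = character())
  out <- structure(merged, class = "fw_params")
  validate_params(out)
  out
}

# recursive override that rejects keys absent from the base structure
merge_strict <- function(base, override, path) {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == "")) {
    stop("config entries under `", paste(path, collapse = "$"),
         "` must all be named", call. = FALSE)
  }
  for (k in nm) {
    here <- c(path, k)
    if (!k %in% names(base)) {
      stop("unknown config key: ", paste(here, collapse = "$"),
           call. = FALSE)
    }
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]])) {
        stop("config key ", paste(here, collapse = "$"),
             " must be a mapping", call. = FALSE)
      }
      base[[k]] <- merge_strict(base[[k]], override[[k]], here)
    } else {
      val <- override[[k]]
      if (is.list(val)) val <- unlist(val)
      if (length(val) != length(base[[k]])) {
        stop("config key ", paste(here, collapse = "$"), " must have length ",
             length(base[[k]]), call. = FALSE)
      }
      base[[k]] <- val
    }
  }
  base
}

#' @export
print.fw_params <- function(x, ...) {
  cat("<fw_params> stand-in food-web calibration\n")
  cat(sprintf("  forage: anchovy X0 = %g t, sardine X0 = %g t\n",
              x$anchovy$X0, x$sardine$X0))
  cat(sprintf("  halibut: X0 = %g t; pelican: N0 = %g (index), z = %.3f\n",
              x$halibut$X0, x$pelican$N0, x$pelican$z))
  cat(sprintf("  discount rate delta = %g /yr\n", x$econ$delta))
  invisible(x)
}
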