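# Process rates and right-hand sides of the population dynamics.
#
# State vector order used throughout: (Xa, Na, Xs, Ns, Xh, Nh, Nbp).
# Sign conventions: losses (natural mortality, predation, fishing) enter
# negatively; biomass gains are recruit mass inflow r * w_r * N plus
# delay-difference somatic growth kappa * (w_inf * N - X). Growth does not
# remove individuals, so kappa is excluded from the numbers loss term
# unless settings$kappa_in_numbers_loss is set.

state_names <- c("Xa", "Na", "Xs", "Ns", "Xh", "Nh", "Nbp")

#' Type-II predation mortality on the forage species
#'
#' Per-capita predation mortality inflicted by halibut on each forage
#' species through a multi-prey Type-II functional response,
#' \deqn{P_i = C_{max} \alpha_i X_h / (C_{max} + \alpha_a X_a +
#' \alpha_s X_s + Y).}
#' The shared denominator produces prey-switching buffering: mortality on
#' one prey falls when the other prey becomes more abundant. Predation by
#' Pelicans on the forage stocks is neglected (it is a minor share of
#' forage mortality).
#'
#' @param Xa,Xs,Xh biomasses (t), non-negative.
#' @param hp halibut parameter list (see [default_parameters()]).
#' @return Named numeric vector `c(Pa, Ps)` of per-capita rates (1/yr).
#' @export
predation_mortality <- function(Xa, Xs, Xh, hp) {
  D <- hp$Cmax + hp$alpha_a * Xa + hp$alpha_s * Xs + hp$Y
  c(Pa = hp$Cmax * hp$alpha_a * Xh / D,
    Ps = hp$Cmax * hp$alpha_s * Xh / D)
}

#' Halibut Beverton-Holt recruitment
#'
#' Recruitment into the fishable halibut stock from the lagged spawning
#' biomass, discounted for density-independent pre-recruit mortality over
#' the maturation delay:
#' \deqn{R = a X_h(t-\tau) / (1 + b X_h(t-\tau)) \cdot e^{-M_j \tau}.}
#'
#' @param Xh_lag halibut biomass `tau` years ago (t).
#' @param hp halibut parameter list.
#' @return Recruitment rate (millions of recruits / yr).
#' @export
halibut_recruitment <- function(Xh_lag, hp) {
  hp$a * Xh_lag / (1 + hp$b * Xh_lag) * exp(-hp$M_j * hp$tau)
}

#' Consumption-dependent halibut asymptotic mass
#'
#' Generalized von Bertalanffy energetics: the asymptotic mass scales
#' with relative realized consumption,
#' \deqn{w_\infty = w_{\infty 0} (f / f_{base})^{\gamma_w}, \quad
#'   f = (\alpha_a X_a + \alpha_s X_s + Y) /
#'       (C_{max} + \alpha_a X_a + \alpha_s X_s + Y),}
#' normalized so that prey at their unfished baseline gives exactly
#' `w_inf0`. Non-decreasing in each prey biomass.
#'
#' @param Xa,Xs forage biomasses (t).
#' @param hp halibut parameter list.
#' @return Asymptotic mass (g).
#' @export
halibut_asymptotic_mass <- function(Xa, Xs, hp) {
  avail <- hp$alpha_a * Xa + hp$alpha_s * Xs + hp$Y
  f <- avail / (hp$Cmax + avail)
  hp$w_inf0 * (f / hp$f_base)^hp$gamma_w
}

#' Pelican forage-depletion index
#'
#' Diet-weighted forage biomass relative to the unfished long-run
#' baselines, \eqn{d = \Gamma_a X_a/X_{ao} + \Gamma_s X_s/X_{so} +
#' \Gamma_{other}}. Equals 1 when both forage stocks sit at their
#' unfished means; the "other prey" diet share is assumed constant.
#'
#' @param Xa,Xs forage biomasses (t).
#' @param pp Pelican parameter list.
#' @return The depletion index (dimensionless).
#' @export
pelican_depletion <- function(Xa, Xs, pp) {
  if (pp$Xa_o <= 0 || pp$Xs_o <= 0) {
    stop("unfished baselines Xa_o, Xs_o must be positive", call. = FALSE)
  }
  pp$Gamma_a * Xa / pp$Xa_o + pp$Gamma_s * Xs / pp$Xs_o + pp$Gamma_other
}

#' Saturating prey-response scalar
#'
#' Shared functional form for the effect of prey availability on Pelican
#' reproduction and adult survival. Zero for depletion `d` at or below
#' `theta[1]` (the largest depletion at which reproductive success is
#' zero), then rises along a saturating curve whose steepness is governed
#' by `theta[2]` and `theta[3]`, approaching 1 as `d` grows:
#' \deqn{\phi(d) = \frac{\theta_3 (1-\theta_1-\theta_2)(d-\theta_1)}
#' {(1-\theta_1)\theta_2(1-\theta_3) + \theta_3(1-\theta_1-\theta_2)(d-\theta_1)}}
#' clamped to `[0, 1]`. Setting `theta[2] = 0` makes the response
#' identically 1 above `theta[1]`, decoupling the vital rate from prey.
#'
#' @param d depletion index (scalar or vector).
#' @param theta numeric length-3 vector `(theta1, theta2, theta3)` with
#'   `theta1` in `[0, 1)`, `theta2` in `[0, 1)`, `theta3` in `(0, 1)`.
#' @return Scalar(s) in `[0, 1]`, non-decreasing in `d`.
#' @export
prey_response <- function(d, theta) {
  if (length(theta) != 3 || theta[1] < 0 || theta[1] >= 1 ||
      theta[2] < 0 || theta[2] >= 1 || theta[3] <= 0 || theta[3] >= 1) {
    stop("prey-response parameters out of range: theta1 in [0,1), ",
         "theta2 in [0,1), theta3 in (0,1)", call. = FALSE)
  }
  x <- d - theta[1]
  num <- theta[3] * (1 - theta[1] - theta[2]) * x
  den <- (1 - theta[1]) * theta[2] * (1 - theta[3]) + num
  out <- ifelse(x <= 0 | den <= 0, 0, num / den)
  pmin(pmax(out, 0), 1)
}

#' Pelican reproduction (fledged female chicks)
#'
#' Density-dependent fledging from the lagged breeding population,
#' reduced by the prey-response scalar:
#' \deqn{R_{bp} = 0.5 e^{-\bar M \tau_{bp}} N_{bp}(t-\tau_{bp}) \phi_r
#' \left[1 + (\Phi-1)\left(1 - (N_{bp}(t-\tau_{bp})/K_{bp})^z\right)\right]_+.}
#' The factor 0.5 reflects that only females are modeled;
#' \eqn{e^{-\bar M \tau_{bp}}} is survival through the pre-breeding
#' years (held at the prey-abundant rate); the bracketed density factor
#' equals \eqn{\Phi} as the population vanishes and 1 at `K_bp`, the
#' abundance at which every female fledges one chick.
#'
#' @param Nbp_lag Pelican index `tau_bp` years ago.
#' @param phi_r reproduction prey-response scalar in `[0, 1]`.
#' @param pp Pelican parameter list.
#' @return Recruitment rate (index units / yr).
#' @export
pelican_reproduction <- function(Nbp_lag, phi_r, pp) {
  if (Nbp_lag < 0 || phi_r < 0 || phi_r > 1) {
    stop("Nbp_lag must be >= 0 and phi_r in [0, 1]", call. = FALSE)
  }
  dens <- pmax(0, 1 + (pp$Phi - 1) * (1 - (Nbp_lag / pp$K_bp)^pp$z))
  0.5 * exp(-pp$Mbar * pp$tau_bp) * Nbp_lag * phi_r * dens
}

#' Pelican adult mortality rate
#'
#' Adult mortality rises as the survival prey-response scalar falls:
#' \eqn{M_{bp} = \bar M - \log \phi_v(d)}. Equals the prey-abundant rate
#' `Mbar` when the scalar is 1; the scalar is floored at
#' `pp$phi_floor` so the rate stays finite and extinction is approached
#' dynamically rather than through a singularity.
#'
#' @param d current depletion index.
#' @param pp Pelican parameter list.
#' @return Mortality rate (1/yr).
#' @export
pelican_mortality_rate <- function(d, pp) {
  phi_v <- prey_response(d, pp$theta_s)
  pp$Mbar - log(pmax(phi_v, pp$phi_floor))
}

#' Forage-species derivatives
#'
#' Right-hand sides of the forage biomass/numbers dynamics for both
#' species at a given state, time and fishing mortalities:
#' \deqn{dN_i/dt = [r_i(t) - (M_i + P_i + F_i)] N_i,}
#' \deqn{dX_i/dt = r_i(t) w_{i,r} N_i + \kappa_i (w_{i,\infty} N_i - X_i)
#'   - (M_i + P_i + F_i) X_i.}
#'
#' @param state named numeric vector with at least `Xa`, `Na`, `Xs`,
#'   `Ns`, `Xh`; all non-negative.
#' @param t time (yr).
#' @param F_a,F_s fishing mortality rates (1/yr), non-negative.
#' @param params an `fw_params` object.
#' @return Named list with `anchovy = c(dX, dN)` and `sardine = c(dX, dN)`.
#' @export
forage_derivatives <- function(state, t, F_a, F_s, params) {
  if (any(state[c("Xa", "Na", "Xs", "Ns", "Xh")] < 0)) {
    stop("state variables must be non-negative", call. = FALSE)
  }
  if (F_a < 0 || F_s < 0) stop("fishing mortality must be >= 0", call. = FALSE)
  P <- predation_mortality(state[["Xa"]], state[["Xs"]], state[["Xh"]],
                           params$halibut)
  one <- function(sp, P_i, F_i, X, N) {
    fp <- params[[sp]]
    r <- recruitment_rate(t, fp)
    loss <- fp$M + P_i + F_i
    c(dX = r * fp$w_r * N + fp$kappa * (fp$w_inf * N - X) - loss * X,
      dN = (r - loss) * N)
  }
  list(anchovy = one("anchovy", P[["Pa"]], F_a, state[["Xa"]], state[["Na"]]),
       sardine = one("sardine", P[["Ps"]], F_s, state[["Xs"]], state[["Ns"]]))
}

#' Halibut derivatives
#'
#' Right-hand side of the halibut delay-recruitment dynamics:
#' \deqn{dN_h/dt = R(X_h(t-\tau)) - (M_h + F_h) N_h,}
#' \deqn{dX_h/dt = R(X_h(t-\tau)) w_r + \kappa (w_\infty(X_a, X_s) N_h -
#'   X_h) - (M_h + F_h) X_h.}
#' With `params$settings$kappa_in_numbers_loss` set, `kappa` is added to
#' the numbers loss as well (an alternative reading of the numbers
#' equation); the default excludes it since somatic growth does not
#' remove individuals.
#'
#' @param state named numeric vector with `Xa`, `Xs`, `Xh`, `Nh`.
#' @param t time (yr), unused by the autonomous rates but kept for a
#'   uniform signature.
#' @param lagged_Xh halibut biomass `tau` years ago (t).
#' @param F_h fishing mortality (1/yr).
#' @param params an `fw_params` object.
#' @return Named vector `c(dX, dN)`.
#' @export
halibut_derivatives <- function(state, t, lagged_Xh, F_h, params) {
  if (any(state[c("Xa", "Xs", "Xh", "Nh")] < 0) || lagged_Xh < 0) {
    stop("state variables must be non-negative", call. = FALSE)
  }
  if (F_h < 0) stop("fishing mortality must be >= 0", call. = FALSE)
  hp <- params$halibut
  R <- halibut_recruitment(lagged_Xh, hp)
  w_inf <- halibut_asymptotic_mass(state[["Xa"]], state[["Xs"]], hp)
  loss_N <- hp$M + F_h +
    if (isTRUE(params$settings$kappa_in_numbers_loss)) hp$kappa else 0
  c(dX = R * hp$w_r + hp$kappa * (w_inf * state[["Nh"]] - state[["Xh"]]) -
      (hp$M + F_h) * state[["Xh"]],
    dN = R - loss_N * state[["Nh"]])
}

#' Pelican derivative
#'
#' Right-hand side of the Pelican index dynamics: reproduction from the
#' lagged breeding population with the prey response evaluated at lagged
#' (default) or current depletion, minus prey-dependent adult mortality
#' at the current depletion:
#' \deqn{dN_{bp}/dt = R_{bp}(\cdot) - M_{bp}(X_a(t), X_s(t)) N_{bp}(t).}
#'
#' @param state named numeric vector with `Xa`, `Xs`, `Nbp`.
#' @param t time (yr).
#' @param lagged named list/vector with `Xa`, `Xs`, `Nbp` evaluated
#'   `tau_bp` years ago.
#' @param params an `fw_params` object.
#' @return `dNbp` (scalar).
#' @export
pelican_derivative <- function(state, t, lagged, params) {
  pp <- params$pelican
  if (state[["Nbp"]] < 0 || lagged[["Nbp"]] < 0) {
    stop("Pelican index must be non-negative", call. = FALSE)
  }
  d_now <- pelican_depletion(state[["Xa"]], state[["Xs"]], pp)
  d_rep <- if (isTRUE(params$settings$lagged_reproduction_prey)) {
    pelican_depletion(lagged[["Xa"]], lagged[["Xs"]], pp)
  } else {
    d_now
  }
  phi_r <- prey_response(d_rep, pp$theta_r)
  R_bp <- pelican_reproduction(lagged[["Nbp"]], phi_r, pp)
  R_bp - pelican_mortality_rate(d_now, pp) * state[["Nbp"]]
}
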