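# Profit flows, the open-access closure and discounted value accounting.

#' Instantaneous fishing profit
#'
#' Quadratic-in-effort profit flow for one fishery,
#' \eqn{\Psi = (\tilde p q X - c_1 - c_2 E) E}: revenue proportional to
#' biomass and effort, minus linear and quadratic effort costs.
#'
#' @param X stock biomass (t); vectorized.
#' @param E fishing effort (>= 0); vectorized.
#' @param ec economic parameter list with `p_tilde`, `q`, `c1`, `c2`.
#' @return Profit flow (currency/yr).
#' @export
profit <- function(X, E, ec) {
  (ec$p_tilde * ec$q * X - ec$c1 - ec$c2 * E) * E
}

#' Open-access effort closure
#'
#' Effort in an unmanaged fishery adjusts instantaneously until average
#' profit \eqn{\Psi/E} is zero:
#' \eqn{E_{oa} = \max\{0, (\tilde p q X - c_1)/c_2\}}. Below the
#' break-even biomass \eqn{c_1/(\tilde p q)} the fishery is idle.
#'
#' @param X stock biomass (t); vectorized.
#' @param ec economic parameter list (requires `c2 > 0`).
#' @return Open-access effort (>= 0).
#' @export
open_access_effort <- function(X, ec) {
  if (ec$c2 <= 0) {
    stop("open-access closure undefined for c2 <= 0", call. = FALSE)
  }
  pmax(0, (ec$p_tilde * ec$q * X - ec$c1) / ec$c2)
}

#' Net present value of a trajectory
#'
#' Discounted integral of total fishing profit along a simulated
#' trajectory, \eqn{J = \int_0^T e^{-\delta t} \sum_i \Psi_i\, dt},
#' evaluated by trapezoidal quadrature on the trajectory's dense time
#' grid, with the per-species components reported separately. Optionally
#' adds a steady-flow salvage term \eqn{e^{-\delta T} \Psi_i(T)/\delta}
#' approximating continuation beyond the horizon.
#'
#' @param traj an `fw_trajectory` (from [simulate()]), carrying effort
#'   columns `Ea`, `Es`, `Eh`.
#' @param params the `fw_params` used (defaults to the trajectory's
#'   attached parameters).
#' @param delta discount rate (1/yr); defaults to `params$econ$delta`.
#' @param salvage add the continuation term at the terminal time?
#' @return A tibble with columns `species` (`anchovy`, `sardine`,
#'   `halibut`, `total`) and `npv`.
#' @export
npv <- function(traj, params = attr(traj, "params"),
                delta = params$econ$delta, salvage = FALSE) {
  t <- traj$t
  disc <- exp(-delta * t)
  cols <- list(anchovy = c("Xa", "Ea"), sardine = c("Xs", "Es"),
               halibut = c("Xh", "Eh"))
  vals <- vapply(names(cols), function(sp) {
    X <- pmax(traj[[cols[[sp]][1]]], 0)
    E <- pmax(traj[[cols[[sp]][2]]], 0)
    psi <- profit(X, E, params$econ[[sp]])
    J <- trapz(t, disc * psi)
    if (salvage) {
      n <- length(t)
      J <- J + disc[n] * psi[n] / delta
    }
    J
  }, numeric(1))
  tibble::tibble(species = c(names(cols), "total"),
                 npv = unname(c(vals, sum(vals))))
}

# trapezoidal quadrature on an arbitrary grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
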