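# Post-processing: long-run levels, conservation gains, elasticities,
# crossing times and cross-regime summary tables.

#' Long-run averaging window for a scenario
#'
#' "Long-run" is operationalized as the final full recruitment period of
#' the horizon under variability forcing, and the final 10 years (capped
#' at 20 percent of the horizon) under constant forcing.
#'
#' @param scenario an `fw_scenario`.
#' @return Length of the trailing averaging window (yr).
#' @export
longrun_window <- function(scenario) {
  if (scenario$forcing$mode == "constant") {
    return(min(10, 0.2 * scenario$T))
  }
  p <- max(scenario$params$anchovy$p, scenario$params$sardine$p)
  min(p, scenario$T)
}

#' Long-run level of a trajectory variable
#'
#' Mean of a state variable over the trailing window of the trajectory.
#'
#' @param traj an `fw_trajectory`.
#' @param var column name (default `"Nbp"`).
#' @param window trailing window length (yr); defaults to 20 percent of
#'   the span.
#' @return Scalar mean level.
#' @export
longrun_level <- function(traj, var = "Nbp", window = NULL) {
  tmax <- max(traj$t)
  if (is.null(window)) window <- 0.2 * tmax
  sel <- traj$t >= tmax - window
  mean(traj[[var]][sel])
}

#' Long-run Pelican gain relative to a baseline run
#'
#' Percent increase in the long-run Pelican level of a managed run over
#' an all-open-access baseline sharing the same forcing and horizon.
#'
#' @param traj trajectory of the evaluated regime (or an `fw_solution`).
#' @param baseline trajectory of the baseline (all fisheries open
#'   access), or an `fw_solution`.
#' @param window trailing averaging window (yr), shared by both runs.
#' @return Percent gain (scalar; 30 means a 30 percent higher long-run
#'   Pelican level).
#' @export
longrun_pelican_gain <- function(traj, baseline, window = NULL) {
  if (inherits(traj, "fw_solution")) traj <- traj$trajectory
  if (inherits(baseline, "fw_solution")) baseline <- baseline$trajectory
  L1 <- longrun_level(traj, "Nbp", window)
  L0 <- longrun_level(baseline, "Nbp", window)
  if (L0 == 0) stop("baseline long-run Pelican level is zero", call. = FALSE)
  100 * (L1 - L0) / L0
}

#' Pelican life-years
#'
#' Undiscounted time-integral of the Pelican index over the horizon,
#' \eqn{TN_{bp} = \int_0^T N_{bp}(t)\,dt} (trapezoidal quadrature on the
#' trajectory grid).
#'
#' @param traj an `fw_trajectory` (or `fw_solution`).
#' @return Pelican life-years (index-years).
#' @export
pelican_life_years <- function(traj) {
  if (inherits(traj, "fw_solution")) traj <- traj$trajectory
  trapz(traj$t, traj$Nbp)
}

#' Elasticity of net present value to Pelican life-years
#'
#' Percent NPV forgone per percent of Pelican life-years gained when the
#' conservation floor is imposed:
#' \deqn{\epsilon = \frac{(J_{unc} - J_{con})/J_{unc}}
#'                       {(TN_{con} - TN_{unc})/TN_{unc}}.}
#' Both numerator and denominator are taken positive (the constraint
#' costs value and buys Pelican life-years), so an elasticity above one
#' reads as a more-than-1-percent value loss per percent of Pelican
#' gain.
#'
#' @param J_unc,J_con objective values without/with the floor
#'   (`J_unc > 0`).
#' @param TN_unc,TN_con Pelican life-years without/with the floor
#'   (`TN_con >= TN_unc > 0`; equality is degenerate and errors).
#' @return The elasticity (scalar).
#' @export
elasticity <- function(J_unc, J_con, TN_unc, TN_con) {
  if (J_unc <= 0) stop("unconstrained NPV must be positive", call. = FALSE)
  if (TN_unc <= 0) stop("Pelican life-years must be positive", call. = FALSE)
  if (TN_con == TN_unc) {
    stop("constraint did not change Pelican life-years: ",
         "elasticity undefined", call. = FALSE)
  }
  ((J_unc - J_con) / J_unc) / ((TN_con - TN_unc) / TN_unc)
}

#' Constraint crossing and anticipation times
#'
#' `T_cross` is the first time the unconstrained trajectory's Pelican
#' index falls below the floor (`Inf` if never). `T_change` is the first
#' time any species' constrained effort deviates from its unconstrained
#' effort by more than 1 percent relative (with a small absolute effort
#' floor `eps0` to ignore noise around zero effort). Anticipatory
#' management shows up as `T_change < T_cross`.
#'
#' @param unconstrained,constrained trajectories on a common time grid
#'   (or `fw_solution`s).
#' @param floor the Pelican floor.
#' @param rel relative effort-divergence threshold (default 0.01).
#' @param eps0 absolute effort floor in the relative comparison.
#' @return A list with `T_cross` and `T_change` (yr, possibly `Inf`).
#' @export
crossing_times <- function(unconstrained, constrained, floor,
                           rel = 0.01, eps0 = 1e-6) {
  if (inherits(unconstrained, "fw_solution")) {
    unconstrained <- unconstrained$trajectory
  }
  if (inherits(constrained, "fw_solution")) {
    constrained <- constrained$trajectory
  }
  if (nrow(unconstrained) != nrow(constrained) ||
      max(abs(unconstrained$t - constrained$t)) > 1e-9) {
    stop("trajectories must share a common time grid", call. = FALSE)
  }
  t <- unconstrained$t
  below <- unconstrained$Nbp < floor
  T_cross <- if (any(below)) t[which(below)[1]] else Inf
  div <- rep(FALSE, length(t))
  for (col in c("Ea", "Es", "Eh")) {
    ref <- pmax(unconstrained[[col]], eps0)
    div <- div | (abs(constrained[[col]] - unconstrained[[col]]) / ref > rel)
  }
  T_change <- if (any(div)) t[which(div)[1]] else Inf
  list(T_cross = T_cross, T_change = T_change)
}

#' Scale a trajectory's biomasses off the initial conditions
#'
#' Long-format tibble of `X(t)/X(0)` for the three fished stocks plus
#' the Pelican index relative to its initial level, the form used for
#' cross-regime comparison plots.
#'
#' @param traj an `fw_trajectory`.
#' @return Tibble with columns `t`, `series`, `value`.
#' @export
scale_trajectory <- function(traj) {
  take <- c(anchovy = "Xa", sardine = "Xs", halibut = "Xh",
            pelican = "Nbp")
  purrr::map_dfr(names(take), function(nm) {
    v <- traj[[take[[nm]]]]
    tibble::tibble(t = traj$t, series = nm, value = v / v[1])
  })
}

#' Cross-regime comparison table
#'
#' Summarizes a sweep of solved or simulated regimes into one tidy row
#' per regime-by-forcing cell: total and per-species NPV, the long-run
#' Pelican level, and (where the matching all-open-access baseline is
#' present in the sweep) the percent long-run Pelican gain. Cells listed
#' in the input but missing a result are reported with `NA`s rather than
#' dropped; missing baselines are flagged in a message.
#'
#' @param results a list of `fw_solution`s and/or `fw_trajectory`s. Each
#'   element needs a regime and forcing identity: solutions carry their
#'   scenario; bare trajectories use their names in the list, formatted
#'   `"<regime>/<forcing>"`.
#' @param window trailing long-run averaging window (yr); default from
#'   each scenario via [longrun_window()] where available.
#' @return A tibble with columns `regime`, `forcing`, `J`,
#'   `npv_anchovy`, `npv_sardine`, `npv_halibut`, `longrun_Nbp`,
#'   `pelican_gain_vs_OA` (percent).
#' @export
summary_report <- function(results, window = NULL) {
  parse_one <- function(x, nm) {
    if (inherits(x, "fw_solution")) {
      sc <- x$scenario
      win <- if (is.null(window)) longrun_window(sc) else window
      v <- setNames(x$npv$npv, x$npv$species)
      tibble::tibble(
        regime = sc$regime$label, forcing = sc$forcing$mode,
        J = x$J, npv_anchovy = v[["anchovy"]],
        npv_sardine = v[["sardine"]], npv_halibut = v[["halibut"]],
        longrun_Nbp = longrun_level(x$trajectory, "Nbp", win))
    } else if (inherits(x, "fw_trajectory")) {
      parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("name trajectory entries as '<regime>/<forcing>': ", nm,
             call. = FALSE)
      }
      params <- attr(x, "params")
      v <- setNames(npv(x, params)$npv, npv(x, params)$species)
      tibble::tibble(
        regime = parts[1], forcing = parts[2],
        J = v[["total"]], npv_anchovy = v[["anchovy"]],
        npv_sardine = v[["sardine"]], npv_halibut = v[["halibut"]],
        longrun_Nbp = longrun_level(x, "Nbp", window))
    } else if (is.null(x)) {
      parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
      tibble::tibble(regime = parts[1], forcing = parts[2],
                     J = NA_real_, npv_anchovy = NA_real_,
                     npv_sardine = NA_real_, npv_halibut = NA_real_,
                     longrun_Nbp = NA_real_)
    } else {
      stop("unsupported result type for entry ", nm, call. = FALSE)
    }
  }
  nms <- names(results)
  if (is.null(nms)) nms <- rep("", length(results))
  tab <- purrr::map2_dfr(results, nms, parse_one)
  tab <- dplyr::group_by(tab, .data$forcing)
  tab <- dplyr::mutate(
    tab,
    pelican_gain_vs_OA = {
      base <- .data$longrun_Nbp[.data$regime == "OA_all"]
      if (length(base) == 1 && !is.na(base) && base > 0) {
        100 * (.data$longrun_Nbp - base) / base
      } else {
        NA_real_
      }
    })
  tab <- dplyr::ungroup(tab)
  missing_base <- unique(tab$forcing[is.na(tab$pelican_gain_vs_OA) &
                                       !is.na(tab$longrun_Nbp)])
  if (length(missing_base)) {
    message("no OA_all baseline for forcing(s): ",
            paste(missing_base, collapse = ", "),
            "; gains reported as NA")
  }
  tab
}
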