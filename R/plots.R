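# Plotting and broom-style tidiers.

#' Plot a simulated trajectory
#'
#' Scaled stock biomasses (`X(t)/X(0)`) and the Pelican index relative
#' to its initial level, faceted by series.
#'
#' @param object an `fw_trajectory`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.fw_trajectory <- function(object, ...) {
  dat <- scale_trajectory(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (yr)", y = "level relative to t = 0")
}

#' Plot a solved management regime
#'
#' Two-panel view of a solution: optimized and open-access fishing
#' mortality rates over time, and the scaled stock/Pelican trajectories.
#'
#' @param object an `fw_solution`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.fw_solution <- function(object, ...) {
  traj <- object$trajectory
  eff <- tidyr::pivot_longer(
    dplyr::select(traj, "t", "Fa", "Fs", "Fh"),
    cols = c("Fa", "Fs", "Fh"),
    names_to = "species", values_to = "F")
  eff$species <- c(Fa = "anchovy", Fs = "sardine",
                   Fh = "halibut")[eff$species]
  ggplot2::ggplot(eff,
                  ggplot2::aes(x = .data$t, y = .data$F,
                               colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (yr)", y = "fishing mortality (1/yr)",
                  title = object$scenario$name)
}

#' Bar chart of long-run Pelican gains by regime
#'
#' @param comparison a table from [summary_report()].
#' @return A ggplot object.
#' @export
plot_regime_comparison <- function(comparison) {
  dat <- dplyr::filter(comparison, !is.na(.data$pelican_gain_vs_OA),
                       .data$regime != "OA_all")
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$regime,
                               y = .data$pelican_gain_vs_OA)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~forcing) +
    ggplot2::labs(x = NULL,
                  y = "long-run Pelican gain vs open access (%)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solved regime
#'
#' One row per fished species: NPV contribution, mean fishing mortality
#' and the share of the horizon with the fishery closed (effort below
#' 0.1 percent of its maximum).
#'
#' @param x an `fw_solution`.
#' @param ... ignored.
#' @return A tibble.
#' @export
tidy.fw_solution <- function(x, ...) {
  traj <- x$trajectory
  cols <- c(anchovy = "Fa", sardine = "Fs", halibut = "Fh")
  purrr::map_dfr(names(cols), function(sp) {
    Fv <- traj[[cols[[sp]]]]
    thr <- 1e-3 * max(Fv, 1e-12)
    tibble::tibble(
      species = sp,
      role = if (sp %in% x$scenario$regime$optimized) "optimized"
      else if (sp %in% x$scenario$regime$open_access) "open_access"
      else "closed",
      npv = x$npv$npv[x$npv$species == sp],
      mean_F = mean(Fv),
      closed_fraction = mean(Fv <= thr))
  })
}

#' Summarize a solved regime in one row
#'
#' @param x an `fw_solution`.
#' @param ... ignored.
#' @return A one-row tibble with the objective value, status,
#'   verification mismatch, minimum Pelican level and (for constrained
#'   solves) the floor and crossing diagnostics.
#' @export
glance.fw_solution <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario$name,
    status = x$status,
    J = x$J,
    npv_total = x$npv$npv[x$npv$species == "total"],
    min_Nbp = min(x$trajectory$Nbp),
    floor = if (is.null(x$floor)) NA_real_ else x$floor,
    T_cross = if (is.null(x$T_cross)) NA_real_ else x$T_cross,
    T_change = if (is.null(x$T_change)) NA_real_ else x$T_change,
    verify_mismatch = x$diagnostics$verification$mismatch %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
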