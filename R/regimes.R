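# Management regimes, scenarios and the sensitivity suite.

fished_species <- c("anchovy", "sardine", "halibut")

#' Management-regime definitions
#'
#' A regime partitions the three fished species into an optimally managed
#' set, an open-access set and a closed (moratorium) set. The seven
#' optimization regimes combine single-species and joint management
#' (`"H"`, `"S"`, `"A"`, `"H+S"`, `"H+A"`, `"A+S"`, `"A+S+H"`); species not
#' named are open access. `"OA_all"` leaves every fishery unmanaged and
#' `"Moratorium_all"` closes all three. `"Moratorium:<set>"` (e.g.
#' `"Moratorium:A+S"`) closes the named set while the rest operate under
#' open access - the benchmark for the greatest Pelican gain attainable
#' with a given managed set.
#'
#' @param regime a regime label as above.
#' @return A list with character vectors `optimized`, `open_access`,
#'   `closed` and the `label`.
#' @examples
#' regime_definition("A+S")
#' regime_definition("Moratorium:S")
#' @export
regime_definition <- function(regime) {
  stopifnot(is.character(regime), length(regime) == 1)
  parse_set <- function(s) {
    codes <- strsplit(s, "+", fixed = TRUE)[[1]]
    map <- c(A = "anchovy", S = "sardine", H = "halibut")
    if (!all(codes %in% names(map))) {
      stop("unknown species code in regime: ", s, call. = FALSE)
    }
    unname(map[codes])
  }
  if (regime == "OA_all") {
    opt <- character(); closed <- character()
  } else if (regime == "Moratorium_all") {
    opt <- character(); closed <- fished_species
  } else if (grepl("^Moratorium:", regime)) {
    opt <- character()
    closed <- parse_set(sub("^Moratorium:", "", regime))
  } else {
    opt <- parse_set(regime); closed <- character()
  }
  oa <- setdiff(fished_species, union(opt, closed))
  list(optimized = opt, open_access = oa, closed = closed, label = regime)
}

#' The seven optimization regimes
#'
#' @return Character vector of the seven optimally managed regime labels,
#'   from single-species management to the full ecosystem-based regime.
#' @export
optimization_regimes <- function() {
  c("H", "S", "A", "H+S", "H+A", "A+S", "A+S+H")
}

#' Construct a management scenario
#'
#' Bundles a calibration, a recruitment-variability forcing, a management
#' regime, an optional Pelican-floor specification and the planning
#' horizon into a single object consumed by [simulate()] and
#' [solve_regime()].
#'
#' @param params an `fw_params` calibration (default [default_parameters()]).
#' @param forcing a forcing mode string or `fw_forcing` object (default
#'   `"constant"`).
#' @param regime a regime label understood by [regime_definition()].
#' @param psi optional Pelican-floor share in `[0.05, 0.2]`: the floor is
#'   placed `psi` of the way from the unconstrained-optimal long-run
#'   Pelican level up to the no-fishing level (see [pelican_threshold()]).
#' @param T planning horizon (yr). The default 60 keeps the discounted
#'   weight of the neglected tail below five percent at the default
#'   discount rate.
#' @param longrun_T horizon used for unfished long-run averages (yr).
#' @return An object of class `fw_scenario`; its `params` component has
#'   the forcing already applied.
#' @examples
#' sc <- fw_scenario(regime = "A+S", forcing = "synchronous")
#' sc$name
#' @export
fw_scenario <- function(params = default_parameters(),
                        forcing = "constant",
                        regime = "A+S+H",
                        psi = NULL, T = 60, longrun_T = 200) {
  if (is.character(forcing)) {
    forcing <- make_recruitment_forcing(forcing, params)
  }
  if (!is.null(psi)) {
    stopifnot(is.numeric(psi), length(psi) == 1)
    if (psi < 0.05 || psi > 0.2) {
      stop("psi must lie in [0.05, 0.2]", call. = FALSE)
    }
  }
  reg <- regime_definition(regime)
  params <- apply_forcing(params, forcing)
  validate_params(params)
  structure(
    list(params = params, forcing = forcing, regime = reg, psi = psi,
         T = T, longrun_T = longrun_T,
         name = paste0(reg$label, "/", forcing$mode)),
    class = "fw_scenario")
}

#' @export
print.fw_scenario <- function(x, ...) {
  cat("<fw_scenario>", x$name, "\n")
  cat("  optimized:", paste(x$regime$optimized, collapse = ", "), "\n")
  cat("  open access:", paste(x$regime$open_access, collapse = ", "), "\n")
  cat("  closed:", paste(x$regime$closed, collapse = ", "), "\n")
  if (!is.null(x$psi)) cat("  Pelican floor share psi =", x$psi, "\n")
  cat("  horizon:", x$T, "yr\n")
  invisible(x)
}

#' Sensitivity-analysis scenario suite
#'
#' Produces the six robustness variants of a base scenario: a higher
#' discount rate (10 percent), forage prices raised by 25 percent,
#' Pelican adult survival decoupled from the forage stocks (second
#' survival prey-response parameter set to zero), Pelican reproduction
#' decoupled (second reproduction parameter set to zero), initial fished
#' stocks halved, and anti-synchronous forcing with a longer sardine
#' period.
#'
#' @param base an `fw_scenario`.
#' @return Named list of six `fw_scenario` objects.
#' @export
sensitivity_suite <- function(base) {
  stopifnot(inherits(base, "fw_scenario"))
  remake <- function(params = base$params, forcing = base$forcing) {
    fw_scenario(params = params, forcing = forcing,
                regime = base$regime$label, psi = base$psi,
                T = base$T, longrun_T = base$longrun_T)
  }
  p <- base$params

  p1 <- p; p1$econ$delta <- 0.10
  p2 <- p
  p2$econ$anchovy$p_tilde <- 1.25 * p$econ$anchovy$p_tilde
  p2$econ$sardine$p_tilde <- 1.25 * p$econ$sardine$p_tilde
  p3 <- p; p3$pelican$theta_s[2] <- 0
  p4 <- p; p4$pelican$theta_r[2] <- 0
  p5 <- p
  for (sp in fished_species) {
    p5[[sp]]$X0 <- 0.5 * p[[sp]]$X0
    p5[[sp]]$N0 <- 0.5 * p[[sp]]$N0
  }

  list(
    higher_discount = remake(params = p1),
    higher_forage_prices = remake(params = p2),
    decoupled_survival = remake(params = p3),
    decoupled_recruitment = remake(params = p4),
    half_initial = remake(params = p5),
    long_sardine = remake(
      forcing = make_recruitment_forcing("anti_synchronous_long_sardine", p))
  )
}
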