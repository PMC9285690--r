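# Harvest control rules and policy-path objects.

#' Stylized sardine harvest guideline (catch-based)
#'
#' Approximation of the current sardine harvest guideline: no catch at or
#' below a 150,000 t cutoff; above it, catch is a share (0.87, correcting
#' for fish outside U.S. waters) of the biomass surplus over the cutoff
#' times an exploitation fraction that tracks the recruitment deviation,
#' \eqn{F_s(t) = 0.0465824 + 0.06224328\, r_s(t)/\bar r_s}, capped at
#' 200,000 t.
#'
#' @param Xs sardine biomass (t).
#' @param r_s_t current sardine recruitment rate (1/yr).
#' @param r_s_bar mean sardine recruitment rate (1/yr), > 0.
#' @param pc policy constants (see `default_parameters()$policy`).
#' @return Catch (t/yr).
#' @examples
#' pc <- default_parameters()$policy
#' hcr_catch(150000, 1, 1, pc)   # at the cutoff: zero
#' hcr_catch(1e7, 1, 1, pc)      # cap binds: 200,000
#' @export
hcr_catch <- function(Xs, r_s_t, r_s_bar, pc) {
  stopifnot(r_s_bar > 0)
  Fs <- pc$hcr_f0 + pc$hcr_f1 * r_s_t / r_s_bar
  C <- ifelse(Xs <= pc$hcr_cutoff, 0,
              pc$hcr_share * (Xs - pc$hcr_cutoff) * Fs)
  pmin(C, pc$hcr_cap)
}

#' Hockey-stick fishing-mortality rule for sardine
#'
#' Piecewise-linear precautionary rule: no fishing below 40 percent of
#' the unfished sardine biomass, a linear ramp between 40 and 80 percent,
#' and a plateau at half the sardine natural mortality above 80 percent.
#' Continuous at both knots.
#'
#' @param Xs sardine biomass (t).
#' @param Xs_o unfished sardine biomass (long-run average, t), > 0.
#' @param M_s sardine natural mortality (1/yr).
#' @param pc policy constants (knots `hs_lower`, `hs_upper` and plateau
#'   multiplier `hs_fmax_mult`).
#' @return Fishing mortality rate (1/yr).
#' @examples
#' pc <- default_parameters()$policy
#' hockey_stick_F(0.6 * 6e5, 6e5, 0.4, pc)  # midpoint of the ramp
#' @export
hockey_stick_F <- function(Xs, Xs_o, M_s, pc) {
  stopifnot(Xs_o > 0)
  x <- Xs / Xs_o
  Fmax <- pc$hs_fmax_mult * M_s
  slope <- Fmax / (pc$hs_upper - pc$hs_lower)
  ifelse(x <= pc$hs_lower, 0,
         ifelse(x >= pc$hs_upper, Fmax, slope * (x - pc$hs_lower)))
}

#' Convert a rule's catch or fishing rate to effort
#'
#' Harvest rules prescribe either an instantaneous catch `C = F X` or a
#' fishing mortality `F = q E`; simulation needs effort. Catch is
#' converted through the current biomass (`E = C / (q X)`), with zero
#' effort when the stock is absent.
#'
#' @param state_X current biomass of the target species (t).
#' @param ec that species' economic parameters (for catchability `q`).
#' @param catch instantaneous catch (t/yr); give exactly one of `catch`
#'   and `F`.
#' @param F fishing mortality rate (1/yr).
#' @return Effort (non-negative scalar).
#' @examples
#' ec <- default_parameters()$econ$sardine
#' rule_to_effort(2e5, ec, F = 0.1)
#' @export
rule_to_effort <- function(state_X, ec, catch = NULL, F = NULL) {
  if (is.null(catch) == is.null(F)) {
    stop("give exactly one of `catch` or `F`", call. = FALSE)
  }
  if (is.null(F)) {
    if (state_X <= 0) return(0)
    F <- catch / state_X
  }
  max(0, F / ec$q)
}

# ---- policy-path objects ---------------------------------------------------

new_policy_component <- function(kind, effort = NULL, label = kind,
                                 data = NULL) {
  structure(list(kind = kind, effort = effort, label = label, data = data),
            class = "fw_policy_component")
}

#' Build a per-species policy path
#'
#' A policy assigns each fished species one of: `"closed"` (moratorium,
#' zero effort), `"open_access"` (effort adjusts instantaneously so
#' average profit is zero), an open-loop effort path (a function of time
#' or a `data.frame`/list with `t` and `E` knots, linearly interpolated),
#' a feedback rule (a function `(state, t, params)` returning effort), or
#' a constant fishing mortality given as `list(F = value)`.
#'
#' @param anchovy,sardine,halibut the component specification for each
#'   species, as above. Defaults: all closed.
#' @return An object of class `fw_policy`.
#' @examples
#' fw_policy(sardine = "open_access")                  # others closed
#' fw_policy(sardine = list(F = 0.1))                  # constant F
#' fw_policy(sardine = function(t) 100 + 0 * t)        # open loop
#' @export
fw_policy <- function(anchovy = "closed", sardine = "closed",
                      halibut = "closed") {
  comp <- function(x, sp) {
    if (inherits(x, "fw_policy_component")) return(x)
    if (is.character(x) && length(x) == 1) {
      if (!x %in% c("closed", "open_access")) {
        stop("unknown policy kind for ", sp, ": ", x, call. = FALSE)
      }
      return(new_policy_component(x))
    }
    if (is.function(x)) {
      nargs <- length(formals(x))
      if (nargs <= 1) {
        return(new_policy_component("open_loop", effort = x,
                                    label = "open_loop"))
      }
      return(new_policy_component("feedback", effort = x,
                                  label = "feedback"))
    }
    if (is.list(x) && !is.null(x$F)) {
      return(new_policy_component("constant_F", effort = x$F,
                                  label = paste0("constant_F:", x$F)))
    }
    if (is.list(x) && !is.null(x$t) && !is.null(x$E)) {
      f <- approxfun(x$t, x$E, rule = 2)
      return(new_policy_component("open_loop", effort = f,
                                  data = list(t = x$t, E = x$E)))
    }
    stop("cannot interpret policy specification for ", sp, call. = FALSE)
  }
  structure(list(anchovy = comp(anchovy, "anchovy"),
                 sardine = comp(sardine, "sardine"),
                 halibut = comp(halibut, "halibut")),
            class = "fw_policy")
}

#' Policy implied by a management regime (pre-optimization)
#'
#' For simulation without optimization: optimized species are given the
#' supplied open-loop efforts (or closed if none), open-access species the
#' open-access closure, closed species zero effort.
#'
#' @param regime a regime definition from [regime_definition()] or label.
#' @param efforts optional named list of open-loop effort functions for
#'   the optimized species.
#' @return An `fw_policy`.
#' @export
regime_policy <- function(regime, efforts = list()) {
  if (is.character(regime)) regime <- regime_definition(regime)
  spec <- list()
  for (sp in fished_species) {
    spec[[sp]] <- if (sp %in% regime$open_access) {
      "open_access"
    } else if (sp %in% regime$optimized && !is.null(efforts[[sp]])) {
      efforts[[sp]]
    } else {
      "closed"
    }
  }
  fw_policy(anchovy = spec$anchovy, sardine = spec$sardine,
            halibut = spec$halibut)
}

#' Registry of named fixed policies
#'
#' Convenience constructors for the standard fixed policies:
#' `moratorium` (all fisheries closed), `open_access` (all fisheries
#' unmanaged), `constant_F(Fa, Fs, Fh)`, `hcr` (stylized sardine harvest
#' guideline with anchovy and halibut under open access), and
#' `hockey_stick` (sardine hockey-stick rule, others open access). The
#' two sardine rules are closed-loop: catch rules are converted to an
#' instantaneous fishing rate `F = C/X` at each instant (the
#' continuous-time model carries no annual quota bookkeeping), and the
#' rules read the model biomass directly (no assessment error).
#'
#' @return Named list of policy constructors / policies.
#' @examples
#' pol <- policy_registry()$hockey_stick()
#' @export
policy_registry <- function() {
  list(
    moratorium = function() fw_policy(),
    open_access = function() {
      fw_policy("open_access", "open_access", "open_access")
    },
    constant_F = function(Fa = 0, Fs = 0, Fh = 0) {
      fw_policy(list(F = Fa), list(F = Fs), list(F = Fh))
    },
    hcr = function(others = "open_access") {
      fw_policy(anchovy = others,
                sardine = hcr_feedback(),
                halibut = others)
    },
    hockey_stick = function(others = "open_access") {
      fw_policy(anchovy = others,
                sardine = hockey_stick_feedback(),
                halibut = others)
    }
  )
}

#' @rdname policy_registry
#' @export
hcr_feedback <- function() {
  f <- function(state, t, params) {
    fp <- params$sardine
    C <- hcr_catch(state[["Xs"]], recruitment_rate(t, fp), fp$r_bar,
                   params$policy)
    rule_to_effort(state[["Xs"]], params$econ$sardine, catch = C)
  }
  new_policy_component("feedback", effort = f, label = "HCR")
}

#' @rdname policy_registry
#' @export
hockey_stick_feedback <- function() {
  f <- function(state, t, params) {
    Fs <- hockey_stick_F(state[["Xs"]], params$pelican$Xs_o,
                         params$sardine$M, params$policy)
    rule_to_effort(state[["Xs"]], params$econ$sardine, F = Fs)
  }
  new_policy_component("feedback", effort = f, label = "hockey_stick")
}
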