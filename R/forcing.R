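# Environmentally forced recruitment.

#' Time-varying per-capita recruitment rate
#'
#' Sinusoidal recruitment forcing on the log scale with a bias
#' correction,
#' \deqn{r(t) = \bar r \exp\{A \sin(2\pi t/p + s\pi/180 + \pi) - A^2/4\},}
#' so that the time-mean of the series stays within a fraction of a
#' percent of \eqn{\bar r} for amplitudes up to about 0.6 (the correction
#' comes from the variance of a sine wave being \eqn{A^2/2}).
#'
#' @param t time (yr); may be a vector.
#' @param fp forage parameter list with fields `r_bar`, `A`, `p` (period,
#'   yr) and `s` (phase start, degrees), e.g. `default_parameters()$sardine`.
#' @return Recruitment rate(s) (1/yr), strictly positive.
#' @examples
#' fp <- default_parameters()$sardine
#' recruitment_rate(c(0, fp$p / 2), fp)
#' @export
recruitment_rate <- function(t, fp) {
  if (fp$A > 0 && fp$p <= 0) {
    stop("recruitment period `p` must be > 0 when amplitude A > 0",
         call. = FALSE)
  }
  if (fp$A == 0) return(rep_len(fp$r_bar, length(t)))
  fp$r_bar * exp(fp$A * sin(2 * pi * t / fp$p + fp$s * pi / 180 + pi) -
                   fp$A^2 / 4)
}

#' Recruitment-variability forcing for the forage species
#'
#' Returns the amplitude/period/phase triplets that realize one of the
#' study's deterministic variability scenarios:
#' \describe{
#'   \item{`constant`}{no variability, `A = 0` for both species;}
#'   \item{`synchronous`}{both species share amplitude, period and phase
#'     (peaks and troughs coincide);}
#'   \item{`anti_synchronous`}{same amplitude and period, phases offset by
#'     half a period (one peaks while the other troughs);}
#'   \item{`anti_synchronous_long_sardine`}{as anti-synchronous but the
#'     sardine period is twice the anchovy period (slower sardine
#'     fluctuations).}
#' }
#' Forcings are deterministic functions of time; there is no randomness
#' anywhere in the model.
#'
#' @param mode one of `"constant"`, `"synchronous"`, `"anti_synchronous"`,
#'   `"anti_synchronous_long_sardine"`.
#' @param params an `fw_params` object supplying the base amplitude,
#'   period and phase (taken from the anchovy entry).
#' @return An object of class `fw_forcing`: list with `mode` and per-species
#'   `anchovy`/`sardine` lists of `A`, `p`, `s`.
#' @export
make_recruitment_forcing <- function(mode = c("constant", "synchronous",
                                              "anti_synchronous",
                                              "anti_synchronous_long_sardine"),
                                     params = default_parameters()) {
  mode <- match.arg(mode)
  A <- params$anchovy$A
  p <- params$anchovy$p
  s <- params$anchovy$s
  f <- switch(mode,
    constant = list(anchovy = list(A = 0, p = p, s = s),
                    sardine = list(A = 0, p = p, s = s)),
    synchronous = list(anchovy = list(A = A, p = p, s = s),
                       sardine = list(A = A, p = p, s = s)),
    anti_synchronous = list(anchovy = list(A = A, p = p, s = s),
                            sardine = list(A = A, p = p, s = s + 180)),
    anti_synchronous_long_sardine =
      list(anchovy = list(A = A, p = p, s = s),
           sardine = list(A = A, p = 2 * p, s = s + 180))
  )
  structure(c(f, list(mode = mode)), class = "fw_forcing")
}

#' Apply a recruitment forcing to a parameter set
#'
#' Overwrites the forage species' amplitude, period and phase with the
#' values of a forcing produced by [make_recruitment_forcing()].
#'
#' @param params an `fw_params` object.
#' @param forcing an `fw_forcing` object or a mode string.
#' @return The modified `fw_params`.
#' @export
apply_forcing <- function(params, forcing) {
  if (is.character(forcing)) {
    forcing <- make_recruitment_forcing(forcing, params)
  }
  for (sp in c("anchovy", "sardine")) {
    params[[sp]][c("A", "p", "s")] <- forcing[[sp]][c("A", "p", "s")]
  }
  params
}
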