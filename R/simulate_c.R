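# Packing of parameters and policies for the compiled right-hand side.
# The offsets here mirror src/forageweb.c and must stay in step with it.

MAXK <- 80L
NPARMS <- 565L

C_KINDS <- c(closed = 0, open_access = 1, open_loop = 2, constant_F = 3,
             HCR = 4, hockey_stick = 5, myopic = 6)

# returns the packed parameter vector, or NULL when the policy cannot be
# expressed for the compiled code (arbitrary R feedback functions,
# function-only open-loop paths, too many knots)
pack_parms <- function(params, policy, y0) {
  kinds <- numeric(3); pconst <- numeric(3); nk <- integer(3)
  kdata <- matrix(0, 3, 2 * MAXK)
  for (i in seq_along(fished_species)) {
    sp <- fished_species[i]
    comp <- policy[[sp]]
    if (comp$kind %in% c("closed", "open_access")) {
      kinds[i] <- C_KINDS[[comp$kind]]
    } else if (comp$kind == "constant_F") {
      kinds[i] <- C_KINDS[["constant_F"]]
      pconst[i] <- comp$effort
    } else if (comp$kind == "open_loop") {
      if (is.null(comp$data)) return(NULL)
      n <- length(comp$data$t)
      if (n > MAXK || n < 1) return(NULL)
      kinds[i] <- C_KINDS[["open_loop"]]
      nk[i] <- n
      kdata[i, seq_len(n)] <- comp$data$t
      kdata[i, MAXK + seq_len(n)] <- comp$data$E
    } else if (comp$kind == "feedback" &&
               comp$label %in% c("HCR", "hockey_stick", "myopic")) {
      if (comp$label %in% c("HCR", "hockey_stick") && sp != "sardine") {
        return(NULL)
      }
      kinds[i] <- C_KINDS[[comp$label]]
    } else {
      return(NULL)
    }
  }
  ap <- params$anchovy; spp <- params$sardine
  hp <- params$halibut; pp <- params$pelican
  out <- c(
    as.numeric(isTRUE(params$settings$kappa_in_numbers_loss)),
    as.numeric(isTRUE(params$settings$lagged_reproduction_prey)),
    ap$r_bar, ap$A, ap$p, ap$s, ap$w_r, ap$w_inf, ap$kappa, ap$M,
    spp$r_bar, spp$A, spp$p, spp$s, spp$w_r, spp$w_inf, spp$kappa, spp$M,
    hp$a, hp$b, hp$M_j, hp$tau, hp$kappa, hp$w_r, hp$w_inf0, hp$Cmax,
    hp$alpha_a, hp$alpha_s, hp$Y, hp$gamma_w, hp$M, hp$f_base,
    pp$Mbar, pp$tau_bp, pp$Phi, pp$K_bp, pp$z,
    pp$theta_r, pp$theta_s,
    pp$Gamma_a, pp$Gamma_s, pp$Gamma_other, pp$Xa_o, pp$Xs_o,
    pp$phi_floor,
    unlist(lapply(params$econ[fished_species], function(e) {
      c(e$p_tilde, e$q, e$c1, e$c2)
    }), use.names = FALSE),
    params$policy$hcr_cutoff, params$policy$hcr_cap,
    params$policy$hcr_share, params$policy$hcr_f0, params$policy$hcr_f1,
    params$policy$hs_lower, params$policy$hs_upper,
    params$policy$hs_fmax_mult,
    y0,
    kinds, pconst, as.numeric(nk),
    as.vector(t(kdata)))
  stopifnot(length(out) == NPARMS)
  unname(out)
}
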