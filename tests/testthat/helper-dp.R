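# Single-species reduction and an independent dynamic-programming
# oracle for the optimal-control solver.
#
# The reduction is the halibut fishery with no recruitment delay, no
# prey-dependent growth and recruit mass equal to asymptotic mass, so
# biomass stays on the manifold X = w * N and the dynamics collapse to
# one dimension:
#   dX/dt = w * a X / (1 + b X) - (M + qE) X.
# The forage stocks are emptied so predation and consumption terms are
# inert. The oracle solves the infinite-horizon discounted problem by
# semi-Lagrangian value iteration on a biomass grid, independently of
# the package's integrator and optimizer.

reduction_params <- function(w = 4500, c2 = 0.02) {
  p <- default_parameters()
  p$halibut$tau <- 0
  p$halibut$gamma_w <- 0
  p$halibut$w_r <- w
  p$halibut$w_inf0 <- w
  p$halibut$X0 <- 4e4
  p$halibut$N0 <- 4e4 / w
  for (sp in c("anchovy", "sardine")) {
    p[[sp]]$X0 <- 0
    p[[sp]]$N0 <- 0
  }
  p$econ$halibut$c2 <- c2
  validate_params(p)
  p
}

reduction_scenario <- function(T = 60) {
  fw_scenario(params = reduction_params(), forcing = "constant",
              regime = "H", T = T)
}

# infinite-horizon value iteration; returns V interpolator and J(X0)
dp_oracle <- function(params, Xmax = 1.8e5, nX = 601, Emax = 6000,
                      nE = 121, dt = 0.1, tol = 1e-9, maxiter = 8000) {
  hp <- params$halibut
  ec <- params$econ$halibut
  delta <- params$econ$delta
  w <- hp$w_r
  Xg <- seq(0, Xmax, length.out = nX)
  Eg <- seq(0, Emax, length.out = nE)
  gam <- exp(-delta * dt)
  # reward over one step: profit flow discounted within the step
  flow_w <- (1 - gam) / delta

  drift <- function(X, F) w * hp$a * X / (1 + hp$b * X) - (hp$M + F) * X
  lo <- matrix(0L, nE, nX); wt <- matrix(0, nE, nX)
  reward <- matrix(0, nE, nX)
  for (j in seq_len(nE)) {
    E <- Eg[j]; F <- ec$q * E
    Xm <- Xg + 0.5 * dt * drift(Xg, F)
    X1 <- pmin(pmax(Xg + dt * drift(pmax(Xm, 0), F), 0), Xmax)
    pos <- pmin(pmax(findInterval(X1, Xg), 1L), nX - 1L)
    lo[j, ] <- pos
    wt[j, ] <- (X1 - Xg[pos]) / (Xg[pos + 1L] - Xg[pos])
    reward[j, ] <- profit(Xg, E, ec) * flow_w
  }
  V <- rep(0, nX)
  for (it in seq_len(maxiter)) {
    Vbest <- rep(-Inf, nX)
    for (j in seq_len(nE)) {
      Vn <- V[lo[j, ]] * (1 - wt[j, ]) + V[lo[j, ] + 1L] * wt[j, ]
      cand <- reward[j, ] + gam * Vn
      upd <- cand > Vbest
      Vbest[upd] <- cand[upd]
    }
    diff <- max(abs(Vbest - V))
    V <- Vbest
    if (diff < tol * (1 + max(abs(V)))) break
  }
  list(V = approxfun(Xg, V, rule = 2), iterations = it,
       J0 = approx(Xg, V, xout = params$halibut$X0)$y)
}
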