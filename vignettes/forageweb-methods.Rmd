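---
title: "Model and methods: bioeconomic management of a forage-fish food web"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: bioeconomic management of a forage-fish food web}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageweb)
```

## The system being modeled

`forageweb` couples a four-species California Current food web to a
simple fishery economy. Two forage stocks — northern anchovy and
Pacific sardine — support a harvested predator (California halibut) and
a predator of conservation concern (Brown Pelican). Three fisheries
(anchovy, sardine, halibut) generate profit; the Pelican generates no
revenue but its population index responds to forage availability. The
management question is how much economic and conservation value is
gained by choosing fishing effort for one, two or all three fisheries
jointly, relative to leaving them unmanaged, and what it costs to keep
the Pelican index above a floor.

## Population dynamics

All stocks are modeled in continuous time. The seven states are
biomass and numbers for each fish stock, $(X_i, N_i)$ for
$i \in \{a, s, h\}$, plus the Pelican index $N_{bp}$.

**Forage species.** Numbers grow at a per-capita recruitment rate
$r_i(t)$ and die from natural mortality $M_i$, halibut predation $P_i$
and fishing $F_i$:
$$\dot N_i = \left[r_i(t) - (M_i + P_i + F_i)\right] N_i .$$
Biomass gains recruit mass $r_i w_{i,r} N_i$ and delay-difference
somatic growth $\kappa_i (w_{i,\infty} N_i - X_i)$, and loses the same
mortality terms:
$$\dot X_i = r_i(t)\, w_{i,r} N_i + \kappa_i (w_{i,\infty} N_i - X_i)
            - (M_i + P_i + F_i) X_i .$$
The mean mass $X_i/N_i$ therefore relaxes between the recruit mass
$w_{i,r}$ and the asymptotic mass $w_{i,\infty}$. Recruitment is forced
sinusoidally on the log scale with a bias correction,
$$r_i(t) = \bar r_i \exp\!\left\{A_i \sin\!\big(2\pi t/p_i +
  s_i \pi/180 + \pi\big) - A_i^2/4\right\},$$
so the time-mean of the series equals $\bar r_i$ to within a fraction
of a percent for amplitudes up to about 0.6 (the correction comes from
the variance $A^2/2$ of the sine on the log scale). Four deterministic
forcing modes are supported: constant ($A=0$), synchronous (identical
amplitude, period and phase for both species), anti-synchronous
(phases half a period apart) and anti-synchronous with a doubled
sardine period. There is no stochasticity anywhere in the model.

**Predation.** Halibut consume both forage species through a
multi-prey Type-II functional response; per-capita predation mortality
on prey $i$ is
$$P_i = \frac{C_{max}\, \alpha_i X_h}
             {C_{max} + \alpha_a X_a + \alpha_s X_s + Y},$$
with $Y$ an other-prey availability term. The shared denominator
produces prey switching: mortality on one prey falls when the other is
abundant. Pelican predation on forage is neglected (a minor share of
forage mortality).

**Halibut.** Recruitment to the fishable stock follows a
Beverton-Holt function of biomass lagged by the maturation delay
$\tau$, discounted by pre-recruit mortality:
$R = a X_h(t-\tau) / (1 + b X_h(t-\tau)) \, e^{-M_j \tau}$. The
asymptotic mass is consumption-dependent (generalized von Bertalanffy):
$w_\infty = w_{\infty 0} (f/f_{base})^{\gamma_w}$ where
$f$ is relative realized consumption, normalized to 1 at the unfished
forage baselines. A printed-form ambiguity in the numbers equation
(whether $\kappa$ appears in the numbers loss) is resolved by excluding
it — somatic growth does not remove individuals — with the setting
`kappa_in_numbers_loss` preserving the alternative reading.

**Brown Pelican.** Prey availability enters through a diet-weighted
depletion index
$d = \Gamma_a X_a/X_{ao} + \Gamma_s X_s/X_{so} + \Gamma_{other}$,
equal to 1 when both forage stocks sit at their unfished long-run
means. Reproduction (female fledglings) uses the lagged breeder stock
and lagged prey:
$$R_{bp} = 0.5\, e^{-\bar M \tau_{bp}}\, N_{bp}(t-\tau_{bp})\,
  \phi_r(d_{lag}) \left[1 + (\Phi - 1)\big(1 -
  (N_{bp}(t-\tau_{bp})/K_{bp})^z\big)\right]_+,$$
and adult mortality uses current prey,
$M_{bp} = \bar M - \log \phi_v(d)$. Both prey responses share a
saturating form that is zero below a depletion threshold $\theta_1$,
rises with steepness set by $\theta_2, \theta_3$, and saturates at 1;
setting $\theta_2 = 0$ decouples the corresponding vital rate from the
forage stocks (used in the sensitivity suite). The density-dependence
exponent $z$ is chosen numerically so that *total* net productivity
(recruitment minus adult mortality at saturated prey response) peaks
at 60% of $K_{bp}$; note that per-capita productivity under this
density term is monotone in abundance, so the peak condition is only
meaningful for total productivity. The survival scalar is floored at
$10^{-6}$ so mortality stays finite and extinction is approached
dynamically rather than through a singularity. Whether reproduction
responds to lagged or current depletion is ambiguous in the source
formulation; the default is lagged, switchable via
`lagged_reproduction_prey`.

## Economics and management

Each fishery earns a profit flow quadratic in its own effort,
$\Psi_i = (\tilde p_i q_i X_i - c_{i1} - c_{i2} E_i) E_i$, with
$F_i = q_i E_i$. Unmanaged fisheries operate under open access: effort
adjusts instantaneously until average profit $\Psi_i / E_i$ is zero,
$E_{oa} = \max\{0, (\tilde p q X - c_1)/c_2\}$, which makes their
profit contribution identically zero. A regulator chooses effort paths
for the managed set to maximize
$J = \int_0^T e^{-\delta t} \sum_i \Psi_i \, dt$ subject to the
dynamics, with management regimes ranging from single-species to full
three-fishery management, plus all-open-access and moratorium
benchmarks. The conservation constraint places a floor on the Pelican
index at every instant, located a share $\psi$ of the way from the
unconstrained-optimal long-run level up to the no-fishing (managed-set
moratorium) level.

Two stylized sardine harvest rules are provided for comparison: the
current harvest-guideline approximation (cutoff 150,000 t, share 0.87,
recruitment-dependent exploitation fraction, 200,000 t cap) and a
hockey-stick rule (zero fishing below 40% of unfished biomass, linear
ramp to half the natural mortality rate at 80%). Both are applied to
model biomass directly — no assessment or implementation error is
modeled — and catch-based rules are converted to an instantaneous
fishing rate $F = C/X$, since the continuous-time model carries no
annual quota bookkeeping.

## Calibration: what the defaults are and are not

The published calibration behind the original analysis lives in
supplementary tables that are not distributed with this package, so
`default_parameters()` ships a documented **stand-in** built by
steady-state algebra: target unfished biomasses (anchovy 800 kt,
sardine 600 kt, halibut 40 kt) are design inputs, and the mean
recruitment rates, Beverton-Holt slope, mean masses and initial
numbers are derived so that the unfished system under constant forcing
is an *exact* fixed point. Design criteria, in order: the unfished
system is viable under every forcing mode (in particular the Pelican
persists through synchronous forage troughs); halibut predation is a
small share of forage mortality (weak top-down control, a few
percent); the Pelican diet is sardine-dominant
($\Gamma_s = 0.5 > \Gamma_a = 0.3$); and open access depresses the
forage stocks to roughly 25–35% of unfished levels with the Pelican
index falling well below its unfished level, so the management
question has room to matter. The recruitment amplitude default
($A = 0.3$, period 25 yr) was set by the viability criterion: because
the forage species have no direct density dependence, log-biomass
integrates the forcing, and amplitudes much above 0.4 drive unfished
biomass swings so deep that the Pelican cannot persist even with no
fishing.

Two structural consequences of the missing density dependence are
worth knowing. First, the unfished forage system is only neutrally
stable: under periodic forcing the predation feedback produces a slow
drift in the cycling mean (of order tens of percent over 200
simulated years). The depletion-index baselines $X_{ao}, X_{so}$ are
therefore defined at the constant-forcing fixed point, where the
200-yr average equals the equilibrium exactly;
`calibrate_baselines()` recomputes them by simulation for any other
convention. Second, forage surplus production comes almost entirely
from riding the recruitment cycles, so optimal forage fishing
concentrates effort near cycle peaks and closes the fishery around
troughs — moratorium episodes arise from the economics, not from an
imposed rule.

Initial conditions default to the unfished steady state (the Pelican
index starts at 100, slightly above its prey-limited equilibrium of
about 96.6). The base discount rate is 0.05/yr, with 0.10 as the
sensitivity value; the planning horizon defaults to 60 yr, leaving
under 5% of discounted weight beyond the horizon; unfished long-run
averages use 200 yr. All of these are package decisions, documented
here rather than inherited from a source.

The YAML config interface (`load_config()`) overrides any field
verbatim and rejects unknown keys, so an external calibration can be
substituted without touching code.

## Numerical methods

**Integration.** The seven-state delay system is integrated with
`deSolve::dede` (lsoda, method of steps), relative tolerance $10^{-8}$
for reported trajectories and $10^{-6}$ inside optimization loops,
with per-state absolute tolerances scaled from initial magnitudes.
The initial history is held constant at the initial state. States are
clamped at zero inside the right-hand side; per-capita rates vanish
with the population, so extinct states stay extinct without event
handling. A compiled right-hand side (C, shipped in `src/`) is used
for all built-in policy kinds and is cross-checked against the
reference R implementation in the test suite; arbitrary user-supplied
feedback policies fall back to the R path. Trajectory interpolation
for lagged access uses monotone cubic (Fritsch-Carlson) splines.

**Optimal control.** The regulator's problem is solved by
control-parameterized single shooting: each managed species' effort is
piecewise linear on a knot grid (default spacing 2 yr), open-access
efforts are closed algebraically inside the dynamics, the objective is
evaluated by integrating the system and applying trapezoidal
quadrature to discounted profit, and the knot values are optimized
with projected quasi-Newton iterations (L-BFGS-B) under box
constraints $0 \le E \le E_{max}$. Shooting was chosen over
simultaneous collocation because the available optimizer handles box
constraints only; parameterizing controls (not states) keeps the
decision vector small, the dynamics exactly satisfied by construction,
and the delay terms handled by the integrator itself. The cost is that
effort profiles are resolved only to the knot spacing, which is why
the default spacing (2 yr) is finer than the multi-year
fishing/moratorium episodes the model produces. The infinite-horizon
objective is truncated at $T$ with a steady-flow salvage term
$e^{-\delta T} \Psi(T)/\delta$, which removes most of the
end-of-horizon incentive to strip the stocks.

The problem is non-convex, so the solver multi-starts from zero
effort, the realized open-access path and a myopic
(static-profit-maximizing) path, plus any warm starts; each start is
screened with a few iterations and the best is polished. Warm-starting
a larger regime from a smaller one (with the smaller regime's
open-access efforts passed as open-loop paths) guarantees the larger
regime begins at the smaller one's objective value, which is how the
regime-monotonicity property is preserved numerically. Every solution
is verified by re-integrating the solved policy at tight tolerance and
comparing states in relative sup-norm (threshold 0.5%); solutions
failing verification are demoted rather than reported silently. In
the test suite the solver is cross-checked on a one-dimensional
single-species reduction (halibut with no delay and fixed asymptotic
mass) against an independent semi-Lagrangian value-iteration oracle,
agreeing to within 1%.

**Pelican floor.** The floor is enforced by an escalating quadratic
penalty on $\max(0, \text{floor} - N_{bp})$ (default three rounds,
tenfold growth), warm-started from the unconstrained solution, with a
final feasibility check at 0.5% of the floor. Infeasible cases — for
example managing halibut alone while both forage fisheries stay under
open access — are flagged with a certificate (the best attainable
minimum Pelican level found). Two diagnostic times are reported:
`T_cross`, when the unconstrained trajectory first violates the floor,
and `T_change`, when the constrained effort paths first deviate by
more than 1% relative (with a $10^{-6}$ absolute effort floor to
ignore noise around zero); anticipatory management appears as
`T_change < T_cross`. The 1% divergence threshold is a package
definition — "begins to change" has no canonical definition.

**Long-run levels.** "Long-run" is the mean over the final full
recruitment period under variability forcing and the final 10 yr
under constant forcing.

## What the tests do and do not show

The test suite exercises the model at reduced problem sizes chosen for
a laptop-scale run: structural solver properties (moratorium episodes
placed in anticipation of biomass troughs, regime monotonicity,
constrained-value dominance, halibut-only infeasibility) are checked
on 40-yr horizons with 4-yr effort knots under synchronous forcing,
and the value-iteration cross-check uses a 60-yr horizon. These
establish that the machinery is correct and that the qualitative
management conclusions hold under the stand-in calibration. They do
not reproduce the magnitudes of any published analysis — those depend
on a calibration this package does not ship — and, by design, the
model omits stochastic recruitment, assessment and implementation
error, sluggish open-access entry-exit, policy adjustment costs and
spatial structure. Conclusions about real fisheries would additionally
require the config-supplied calibration and treatment of those
omitted processes.

## A worked example

```{r example, eval = FALSE}
sc <- fw_scenario(regime = "A+S", forcing = "synchronous", T = 40)
sol <- solve_regime(sc, solver_control(knot_dt = 4, maxit = 40))
glance(sol)
tidy(sol)
autoplot(sol)

oa <- simulate(sc, policy_registry()$open_access())
longrun_pelican_gain(sol, oa, window = 25)
```
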