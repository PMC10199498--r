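---
title: "Seasonal host-parasite dynamics and the evolution of host phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal host-parasite dynamics and the evolution of host phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hostpheno` implements a semi-discrete (impulsive) model of a free-living,
sterilizing parasite and a univoltine host. Hosts live for a single season:
a cohort of size $\hat s_n$ emerges as susceptible juveniles at per-capita
rate $g(t; t_0, t_l)$ — uniform on the emergence window $[t_0, t_0 + t_l]$ —
matures at rate $l$ into adults that cannot be infected, and reproduces
between seasons. The parasite $v$ is introduced in full at the season start,
decays at rate $\delta$, and infects juveniles at rate $\alpha s v$.
An infection sterilizes its host and, after a fixed latency period $\tau$,
kills it, releasing $\beta$ new parasites; only the fraction
$e^{-\mu_s \tau}$ of infected juveniles survives background mortality through
latency, and infections started after $T - \tau$ release nothing within the
season. Within a season,

$$
\begin{aligned}
\dot s &= \hat s_n\, g(t) - \mu_s s - \alpha s v - l s,\\
\dot a &= l s - \mu_a a,\\
\dot v &= \alpha \beta e^{-\mu_s \tau} s(t-\tau) v(t-\tau) - \delta v,
\end{aligned}
$$

with $s(0) = 0$, $v(0) = \hat v_n$, and the delayed product defined as zero
for $t < \tau$ (no infections predate the season). Parasite loss to
transmission is neglected, the standard free-living-parasite assumption.
Seasons are chained by two discrete maps: Beverton-Holt-type reproduction of
the surviving adults, $\hat s_{n+1} = \epsilon\sigma a_n(T)/(1 + \rho\,
a_n(T))$, and parasite carryover $\hat v_{n+1} = \gamma\, v_n(T)$.

Time is dimensionless; all rates share the same unit. The reference
parameterization (`model_parameters()` defaults, also shipped as
`inst/extdata/default_config.yaml`) is $\alpha = 10^{-6}$, $\beta = 400$,
$\delta = 2$, $\mu_s = 0.2$, $\mu_a = 0.015$, $l = 1$, $\gamma = 0.9$,
$\epsilon = 0.85$, $\sigma = 600$, $\rho = 10^{-4}$, $T = 4$. The latency
period $\tau$ is the axis along which the analyses vary (1–3.5); the
constructor default and the shipped config use $\tau = 3$, the long-latency
(one infection generation per season) scenario, and every analysis that
needs another value sets it explicitly. The emergence-period lower bound
`tl_min = 0.5` is the smallest period considered in the reference analyses
and is exposed as an argument of `phenology_traits()`.

## Numerical integration

The within-season vector field is non-smooth at the emergence-window edges
and, through the delay, at every forward $\tau$-shift of them. The compiled
integrator (Dormand-Prince 5(4), relative tolerance $10^{-8}$, absolute
$10^{-10}$) therefore builds the full breakpoint mesh
$\{0, t_0, t_0+t_l, \tau, t_0+\tau, \dots\} \cap [0, T]$ — including the
mutant's window when one is present — and restarts at every breakpoint, so
no step straddles a kink. Because consecutive breakpoints are at most
$\tau$ apart, every delayed lookup lands in completed history, which is
stored densely and interpolated with cubic Hermite polynomials (locally
$O(h^4)$, matching the integrator's accepted-step accuracy). Sub-tolerance
negative dips of the nonnegative states are clamped to zero; violations
beyond tolerance abort with a diagnostic naming the time. The infected-
but-not-yet-burst pool is deliberately not a state variable — it feeds
nothing back into the dynamics — but cumulative infections
$C(t) = \int_0^t \alpha s v\,du$ are integrated alongside for prevalence
reporting.

The suite cross-checks this integrator three ways: a fixed-step explicit
Euler oracle, an independent `deSolve::dede` integration, and, with
$\alpha = 0$ or one infection generation, closed forms (see below). The
Euler oracle uses step $10^{-5}$: at the nominal step $10^{-4}$ plain Euler's
own error on the stiffest mode ($\delta = 2$ over $T = 4$) is
$\approx \delta^2 T h/2 = 8\times 10^{-4}$, too coarse to certify the
$10^{-4}$ agreement the tests demand; at $10^{-5}$ its intrinsic error is
$\sim 8\times 10^{-5}$ and observed agreement is $\le 2\times10^{-5}$.

### Prevalence

The analyses report "host infection prevalence" without a formula; the
package defines it as cumulative infections over hosts that actually emerged,
$C(T)/(\hat s_n \min(1, (T-t_0)/t_l))$, which is guaranteed to lie in
$[0,1]$. The summary also exposes `infections` and `emerged` so the
alternative normalization by the full cohort $\hat s_n$ is one division away.
Prevalence-curve shapes should not be over-interpreted when comparing with
published figures, since their definition there is unstated.

## Closed-form disease-free results

With no parasites the juvenile/adult system is linear. A host emerging at
time $e$ is alive as an adult at the season's end with probability

$$
P(e) = \frac{l\, e^{-\mu_a (T-e)}\left(1 - e^{-(\mu_s + l - \mu_a)(T-e)}\right)}
       {\mu_s + l - \mu_a},
$$

and averaging over the realized emergence window gives the maturation
probability $\varphi(t_0, t_l)$ (`maturation_probability()`), evaluated from
the elementary antiderivative, with analytic limits at the degeneracies
$\mu_s + l = \mu_a$ and $\mu_a = 0$ rather than numerical epsilons. The
season map then has the explicit fixed point
$\hat s^* = (\epsilon\sigma\varphi - 1)/(\rho\varphi)$ when
$\epsilon\sigma\varphi > 1$, else extinction. These closed forms are the
package's independent oracle for the solver, the multi-season iteration, and
the no-parasite corner of every landscape.

One subtlety the closed form exposes: because adults die ($\mu_a > 0$),
$P(e)$ is maximized not at $e = 0$ but near $e \approx 0.3$, so
$\varphi(t_0)$ *rises* by about $1.4\times10^{-5}$ between $t_0 = 0$ and
$t_0 \approx 0.04$ before falling steeply. The disease-free fitness
landscape is therefore flat-to-slightly-favorable over the first few
hundredths of a time unit, and the no-parasite ESS search honestly stops at
$t_0 \approx 0.05$ (and $t_l \approx 0.51$) rather than exactly at the
bounds. Monotonicity tests assert the decreasing property from $t_0 = 0.1$
onward, where it holds strictly.

## Multi-season dynamics and equilibria

`run_seasons()` chains seasons through the discrete maps; `equilibrium()`
either iterates to a season-to-season relative tolerance (with an absolute
floor for near-zero parasite densities) or runs a fixed season count, the
mode used when replicating published analyses (100 seasons for the density
landscapes, 150 for the time-series scenarios, 300 inside the invasion
analysis). The default initial densities $\hat s_1 = \hat v_1 = 10^4$ are
arbitrary — the published analyses do not state theirs — and the suite
verifies the equilibrium is an attractor independent of initials to
$10^{-3}$ relative (observed: $10^{-14}$). Parasite densities below
$10^{-30}$ are *reported* as extinct but never zeroed during dynamics: the
deterministic model cannot reach zero, and zeroing would distort selection
pressure exactly where it matters, at the parasite-extinction boundary.

At the reference parameterization with $\tau = 3$ and early, brief emergence
($t_0 = 0$, $t_l = 0.5$), the parasite is extraordinarily efficient: the
computed equilibrium has prevalence $0.989$ and host cohort
$3.98\times10^6$, against $5.09\times10^6$ without parasites. The published
value for this one scenario ($4.94\times10^6$) disagrees with the dynamics
as specified; the package's number satisfies the parasite fixed-point
condition (which pins $\int_0^{T-\tau} s\,du = 1/(\gamma\alpha\beta
e^{-\mu_s\tau} e^{-\delta(T-\tau)})$) to machine precision and is confirmed
by an exact integrating-factor solution of the one-generation case, so the
package reports what the equations produce. All other published densities
and all four nontrivial trait optima are reproduced (two of them exactly at
the search resolution). The strong Beverton-Holt saturation
($\rho\,a(T) \sim 10^2$) makes $\hat s^*$ logarithmically insensitive to
adult output, which is why this one high-prevalence scenario is the only
place the discrepancy is visible.

## Evolutionary invasion analysis

`invasion_fitness()` equilibrates the resident for a fixed 300 seasons (as
in the reference analyses; tolerance-based stopping would behave differently
near parasite extinction, where $\hat v$ is tiny but still decaying or
growing), then integrates one season of the five-equation resident+mutant
system with a single mutant founder. Fitness is the mutant's next-season
cohort,

$$
w = \frac{\epsilon\sigma\, a_m(T)}{1 + \rho\, a(T)},
$$

with the *resident's* adult density in the denominator: the mutant is a
measure-zero perturbation of a cohort of $\sim 5\times10^6$, and this choice
makes resident-vs-self neutrality exact rather than accurate to
$O(1/\hat s^*)$. The suite verifies neutrality $|w - 1| \le 10^{-4}$ across
a trait grid (observed: $\le 10^{-9}$), the single strongest end-to-end
check of the pipeline, since it exercises the equilibrium, the coupled
solver and the fitness map simultaneously.

`find_ess()` performs trait substitution: equilibrate the resident, probe
mutants one step $h$ above and below, move the resident by `step` in an
invading direction, repeat. Two numerical policies matter:

* **Invasion guard.** The theoretical criterion is $w \ge 1$, but a neutral
  mutant also satisfies it, so numerically the search requires
  $w > 1 + 10^{-6}$. The guard is far above the solver's fitness error
  ($\sim10^{-9}$) and far below any real selection differential except on
  the deliberately flat disease-free plateau discussed above, where stopping
  (rather than drifting) is the intended behavior; such stops are annotated
  `boundary-flat`.
* **Limit-cycle midpoint.** When evolution pushes the emergence start
  toward the parasite-extinction boundary, the substitution sequence
  2-cycles between adjacent grid values: with the resident one step early,
  parasites persist after 300 seasons and favor later emergence; one step
  late, they collapse and the disease-free gradient points earlier. The
  search detects the 2-cycle and reports the midpoint (e.g. $t_0^* = 0.915$
  for $\tau = 3$, $2.135$ for $\tau = 1.5$), annotated in `note`. The
  interior optima of the emergence *period* ($t_l^* = 1.45$, $2.88$) are
  ordinary convergent stops.

One trait evolves at a time with the other held at its reference value
($t_0 = 0$ or $t_l = 0.5$), matching the scope of the reference analysis;
simultaneous two-trait evolution and parasite (co)evolution are out of
scope. `pairwise_invasibility()` provides the standard PIP cross-check: the
suite verifies diagonal neutrality, the all-invade ordering of the
disease-free landscape, and mutual invasibility bracketing the extinction
boundary at $\tau = 3$.

## Problem sizes

The shipped tests and the acceptance script use the reference scales
directly — 100–300 seasons per equilibrium, step and probe $0.01$, full
substitution walks from the reference starts — since a season integrates in
a fraction of a millisecond; coarser grids (e.g. the $10\times10$ phenology
landscape) are used only where the published grids' resolution is not the
point.

## Known limitations

* The model is deterministic; demographic stochasticity, which would resolve
  the tiny-but-positive parasite densities near the extinction boundary into
  actual extinctions, is not represented, so boundary optima like
  $t_0^* = 0.915$ are numerically pinned rather than classical interior ESSs.
* Only the uniform emergence density is implemented; other distributions are
  expected to change results quantitatively but not qualitatively.
* Single parasite strain, one host type plus one rare mutant; no
  coevolution, no host-parasite cycling diagnostics (none was observed in
  the explored parameter ranges).
* The high-prevalence parasitized equilibrium is reported as computed from
  the stated equations (see above), not as the published approximation.

```{r example}
library(hostpheno)
p <- model_parameters(tau = 3)
equilibrium(phenology_traits(0, 0.5), p, n_seasons = 150)
find_ess("t0", start = 0, params = p, n_seasons = 300)
```
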