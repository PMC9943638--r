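---
title: "A desperation-threshold model of community violence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desperation-threshold model of community violence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 7, fig.height = 4)
library(desperation)
```

## The model

This package implements a formal model of why interpersonal violence is
high and persistent in economically deprived communities. It couples two
layers:

* an **individual decision model**: a stochastic dynamic program over an
  agent's resource level, and
* a **population layer**: a large population of agents who asynchronously
  adopt whatever strategy the decision model deems optimal given the
  current mix of behaviours around them.

Each agent carries a resource state $x$ following a stationary AR(1)
process with autocorrelation $r$,

$$x_{t+1} = \mu + r\,(x_t - \mu) + \varepsilon_t,\qquad
  \varepsilon_t \sim \mathcal N\!\big(0,\ \sigma^2 (1 - r^2)\big),$$

so that the cross-section of resources is $\mathcal N(\mu, \sigma^2)$ at
all times. A **desperation threshold** sits at $x = 0$: an agent below it
is failing to meet basic needs, and its eventual fitness is cut by a
fraction $\omega$ for every period spent there.

Each round, an agent plays one of three strategies:

* **exploitation** — property crime: try to take $\beta$ resources from a
  victim, risking a sanction of $\pi$ with probability $\gamma$;
* **violence** — a costly *toughness signal*: fight back when targeted,
  which deflects exploiters towards softer targets, at the risk of fights
  (each lost fight cuts fitness by a fraction $\lambda$);
* **submission** — neither steal nor fight; surrender the stake when
  targeted.

Exploiters pick a target among $n$ randomly drawn candidates, preferring
ones without a toughness reputation. With violent fraction $v$ and
exploiter fraction $e$, mean-field victimization rates are

$$\text{unprotected: } e\,\frac{1 - v^{n}}{1 - v}, \qquad
  \text{violent: } e\,v^{\,n-1} .$$

At $n = 1$ the signal is useless (both rates equal $e$); as the violent
fraction approaches one, the few remaining unprotected agents concentrate
*all* attacks (the unprotected rate tends to $e\,n$). That concentration
is the positive feedback behind "violence begets violence".

Fitness is the resource level reached after $T$ periods, floored at zero,
times $(1-\omega)$ per period started below the threshold and
$(1-\lambda)$ per lost fight. `solve_policy()` computes the optimal
strategy on a resource grid by backward induction; `run_to_equilibrium()`
iterates 10%-at-a-time strategy updating in a simulated population until
the strategy mix stabilizes.

## Model semantics decided here

The round-level consequences of each strategy leave some freedom, and the
package fixes them as follows.

**Who carries the toughness reputation.** Only agents *playing the violent
strategy* are deflected targets. Exploiters do react violently when
attacked (a fight over the stake), but exploiting does not itself signal
toughness, so exploiters are victimized at the unprotected rate. The
alternative — granting exploiters the reputation discount — makes
exploitation weakly dominate violence (the signal's benefit without its
mistake-fight costs, plus a free zero-mean lottery), which collapses the
strategy structure: no interior violent region can exist. Fights also
occur when an exploiter's chosen target turns out to be another exploiter.

**Sanction semantics.** A caught exploiter forfeits the loot *and* pays
$\pi$: the expected payoff of a theft against an undefended victim is
$(1-\gamma)\beta - \gamma\pi$, which is exactly zero at the package's
default stakes ($\beta = 10$, $\pi = 20$, $\gamma = 1/3$) and negative
whenever a fight might be lost. Exploitation is therefore never profitable
on average; desperate agents do it for its upside — a one-in-three chance
of jumping back above the threshold — not its mean.

**Mistakes.** With probability $m$ per round a violent agent attacks a
non-exploiter by mistake; a fight ensues only if the target is violent
too. Mistake fights carry no resource stake; the loser of any fight
records the $\lambda$ fitness cost. This is the hawk-dove-style negative
frequency dependence that makes violence costlier as it spreads.

**Event thinning.** Expected per-agent attack counts are converted to
at-most-one-event probabilities via $p = 1 - e^{-\lambda_{\text{att}}}$,
keeping each round's outcome distribution finite. At the equilibria the
model visits, $e$ is a few percent and the correction is negligible; only
in the saturated state does the unprotected rate approach $e\,n$, where
the cap correctly represents "you cannot lose the stake twice in a round".

## Numerical choices

* **Grid**: 301 points spanning $[\mu - 5\sigma,\ \mu + 5\sigma]$, always
  extended to cover $[-3\sigma, \sigma]$ around the threshold. Transitions
  are binned by probability mass onto the grid (midpoint bins, tails into
  the end bins), so the dynamic program is an exact Markov chain on the
  grid; no interpolation is used.
* **Horizon**: $T = 50$ periods. With $r = 0.99$ the policy at $t = 0$ is
  numerically stationary at this horizon; longer horizons move policy
  boundaries by less than a grid step.
* **Terminal fitness** is floored at zero. An unfloored terminal value
  would let the multiplicative below-threshold penalty *reward* agents
  whose expected terminal wealth is negative, reversing the value of
  wealth at the bottom of the grid.
* **Tie-breaking**: exact ties between strategies resolve to the least
  risky one (submission over violence over exploitation), which pins down
  the degenerate $\omega = \lambda = 0$ case.
* **Convergence**: a run is converged when both the exploiter and the
  violent fraction have varied by less than `tol = 1e-3` over the trailing
  50 steps (2000-step cap). Interior equilibria at moderate population
  sizes jitter on a small limit cycle (the policy boundary flips one grid
  step as frequencies fluctuate); such runs report `converged = FALSE`
  with a perfectly usable stationary trajectory.

## Default parameters

Stakes and environment follow the model's standard calibration: $\beta = 10$,
$\pi = 20$, $\gamma = 1/3$, $r = 0.99$, population $10^5$ (simulations in
the test-suite and the bundled reproduction script use $10^4$, which is
binomially indistinguishable here and ten times faster), resource scale
$\mu = 25$, $\sigma = 10$. Four parameters are specified as ranges; the
package fixes one operating point inside those ranges and keeps it
everywhere:

| parameter | range | default | why |
|---|---|---|---|
| $n$ (candidate targets) | 1–50 | 50 | an efficient toughness signal; hysteresis requires the concentration effect to be strong |
| $m$ (mistake probability) | 0.01–0.3 | 0.035 | see below |
| $\omega$ (below-threshold cost) | 0.01–0.3 | 0.10 | mid-scale; strong enough to drive below-threshold risk-proneness without flattening the value function |
| $\lambda$ (lost-fight cost) | 0.01–0.3 | 0.30 | fights must be genuinely dangerous, or fighting back when victimized would weakly dominate submission everywhere |

The product $m\lambda$ prices violence relative to the exploitation risk
it deflects and so positions the population-level transition. With
$m = 0.035$, $\lambda = 0.30$ the model reproduces the full qualitative
surface at one parameter point: a threshold-bound exploitation square, the
violent bands at very low and very high prevalence of violence, an
S-shaped lower branch that saturates at a desperation rate of about
0.016–0.02, a stable all-violent state down to rates of about 0.004, and
the dip-then-explode incentive curve. Larger $m$ blurs the policy map
(stray exploitation pockets above the threshold at near-tied compositions);
smaller $m$ compresses the whole bistable structure into desperation rates
below one percent.

## What the simulations hold fixed

Resources are **frozen** while strategies converge: the desperation rate
is an exogenous dial (set via `rate_to_mu()`, which inverts the Gaussian
tail), not an outcome. This mirrors treating the economy as the slow
variable and behaviour as the fast one; letting thefts and shocks move
resources during convergence would endogenize the desperation rate and
conflate the two timescales. Consequently the synthetic populations
emulate the *decision* content of real communities — heterogeneous
resources, frequency-dependent payoffs — but none of the demography,
spatial structure, income dynamics or imperfect information of real
neighbourhoods; passing tests certify the model's internal logic, not
empirical adequacy.

## Reachability of the violent equilibrium, and the hysteresis protocol

For desperation rates below the saturation point the model is bistable:
an interior low-violence equilibrium coexists with a saturated state in
which every agent above the threshold is violent and every agent below it
exploits. The saturated state's basin is, however, *thin in a specific
way*: it requires both near-zero submission and an already-present
exploiter class. A population initialized "all violent" has no exploiters
yet ($e = 0$), so violence has costs and no benefits for its first
updaters; submission reopens while exploiters accumulate, and — because
each update converts desperate agents to exploiters and wealthy agents to
submission in lockstep ($e \approx \text{rate}\cdot(1 - v)$ along the
path, which keeps the deflection benefit $e\,(1 - v^n)/(1-v)\,\beta$
pinned at the interior equilibrium's scale) — the population lands on the
interior attractor. This is not a numerical artifact; it holds at every
parameter point we examined and for sequential as well as batched
updating.

`hysteresis_sweep()` therefore offers two protocols. `"fresh"` rebuilds
each population from its nominal initialization (above the saturation
rate, both initializations converge to the saturated state — the
regime the reproduction script targets). `"continuation"` implements the
hysteresis loop itself: the peaceful branch walks the desperation rates
upward and the violent branch walks them downward, each rate inheriting
the previous equilibrium's strategies (rank-matched on resources). The
downward branch then tracks the saturated state deep into the low-rate
region where the upward branch is still peaceful — the bistable window —
because it arrives *with* its exploiter class intact. This matches the
phenomenon the model is meant to exhibit: a community keeps the violent
equilibrium it inherited even after conditions improve.

```{r hysteresis, eval = FALSE}
p <- model_params(N_pop = 1e4)
sw <- hysteresis_sweep(p, rates = c(0.005, 0.01, 0.015, 0.02, 0.025),
                       protocol = "continuation", seed = 1)
plot(sw)
```

## Worked example

A small policy map (a coarse grid keeps the vignette light; defaults give
the production resolution):

```{r policy, eval = FALSE}
p <- model_params(grid_n = 61)
pm <- policy_map(p, e_values = c(0.02, 0.1), v_grid = seq(0, 0.89, 0.05))
plot(pm)
```

Below the threshold agents exploit at every level of violence; just above
it they are violent (close to the edge, one has too much to lose); violence
also rules when it is very rare (a free signal) and when it is nearly
universal (the rare submissive agents absorb all exploitation); submission
fills the comfortable middle.

## Known limitations

* The desperation threshold is fixed and absolute; relative or endogenous
  thresholds are only reachable by re-deriving `mu`/`threshold` yourself.
* Violence is binary; graded violence levels and fight-earned (rather than
  declared) reputations are out of scope.
* The mean-field encounter layer ignores network or spatial structure and
  samples targets with replacement; at `N_pop` in the thousands and
  `n_targets` up to 50 the with-replacement error is negligible.
* Interior equilibria are limit cycles of amplitude ~1 grid step of policy
  boundary; reported frequencies are ensemble snapshots, not exact fixed
  points.
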