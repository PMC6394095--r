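---
title: "Adaptive walks of a regulator-target network on a discrete fitness landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive walks of a regulator-target network on a discrete fitness landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitscape)
```

## The model

fitscape simulates evolution of the simplest bacterial transcription unit:
a constitutively produced regulator $R$ that a constant environmental
signal $S$ converts into its active form $R^*$, which — acting as a dimer —
activates a target protein $T$:

$$\frac{dR}{dt} = bas - k_{act} R S + k_r R^* - k_d R$$
$$\frac{dR^*}{dt} = k_{act} R S - k_r R^* - k_d R^*$$
$$\frac{dT}{dt} = \frac{\beta\, R^{*2}}{K_m^2 + R^{*2}} - k_{dT}\, T$$

Because the signal is constant, only the steady state matters for fitness,
and it exists in closed form:

$$\bar R = \frac{bas\,(k_r + k_d)}{k_d\,(k_r + k_d + k_{act} S)}, \qquad
  \bar R^* = \frac{k_{act} \bar R S}{k_r + k_d}, \qquad
  \bar T = \frac{\beta}{k_{dT}} \frac{\bar R^{*2}}{K_m^2 + \bar R^{*2}}.$$

Walks evaluate millions of genotypes, so the closed form is used
throughout; `integrate_dynamics()` (stiff `lsoda` integration) exists as an
independent oracle and the test suite verifies agreement to 1e-6 relative
across a thousand random parameter sets.

Expression is beneficial but costly. Benefit saturates in the steady-state
target level, cost is proportional to the total protein burden, and
fitness is their difference:

$$B = \frac{a T}{T + b}, \qquad C = \alpha\,(T + R^* + R), \qquad F = B - C,$$

with defaults $a = 1$, $b = 10$, $\alpha = 2.5\times 10^{-5}$. Two readings
of the reversion-rate coupling circulate for this model family; we default
to $k_r = 10^{-3} k_{act}$ and expose a fixed-$k_r$ override
(`grn_model(kr_const = )`) for the alternative ($k_r$ tied to the maximal
degradation rate). The signal level is never stated numerically in the
source material for this model class; we default to a saturating
dimensionless $S = 1$, and every structural result below holds for any
fixed $S > 0$.

## The landscape

Each of the six evolvable parameters (`bas`, `k_act`, `k_d`, `beta`,
`K_m`, `k_dT`) takes one of 1000 discrete values: the range endpoints plus
998 values drawn log-uniformly (parameters are rate constants spanning
decades). A mutation moves exactly one parameter to one of the levels
adjacent in that parameter's *neighbor network*: from level $i$, candidate
neighbors are drawn with probability proportional to a Gaussian kernel in
rank space centred on $i$ with $\sigma = 20$ (2% of the levels), truncated
at the grid boundary, and the relation is symmetrized.

Two symmetrization modes are provided. `"strict"` (the default) produces
an (almost exactly) $K$-regular graph: every level has $K$ accessible
alternatives, which matches the definition of connectivity as *the number
of values a parameter can reach by a single mutation*. `"union"` keeps
every node's own $K$ draws plus all reciprocal edges, which realizes
roughly $1.4$–$2\times K$ accessible values; it is retained because the
two readings bracket what a per-node draw-then-symmetrize construction can
mean. All connectivity results in this package are reported against the
strict (regular) semantics.

### Default parameter ranges

The exact ranges used by the original study live in supplementary material
that is not reproduced in the main text, so the package ships its own
defaults (`default_param_ranges()`), chosen once on physiological grounds:

| parameter | range | meaning |
|---|---|---|
| `bas` | $10^{-4}$–$1$ | basal regulator production (conc/time) |
| `k_act` | $10^{-4}$–$1$ | activation rate (per signal per time) |
| `k_d` | $10^{-4}$–$10^{-2}$ | regulator degradation/dilution (1/time) |
| `beta` | $10^{-3}$–$0.25$ | maximal target production (conc/time) |
| `K_m` | $1$–$10^{3}$ | activation threshold (conc) |
| `k_dT` | $10^{-3}$–$10^{-1}$ | target degradation/dilution (1/time) |

One structural property of these defaults is deliberate: the expression
budget binds. The largest attainable steady-state target level,
$\beta_{\max}/k_{dT,\min} = 250$, sits below the level
$\sqrt{ab/\alpha} - b \approx 622$ at which marginal benefit would fall to
marginal cost. The fitness peak is therefore pinned by the physiological
constraints (five parameters at or near range endpoints, one interior),
which gives the landscape a sharp, well-defined global optimum — the
regime implied by a reported global fitness well below the unconstrained
cost-benefit optimum of $\approx 0.968$ under the same constants. Had the
budget not bound, the peak would sit on an extended near-degenerate ridge
(any $(bas, k_d)$ pair with the same ratio yields the same active-regulator
level) and "reaching the global peak" would not be a well-posed event. On
the default grid the peak fitness is $\approx 0.955$.

## Adaptive walks

A walk repeatedly evaluates all $\sum_p \deg(g_p) \approx 6K$ one-mutant
neighbors, moves to one *strictly* beneficial neighbor chosen uniformly at
random, and stops when none exists — a local (possibly global) optimum.
Strictness makes termination provable (fitness takes finitely many values
on the grid and increases every step); equal-fitness neighbors are neither
moves nor blockers, since ties are measure-zero for a continuum-valued
fitness. Drift, deleterious fixation and effect-size-weighted fixation
probabilities are out of scope: the dynamics are purely
selection-dominated.

The walk core is implemented in C++ (Rcpp) with R's RNG, so walks are
bit-reproducible under `set.seed()` across the R and C++ boundaries. The
closed-form fitness is implemented twice — vectorized R (used by the peak
and start-genotype searches and by the tests) and C++ (used by the walk) —
with identical operation order, and the test suite asserts bitwise
agreement.

### When has a walk "reached the global peak"?

The peak has nearly flat directions: at its corner-pinned coordinates a
one-rank move changes $F$ by as little as $10^{-10}$. Consequently no walk
terminates *exactly* at the grid argmax; terminal states form two cleanly
separated families, one within $\lesssim 10^{-3}$ of the peak (the state
differs from the argmax by a rank or two along near-flat directions) and
genuine local optima at least $10^{-2}$ below it. We classify a terminal
state as "at the global peak" when its fitness is within `reach_tol`
(default $5\times 10^{-3}$) of the estimated peak fitness — the
discretization tolerance of the peak value itself, since regenerating the
random grid shifts the attainable maximum by a few $10^{-3}$. Any
tolerance inside the spectral gap gives the same classification.

## Ensemble statistics

`critical_k_scan()` runs, for each connectivity $K \in \{3, 5, 7, 10, 12,
15, 20, 50\}$ and each of five target starting fitnesses $\{0.0826,
0.2251, 0.45, 0.6264, 0.8526\}$, 100 replicate walks, and records the
fraction whose terminal fitness is the global-peak fitness.

Three estimator choices matter and are exposed as flags:

* **Network resampling** (`resample_networks`, default `TRUE`): with one
  frozen network per $K$, the fraction measures the luck of a single
  quenched realization — near the transition it ranged from 0.15 to 1.00
  across network seeds in our measurements, purely by whether particular
  near-peak edges exist — and the fraction-vs-$K$ curve need not be
  monotone. Resampling the network for every replicate estimates the
  graph-ensemble reach probability, which is smooth, monotone and stable.
* **Start genotypes** (`resample_starts`, default `FALSE`): replicates of
  a design point share one start genotype, which between-replicate
  variance dynamics require. Statistics attributed to a starting
  *fitness* (mean steps to peak, speed of evolution) instead use
  `resample_starts = TRUE`, averaging over genotypes that realize the
  target fitness; a single genotype's idiosyncratic neighborhood
  otherwise dominates those statistics.
* **Transition rule** (`transition_rule`): the transition $K$ is the
  smallest tested $K$ from which onward the ensemble is compatible with a
  reach probability of at least 0.95. The default is an exact-binomial
  compatibility test on the pooled counts; the naive point rule (every
  start's sample fraction $\ge 0.95$) is available but flips between
  adjacent tested $K$ values on sampling noise exactly when the true
  fraction sits near the threshold.

On the default landscape the transition is sharp: pooled reach fractions
are $\approx 0$ at $K \le 5$, $\approx 0.5$ at $K = 7$, $\approx 0.95$ at
$K = 10$ and $1.0$ from $K = 12$ on — the population almost surely finds
the global peak once roughly 1% of each parameter's levels are reachable
per mutation. Re-running the scan with $a \times 10$, $\alpha \times 10$
or $b / 10$ leaves the transition $K$ unchanged, consistent with it being
chiefly a property of the mutational graph. The $b \times 10$ scaling is
the exception on this landscape: it roughly doubles both the
discretization-dust and trap depths near the peak while the fixed
`reach_tol` classification scale stays put, and the measured transition
moves one tested value upward — a known limitation of classifying
"reached" by an absolute fitness tolerance across fitness functions with
different local scales (`rt_peak$discretization_step` is exposed for
scenario-specific tolerances).

Derived statistics follow the study's definitions: *speed of evolution* is
the per-mutational-event gain of the ensemble-mean fitness (the walk's
natural clock; no wall-clock time exists in the model); *steps to peak*
averages only replicates that reach the global peak (for the others the
count is infinite) and decreases roughly linearly with starting fitness at
$K = 50$; *variance dynamics* track the between-replicate fitness variance
at each step, with terminated replicates carrying their terminal fitness
forward — the variance rises as trajectories diverge and collapses to zero
exactly when all replicates end on a common peak. The peak speed across
the five starts is attained at an intermediate starting fitness: the
per-mutation benefit gain is maximal while the target level crosses its
half-saturation region, and low-fitness starts first accumulate
potentiating mutations that gain little themselves.

## Numerical and design choices

* **Global peak estimation** (`estimate_global_peak()`): multi-start
  coordinate ascent on the grid with full per-parameter connectivity,
  cross-checked against continuous L-BFGS-B maximization over the box on
  log-scale parameters. The continuous optimum must bound the grid value
  from above and agree within $10^{-3}$ relative; disagreement is flagged
  and warned about.
* **Start genotypes** (`find_start_genotype()`): rejection sampling over
  uniformly random genotypes (keeping starts representative), with a
  coordinate-wise refinement minimizing $|F - F_0|$ only if sampling
  misses the tolerance (default $10^{-3}$). Infeasible targets error with
  the best candidate reported.
* **Seeds**: one master seed; every design point derives a child seed via
  a documented 31-bit multiplicative fold (`child_seed()`), so any subset
  of the experiment reruns identically in any order.
* **Kernel sampling**: sequential draws of `round(rnorm(i, sigma))` with
  rejection of repeats and out-of-range values (C++, R RNG). When $K$
  exceeds $4\sigma$ the tail would stall rejection sampling, so the
  builder switches to exact weighted sampling without replacement; the
  two produce the same law.
* **Degenerate inputs**: production rates may be zero (the steady state
  and fitness degrade gracefully to zero); rate constants must be
  positive; `K` must lie in $[1, n_{levels} - 1]$; `min < max` for every
  range.

## Problem sizes

The test suite runs the full model-correctness property at 1000 random
parameter sets, oracle equivalence on four enumerable fixtures (with
1000-walk Monte-Carlo cross-checks), a reduced transition scan
($K \in \{5, 10, 20\}$, 50 replicates, all five starts, with the four
fitness-constant scalings), and the complete $K = 50$ phenomenology at 100
replicates. The acceptance script runs the full design (8 $K$ values
$\times$ 5 starts $\times$ 100 replicates, fresh network per replicate).
These sizes are the package's chosen defaults for routine verification;
all drivers scale to larger designs from the same configuration surface.

## What the synthetic landscape does and does not show

Everything here is exact simulation of the stated model — there is no
external data. The landscape emulates: discreteness of biochemical
parameter values, locality of mutational effects (the rank-space kernel),
bounded physiological ranges, and a smooth cost-benefit fitness over a
deterministic steady state. It does not emulate: time-varying signals,
stochastic gene expression, drift or deleterious fixation, epistasis
beyond what the shared steady state induces, dimer-acting targets or
toxic-intermediate benefit shapes. Passing tests therefore validate the
framework's internal correctness and the graph-theoretic character of the
critical-connectivity transition; they do not by themselves certify the
biological realism of any particular parameter range, and statistics that
depend on the fitness surface's fine structure (exact transition value,
which start fitness adapts fastest) can shift with the chosen ranges.

## Known limitations

* The default ranges stand in for the study's unavailable supplementary
  table; the global-peak fitness (here $\approx 0.955$) and any
  range-sensitive statistic depend on them.
* The walk's Markov property means ensembles can be enumerated exactly
  only on tiny grids; at full scale all guarantees are statistical.
* One landscape dimensionality (six parameters) is wired into the GRN
  model, though the landscape/walk machinery itself is
  dimension-agnostic (toy fixtures use 1–3 dimensions).
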