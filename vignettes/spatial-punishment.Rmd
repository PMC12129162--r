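---
title: "Direct and indirect punishment on the lattice: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct and indirect punishment on the lattice: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatpunish)
```

## The model

`spatpunish` simulates a two-stage prisoner's dilemma on an $L \times L$
square lattice with periodic boundaries. Every site holds one player with
one of four strategies, combining a first-stage move with a second-stage
choice:

* **CN** — cooperate, don't punish;
* **DN** — defect, don't punish;
* **CP** — cooperate and punish defectors;
* **DP** — defect and punish (other) defectors.

**Stage 1 (the dilemma).** Each player plays a pairwise prisoner's
dilemma with its eight Moore neighbors. Payoffs are parametrized by a
single dilemma strength $r \ge 0$: mutual cooperation pays $R = 1$,
mutual defection $P = 0$, a unilateral defector earns $T = 1 + r$ and
the exploited cooperator $S = -r$. For every $r > 0$ this satisfies
$T > R > P > S$ and $2R > T + S$, so defection is individually tempting
while mutual cooperation is collectively optimal. Stage-1 payoffs depend
only on the cooperate/defect component of each strategy.

**Stage 2 (punishment).** Punishing strategies pay a cost $\gamma$ per
act to impose a fine $\beta$ on each defector within their *punishment
scope*:

* *direct* punishment — the scope is the eight first-order (Moore)
  neighbors;
* *indirect* punishment — the scope is the sixteen second-order
  neighbors, the sites at toroidal Chebyshev distance exactly two
  (equivalently, neighbors of neighbors excluding the focal site and its
  direct neighbors). The punisher thus sanctions defectors who harm its
  *neighbors*, not itself;
* *none* — no second stage; with $\beta = \gamma = 0$ this is also the
  limit in which CP/CN and DP/DN become payoff-indistinguishable, which
  is the punishment-free baseline used throughout.

Punishment is unconditional and pairwise: every punisher fines every
defector in its scope in every payoff evaluation. A player's total
payoff is the plain sum of both stages over its interaction partners
(8 partners in stage 1; 8 or 16 in stage 2), not a degree-normalized
average — so under indirect punishment a player has up to 24 distinct
interaction partners.

**Dynamics.** Evolution is asynchronous Monte Carlo with pairwise Fermi
imitation. One elementary update draws a focal player $i$ uniformly at
random, draws a model player $j$ uniformly from $i$'s eight direct
neighbors, computes both *total* payoffs $\Pi_i, \Pi_j$ on the current
configuration, and lets $i$ copy $j$'s strategy with probability

$$ w_{i \leftarrow j} = \frac{1}{1 + \exp\{(\Pi_i - \Pi_j)\,\kappa\}}. $$

One Monte Carlo step consists of exactly $N = L^2$ elementary updates,
so each player updates once per step on average. $\kappa$ is the
imitation strength: $\kappa \to 0$ gives random imitation
($w = 1/2$ exactly), large $\kappa$ makes imitation essentially
deterministic in the payoff sign. Note the sign convention: larger
$\kappa$ means *less* noise, the inverse of the common
selection-temperature parametrization.

## Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `r` | dilemma strength; $T = 1+r$, $S = -r$ | (required) | payoff, relative to $R - P = 1$ |
| `beta` | fine per punishment act | 0 | payoff units |
| `gamma` | cost per punishment act | 0 | payoff units |
| `kappa` | imitation strength | 10 | dimensionless |
| `L` | lattice side | 50 | sites |
| `mode` | `direct` / `indirect` / `none` | `direct` | — |
| `steps_total` | Monte Carlo steps | 5000 | steps |
| `steps_average` | trailing averaging window | 500 | steps |

`kappa = 10` is the strong-imitation regime in which the cost/fine
phase structure is studied; all defaults can be overridden per run.
Two dilemma strengths serve as reference baselines: $r = 0.05$, where
network reciprocity alone sustains cooperation at a level of roughly
56% without any punishment, and $r = 0.2$, where cooperation vanishes
without punishment. The interesting punishment phenomenology lives at
$\beta, \gamma \ll R$: fines and costs that are small against the
mutual-cooperation payoff of $8R$ per step.

### The desk-scale protocol

The package defaults implement a deliberately scaled-down protocol:
$L = 50$ (2 500 players), 5 000 Monte Carlo steps, time averages over
the trailing 500 steps, and 5 replicate runs per configuration
(`run_ensemble()`, `sweep_parameter()`). A full-scale protocol
($L \ge 100$, more than $10^5$ steps, averages over the last 2 000
steps, 50 replicates) is reachable by overriding exactly those fields
of `pd_params()` — nothing else changes. At desk scale every sweep in
the test-suite and the acceptance script completes in minutes on one
core, at the price of larger replicate-to-replicate spread and small
finite-size shifts of phase boundaries; we quote cost ($\gamma$)
thresholds to about $\pm 0.02$ and fine ($\beta$) thresholds to about
$\pm 0.06$ at this scale. Nucleation of punisher clusters from random
initial conditions is strongly stochastic at $L = 50$: single runs near
a phase boundary either fixate on full cooperation or collapse, and
only the ensemble mean is meaningful there.

## What the initial-condition generators emulate

`init_random()` draws each site's strategy independently and uniformly
— the standard well-mixed start from which all sweeps and phase maps
are run. `init_block()` partitions the lattice into equal contiguous
blocks, one strategy each, to replay invasion fronts with clean
interfaces; the default layout places CN, CP in the top half and DN,
DP in the bottom half (`[CN, CP; DN, DP]` row-major). The arrangement
of the four quadrants is a package choice — the qualitative outcomes
(CP expansion at low cost under indirect punishment, DN takeover at
high cost, CP resistance under direct punishment) do not depend on the
permutation, only the transient does.

These generators emulate the study conditions, not empirical data:
there is no mutation, no heterogeneity in $\beta, \gamma, \kappa$, no
network disorder. Tests passing at desk scale therefore demonstrate
internal correctness of the model and the reproducibility of its phase
structure, and say nothing about robustness to those real-world
features.

## Numerical choices

* **Payoffs are recomputed from scratch** for both players at every
  elementary update; no incremental caching. The compiled engine makes
  this affordable (a full desk-scale run is under a second); the pure-R
  updater `elementary_update()` is the readable reference and consumes
  the RNG identically, so `L^2` reference updates reproduce one
  `mc_step()` bit for bit — this equivalence is property-tested.
* **Fermi exponent clamping.** $(\Pi_i - \Pi_j)\kappa$ is clamped to
  $\pm 700$ before exponentiation; with $\kappa = 10$ and payoff gaps
  of order 25 a naive `exp()` would overflow. Probabilities saturate to
  $\{0, 1\}$.
* **RNG.** Everything runs off R's generator: `set.seed(seed)` makes a
  run fully reproducible, and replicate $k$ of an ensemble uses
  `seed + k`. Sweep configurations derive per-point seeds from a hash
  of (mode, axis, value), so sweep results are invariant to grid
  ordering and replicate order. Each elementary update consumes exactly
  three uniforms (focal site, model neighbor, acceptance), whether or
  not the imitation is a no-op.
* **Absorbing-state fast path.** A monomorphic lattice can never change
  again under pairwise imitation, so the engine stops drawing random
  numbers once only one strategy remains and copies the recorded
  fractions (and any remaining snapshots) forward. The emitted
  trajectory is identical to simulating on; runs that fixate early just
  cost less.
* **Threshold reading.** On ensemble means at finite $L$, "cooperation
  extinct" is read as level $< 0.01$ and "full cooperation" as
  $> 0.99$, absorbing residual Monte Carlo noise. `find_threshold()`
  evaluates *every* grid point (no bisection), because the fine
  response under indirect punishment is reentrant and non-monotone,
  then optionally refines the bracketing interval once.
* **Stabilization criterion.** For pooling punishment-event ledgers
  "before strategy proportions stabilize", a trajectory counts as
  stabilized at the first step where every strategy fraction has ranged
  over at most `tol = 0.005` within the trailing `window = 200` steps.
  Both knobs are explicit arguments; the criterion is a package
  convention, not part of the model.

## Design choices on genuinely open points

* **Second-order neighborhood.** "Neighbors of neighbors, excluding
  direct neighbors" is implemented as the Chebyshev-distance-2 ring
  (the $5\times5$ ball minus the $3\times3$ ball, 16 sites). A
  brute-force neighbors-of-neighbors enumeration is property-tested
  equal on several lattice sizes. $L \ge 5$ is enforced so the ring
  never aliases under the periodic wrap.
* **Indirect scope is exclusive.** Under indirect punishment a punisher
  does *not* additionally sanction first-order defectors; the stage-2
  scope is exactly the 16-ring.
* **Phase-map sign convention.** `phase_map()` reports cooperation
  differences as *direct minus indirect*, so the region where the
  indirect form wins is negative; the convention is recorded in the
  result's `difference_convention` attribute.
* **Reemergence detection.** The fine sweep under indirect punishment
  has three regimes: cooperation is established near $\beta \approx
  0.1$, then second-order free-riders (CN, who enjoy others' costly
  punishment without paying $\gamma$) displace CP at intermediate
  fines and defection creeps back, and cooperation reemerges at large
  fines. `reemergence_threshold()` defines the intermediate window as
  the scan points with cooperation $\le 0.5$ and reports the first
  recovery after it. At desk scale the dip can stay above $0.5$
  (the window deepens with system size); the function then anchors the
  window at the cooperation minimum of the scan and requires the
  recovery to also eliminate defection (defector fraction $< 0.05$),
  the signature of restored full cooperation. Both cuts are arguments.
* **Ledger restriction.** Punishment-event distributions include only
  active punishers (at least one act imposed) and actually punished
  defectors, matching the quantities of interest: what punishing
  *costs* those who do it, and how hard defectors are actually hit.
  Per-defector received counts are structurally capped at 8 (direct)
  vs 16 (indirect) — the mechanism by which the indirect form
  concentrates fines on defectors at cluster boundaries without a
  proportional rise in per-punisher cost.

## Worked example

```{r example, eval = FALSE}
library(spatpunish)

# punishment-free baseline at low dilemma strength
base <- pd_params(r = 0.05, mode = "none", seed = 100)
run_ensemble(base, replicates = 5)$cooperation
#> [1] 0.5590877   (about 56% cooperation without any punishment)

# indirect punishment at low cost: full cooperation
p <- pd_params(r = 0.2, beta = 0.2, gamma = 0.01, mode = "indirect",
               seed = 100)
run_ensemble(p, replicates = 5)$cooperation
#> [1] 1

# the same cost under direct punishment leaves DN coexisting with CP
run_ensemble(pd_params(r = 0.2, beta = 0.2, gamma = 0.01,
                       mode = "direct", seed = 100))$mean
#>    CN    DN    CP    DP
#> 0.000 0.406 0.594 0.000
```

## Known limitations

* Square lattice with Moore neighborhoods only; no von Neumann option,
  no heterogeneous or higher-order networks, no aperiodic boundaries.
* No antisocial punishment (cooperators are never punished), no
  second-order punishment of non-punishers, no probabilistic or
  budget-limited punishment, no mutation.
* Desk-scale defaults trade precision for speed; phase boundaries carry
  the finite-size tolerances stated above, and the intermediate
  free-rider window under indirect punishment is shallower than at full
  scale.
* The punishment-event ledgers pool per-step configuration snapshots of
  a single run; they are not averaged across replicates.
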