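---
title: "Patch loss, the competition-colonization tradeoff, and oscillating food-web complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch loss, the competition-colonization tradeoff, and oscillating food-web complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchweb)
```

## The model and its assumptions

`patchweb` models a metacommunity of many identical habitat patches
(think islands). Each patch can hold one subpopulation of each species;
all species disperse globally. The state variables are patch occupancy
fractions: `P_i` for basal species, `A_i` for consumers. A fraction `U`
of patches is permanently destroyed and unavailable to everyone.

Three assumptions do the real work:

* **Basal species exclude one another within a patch.** Their
  colonization term sees only patches free of *any* basal species
  (`1 − U − Σ P_j`), and occupied patches change hands by *competitive
  displacement*: a colonizer of species `i` arriving at a patch held by
  `j` takes it with probability `H_ij`. Displacement is immediate — no
  within-patch coexistence or transient competition dynamics.
* **Consumers do not compete for patches.** A consumer's colonization is
  proportional to encounters with its prey
  (`Σ_j θ_ji P_j + Σ_k δ_ki A_k`) and to its own vacant-patch fraction
  `1 − U − A_i`. This is bottom-up control: a consumer's persistence is
  set entirely by its prey's equilibrium occupancies.
* **The predation graph is acyclic** (no loops, no cannibalism), so
  consumer equilibria can be solved prey-before-predator, and top-down
  pressure (`μ`, `φ`) only adds extinction terms.

The competition–colonization tradeoff couples the two basal traits:
under the strict hierarchy `H_ij = 1 (i < j)`, species 1 displaces
everyone but colonizes slowest (`c^P_1 < … < c^P_{n_P}`). Regional
coexistence then rests on fugitive dynamics — inferior competitors
surviving in patches the dominants have not yet reached — and habitat
destruction, by thinning the dominants, can *admit* new species. That is
the mechanism behind the non-monotone diversity profiles.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `cP` | basal colonization rates | evenly spaced on [0.45, 0.8] (alternative range [0.25, 1]) | per unit time |
| `eP` | basal intrinsic extinction | 0.2 | per unit time |
| `cA` | consumer colonization | 0.625 | per unit time |
| `eA` | consumer intrinsic extinction | 0.05 | per unit time |
| `mu`, `phi` | top-down extinction on basal / consumer prey, per feeding link | 0.05 | per unit time |
| `U` | fraction of destroyed patches | swept over [0, 0.95] | dimensionless |

These defaults are the standard parameterization used throughout the
package and its tests; `assign_cc_tradeoff()` fills them in. The
"irregular" spacing option draws `cP` i.i.d. uniform from the range and
sorts it — the simplest construction consistent with irregular spacing —
so the strict ordering of the tradeoff is preserved while the gaps vary.
A single basal species receives the upper endpoint of the range.

The balance point `U = 1 − e/c` is worth internalizing: beyond it a
species cannot persist even alone, so the sweep invariably ends in an
empty community.

## Steady-state protocols

Two routes to the steady state are implemented, and they check each
other.

**Numerical protocol** (`run_to_steady_state()`): integrate the coupled
system for 15,000 time units, then average each species' occupancy over
the next 5,000; a species whose averaged occupancy falls below 10⁻⁶ is
deemed extinct and reported at zero. Species are never removed
mid-integration — occupancy zero is absorbing in the dynamics, so
thresholding the average suffices. The default initialization
`(1 − U) / (2S)` per species keeps the basal sum inside the feasible
region; the steady state is insensitive to it (verified in the tests).
Integration uses `deSolve` with `lsoda` at `rtol = 1e-8`,
`atol = 1e-10` — tolerances chosen so occupancies near the 10⁻⁶
extinction threshold are resolved. The Dormand–Prince pair is available
via `method = "ode45"`, but for these smooth, mildly stiff occupancy
systems `lsoda` reaches identical steady states orders of magnitude
faster, so it is the default.

**Analytic route** (`basal_equilibrium_analytic()`,
`consumer_equilibrium_analytic()`), valid when `mu = phi = 0`: the basal
per-capita growth rate is exactly Lotka–Volterra,
`r_i = b_i + Σ_j M_ij P_j`, giving the candidate coexistence point
`P* = −M⁻¹b`. Feasibility is enforced by community assembly: species
with non-positive solutions are dropped most-negative-first and the
reduced system re-solved; dropped species whose invasion growth rate at
the candidate point is positive are re-admitted. Since every `M_ij ≤ 0`,
species with `b_i ≤ 0` can never assemble and are excluded at the
outset. A singular reduced system (or a non-converging assembly loop)
falls back to the numerical protocol with a warning. Consumers then
follow in topological order from `A*_i = 1 − U − e^A_i / (c^A_i Σ prey)`,
zeroed when the prey sum vanishes or the solution is non-positive — the
bottom-up cascade.

On regular instances the two routes agree to ~10⁻¹¹ (the acceptance
script reports the worst deviation over 50 random webs). *Regular*
matters: an equilibrium sitting within ~10⁻³ of an exclusion boundary
approaches it at a vanishing exponential rate, and no fixed burn-in can
settle it; the random-instance generators used for cross-validation
redraw such marginal cases rather than pretending 15,000 time units
decide them.

Numerical guards: trajectory values more negative than `−100·atol` abort
with an error; smaller undershoots (inevitable at absorbing boundaries)
are clamped to zero before averaging. The occupancy bounds
`0 ≤ P, A ≤ 1 − U` and `Σ P_i ≤ 1 − U` are asserted as properties in the
test suite rather than enforced during integration.

## Synthetic food webs

The empirical island webs that motivate the default size classes —
(S, L) = (14, 23), (15, 25), (24, 34), (28, 55) with 3, 4, 4 and 6 basal
species — are not distributed with their adjacency structure, so
`generate_web()` produces random topologies with the same aggregates
instead. The generator places consumers in a random trophic order, wires
each to at least one prey drawn from the basal set and the consumers
below it (guaranteeing acyclicity and a basal-rooted chain for every
consumer), and scatters the remaining links uniformly over the valid
lower-position pairs. Chains of unequal length, and hence omnivores,
arise naturally.

What this emulates: the size, connectance and layered, basal-rooted
character of small island webs. What it does not: empirical degree
distributions, diet contiguity (as in niche or cascade models), or any
particular web's actual topology. Passing tests on these synthetic webs
therefore demonstrate properties of the *model dynamics* across
plausible topologies, not a reproduction of any empirical web's
response curve.

## Competition structures

* `hierarchical_H(n)`: the strict hierarchy; `RI = 0`. An optional rank
  permutation decouples competitive rank from colonization rank (a
  "local tradeoff" scenario hook; the package makes no claim that this
  matches any particular published construction).
* `weakened_H(n, w)`: `H_ij = (1 + w)/2` above the diagonal,
  `(1 − w)/2` below — the minimal one-parameter interpolation between
  strict dominance (`w = 1`) and symmetric coin-flip contests
  (`w = 0`).
* `intransitive_H(n, target_RI, seed)`: randomized single-pair dominance
  flips from the hierarchy, hill-climbing on `|RI − target|` with
  restarts. Relative intransitivity is the cyclic-triad proportion:
  cyclic triads (computed from the score sequence,
  `choose(n,3) − Σ choose(d_i, 2)`, and verified against brute-force
  census in the tests) divided by the maximum attainable —
  `(n³−n)/24` for odd `n`, `(n³−4n)/24` for even. Attainable RIs form a
  discrete grid (e.g. multiples of 1/5 at `n = 5`), so off-grid targets
  resolve to the nearest attainable value with a warning. Only `H` is
  perturbed; the colonization ranking lives in the parameter set and is
  untouched.

## Complexity metrics

A food chain is a directed path from a top species (one nobody eats) to
a basal species; lengths count links by default (`convention = "nodes"`
counts species — the literature uses both, and printed values for
unknown topologies cannot distinguish them). Mean food chain length
averages over *all* such paths, computed by memoized dynamic programming
over the DAG and verified against exhaustive path enumeration. A species
is an omnivore when it has at least two prey and is reached from the
basal level by paths of at least two distinct lengths. Connectance is
`2L / (S(S−1))`. Basal diversity uses the inverse Simpson index
`1 / Σ q_i²` on relative abundances `q_i = P_i / Σ P_j` of surviving
basal species.

The realized web at a steady state is the induced subgraph on
non-extinct species, with consumers left preyless removed iteratively —
the structural expression of bottom-up control.

## The sweep and its oscillation statistic

`run_sweep()` walks a patch-loss grid (default 0 to 0.95 in steps of
0.005, fine enough to resolve the narrow coexistence bands that appear
at larger `n_P`), solving each level analytically when no top-down rates
are present (with spot cross-validation against the numerical protocol)
and numerically otherwise. `mode = "basal_only"` zeroes predation and
drops consumers, isolating the basal subsystem.

The model describes oscillations qualitatively; the package
operationalizes them as the number of local maxima of the inverse
Simpson profile after a window-3 running median (suppressing
single-level grid noise). Local maxima are counted on the closed
interval — an endpoint run higher than its neighbour counts — which is
the standard definition on a bounded domain and treats a profile that
starts at a diversity peak at `U = 0` the same as one that peaks
interiorly. Turning points are threshold crossings of individual basal
occupancies between adjacent grid levels, labelled `enter`/`leave`.

Two deterministic curiosities of the standard parameterization are worth
recording rather than hiding. With `n_P = 4` on the large range
[0.25, 1], the surviving relative abundances at `U = 0` and `U = 0.5`
are permutations of (3, 2, 1)/6, so the inverse Simpson profile attains
its global maximum at *both* levels — an exact tie; the package
accordingly asserts that the maximum is *attained* at some `U > 0`. With
`n_P = 3` on the same range the profile has one interior peak plus a
declining boundary maximum at `U = 0`. Both patterns are genuine outputs
of the model at the stated parameters.

The no-tradeoff control (equal `cP` under a strict hierarchy) collapses
everything: the dominant excludes all others at every `U`, richness
declines monotonically, and no turning points occur — the tradeoff is
the necessary ingredient.

## Problem sizes used in the packaged checks

The test suite and acceptance script work at the scale the model was
designed for: webs up to `S = 28`, basal subsystems up to `n_P = 6`,
50 random webs for the analytic-vs-numerical comparison, 191-level
sweeps for the diversity profiles, and coarser 13-level sweeps for
full-web (predation-on) experiments, where each level runs the full
20,000-time-unit protocol. A full-web sweep at the default grid
resolution is a desk-scale computation (a few minutes); the packaged
checks use the coarser grid because the qualitative non-monotonicity
they assert is already visible there.

## Known limitations

* Patch occupancy is deterministic mean-field: no demographic
  stochasticity, no explicit patch geometry or dispersal limitation.
* Displacement is instantaneous and consumer competition absent by
  construction; `H` off the strict hierarchy is a phenomenological
  interpolation, not derived from within-patch dynamics.
* Local stability of the assembled equilibrium is taken from the
  feasibility-plus-invasion construction and verified against
  integration, not proven spectrally.
* The synthetic web generator matches aggregate structure only; results
  on any *specific* empirical topology require supplying that topology
  (e.g. via `read_web_tsv()`).
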