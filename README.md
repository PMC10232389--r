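# patchweb

Patch-dynamic metacommunity models of complex food webs under habitat
loss, for theoretical ecologists studying how habitat destruction
reshapes community structure. The package implements Levins-type patch
occupancy dynamics for a food web whose basal species compete for
patches through a competition–colonization (C–C) tradeoff, and whose
consumers persist through bottom-up control. Its central result is that
diversity and food-web complexity do **not** decline smoothly as patches
are destroyed: along the habitat-loss gradient, basal species enter and
leave the community at "turning points", producing an oscillating
diversity profile that propagates up the web.

## The model

Basal species `i = 1..n_P` occupy a fraction `P_i` of habitable patches,
with a fraction `U` of patches permanently destroyed. Their dynamics
couple colonization, extinction, pairwise competitive displacement
(probabilities `H_ij`), and top-down predation by consumers `A_k`:

    dP_i/dt = c^P_i P_i (1 − U − Σ_j P_j) − e^P_i P_i
              + Σ_j (c^P_i P_i H_ij P_j − c^P_j P_j H_ji P_i)
              − P_i Σ_k θ_ik μ_ik A_k

Consumers `i = 1..n_A` colonize in proportion to encounters with their
prey (basal, via the binary diet matrix `θ`, and other consumers, via
`δ`) and suffer intrinsic and predation-driven extinction:

    dA_i/dt = c^A_i A_i (Σ_j θ_ji P_j + Σ_k δ_ki A_k)(1 − U − A_i)
              − e^A_i A_i − A_i Σ_k φ_ik δ_ik A_k

With predation disregarded (`μ = 0`), the basal per-capita growth rate
has Lotka–Volterra form `r_i = b_i + Σ_j M_ij P_j` with
`b_i = c^P_i (1 − U) − e^P_i` and
`M_ij = c^P_i H_ij − c^P_j H_ji − c^P_i`, so the coexistence equilibrium
is the linear solve `P* = −M⁻¹ b`; consumer equilibria
`A*_i = 1 − U − e^A_i / (c^A_i Σ prey)` then follow in topological
(prey-before-predator) order. The package provides both this analytic
route and the numerical protocol (integrate 15,000 time units, average
over 5,000 more, call species below 10⁻⁶ extinct), and cross-checks them
against each other.

The C–C tradeoff is the one necessary ingredient: basal species are
ranked from best competitor (species 1; strict hierarchy `H_ij = 1` for
`i < j`) to poorest, while colonization rates increase with the index.
Weakened hierarchies and intransitive (rock–paper–scissors-like)
tournaments, quantified by relative intransitivity `RI` (cyclic-triad
proportion), are also available.

## Worked example

Generate a 14-species web in the size class of a small island food web
(3 basal species, 11 consumers, 23 links), give the basal species evenly
spaced colonization rates on [0.45, 0.8] under a strict hierarchy, and
find the steady state with no habitat loss:

```r
library(patchweb)
web <- generate_web(3, 11, 23, seed = 7)
pars <- assign_cc_tradeoff(web, c(0.45, 0.8))
H <- hierarchical_H(3)
st <- run_to_steady_state(web, H, pars)
st
#> steady_state at U = 0.000: 6 of 14 species surviving
#>     B1     B2     B3     C1     C2     C3     C4     C5     C6     C7     C8
#> 0.4097 0.0000 0.0278 0.8782 0.0000 0.0000 0.6566 0.0000 0.6566 0.8782 0.0000
#>     C9    C10    C11
#> 0.0000 0.0000 0.0000
```

Without habitat loss the best competitor B1 dominates, the intermediate
colonizer B2 is competitively excluded, and only consumers whose diets
reach a surviving basal species persist. Sweeping patch loss for the
basal subsystem (predation off, the Lotka–Volterra fast path):

```r
sw <- run_sweep(web, H, pars, U_grid = seq(0, 0.6, by = 0.05),
                mode = "basal_only")
sw$metrics[, c("U", "n_basal", "inv_simpson")]
#>       U n_basal inv_simpson
#> 1  0.00       1    1.000000
#> ...
#> 10 0.45       3    2.591287
#> 11 0.50       3    2.248536
#> 12 0.55       2    1.092055
#> 13 0.60       2    1.185866
detect_turning_points(sw)$events
#>   U_lo U_hi species direction
#> 1 0.20 0.25      B3     enter
#> 2 0.35 0.40      B2     enter
#> 3 0.50 0.55      B3     leave
#> 4 0.55 0.60      B1     leave
#> 5 0.55 0.60      B3     enter
```

Destroying patches *frees* the inferior-but-faster colonizers from
displacement pressure: richness climbs from 1 to 3 and the inverse
Simpson diversity peaks at `U = 0.45` — maximal basal diversity at
substantial, not zero, habitat loss — before the community collapses as
`U` approaches each species' colonization–extinction balance point
`1 − e/c`.

A shell entry point wrapping the same functions is provided:

```sh
Rscript inst/scripts/patchweb.R generate --n-basal 3 --n-consumers 11 \
    --links 23 --seed 7 --out web.tsv
Rscript inst/scripts/patchweb.R sweep --config config.yaml --out sweep.csv
```

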