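# cbvsim

Stochastic simulation of competition between biogeochemical
cycle-biota variants (CBVs) — an eco-evolutionary box model for asking
whether "persistence selection" can act on nutrient-recycling pathways
through their climatic side effects.

## The problem

Natural selection acts on organisms; planetary habitability is a
property of geochemical cycles. `cbvsim` implements a minimal coupled
model that bridges the two scales. An idealized essential nutrient J
exists as three interconvertible variants (J1, J2, J3) in a well-mixed
open system with abiotic influx and removal. Four microbial species
(A–D) each carry a reaction-performing genotype (frequency *p*) that
drives one Michaelis–Menten interconversion, and a wild type that does
not. Two overlapping recycling pathways result: variant **AB**
(J1⇄J2) and variant **CDB** (J1→J3→J2→J1). Reactions A and B leak a
fraction ε_X of their flux as byproducts that react to form a
climate-like substance X. The X-cycle holds an initially inert
reservoir that must be fully titrated by this byproduct flux before
release; release plus an intrinsic bistable feedback can flip X
irreversibly to a high state, which — above a threshold — imposes a
per-capita kill rate α(X) on species C. Variant AB thereby suppresses
variant CDB through slow, initially decoupled geochemistry: the
variants compete by climatic impact, not by within-species fitness.

The core pieces, in the model's notation:

- growth: `dM/dt = g0 M (1 − (M/K)²)`, minus `α·M` for species C;
- fitness: `W_p = W0 (1 + s·J_substrate)`, `W_q = W0`; frequency drift
  `dp/dt = (W_p − W̄)/W̄ − m_p + m_q` with per-event mutation sampling
  (p→q rate `m0`, q→p rate `m0²`);
- reactions: `R = Rmax·J·BE/(Km + J·BE)` with biological enhancement
  `BE = min(ω, n_p·r̄)`;
- X-cycle: byproduct flux `Xvar = Xvar0·Rmax·XA·XB/(Km + XA·XB)`,
  reservoir titration `dXres/dt = −Xvar·Xres` with release only after
  depletion, bistable feedback between `Xon` and `Xoff`, suppression
  `α = α0/(1 + e^{−kα(X − Xsuppress)})` for `X ≥ Xsuppress`;
- integration: Euler–Maruyama on three nested clocks (biology,
  J-cycle slower by τ_J, X-cycle by τ_J·τ_X), with demographic noise
  coefficients derived from the binomial variance of mutation
  sampling.

The package provides the full seeded integrator (compiled hot loop),
every model operation as a documented R function, the experiment
harness (timescale-contrast runs, replicate-averaged parameter sweeps,
suppression/dominance correlation analysis), a YAML config interface
and a command-line tool.

## Worked example

The headline experiment: identical parameters and seed, two X-cycle
timescale ratios. With τ_X = 10 the byproduct flux titrates the
reservoir within the horizon; release flips X to its high state and
suppression eliminates species C.

```r
library(cbvsim)
par <- cbv_params(Xres_init = 12, tau_X = 10)
sim <- run_simulation(par, run_config(n_steps = 1e5, seed = 4,
                                      record_every = 5000))
print(sim)
#> <cbv_sim> 1e+05 biological steps, seed 4
#>   tau_J = 2, tau_X = 10, s = 0.01, m0 = 0.1, Xvar0 = 1, alpha0 = 1
#>   final: mean J = 1.000, X = 3.994, alpha = 1.000, CBV share AB = 0.500
```

The final state shows the displaced regime: X has settled at its high
stable state (≈ 4, beyond the suppression threshold 3.5), α ≈ 1, and
species C's population has collapsed from K = 1000 to below 10
individuals (`sim$final$M["C"]`). Re-running with `tau_X = 20` and the
same seed leaves the reservoir partially titrated, α(t) = 0
throughout, and the system at its initial equilibrium — the contrast
that makes timescale separation, not biology, the deciding variable.
`run_single()` runs such contrasts in one call; `run_sweep()` and
`correlate_sweep()` reproduce the replicate-averaged sweeps and the
suppression/dominance correlations; `plot(sim)` draws the standard
four-panel display.

A command-line interface is installed with the package:

```sh
cbvsim run   --out out/ --seed 7 --tau-x 10,20
cbvsim sweep --out out/ --row feedback --reps 50
cbvsim correlate --in out/sweep_replicates.csv --out out/
```

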