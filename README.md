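# spinesim

Mechanochemical simulation of spontaneous dendritic-spine shape
fluctuations in 2D.

Dendritic spines — the protrusions carrying most excitatory synapses —
fluctuate in size and shape even without any synaptic plasticity.  The
driver is fast actin turnover concentrated in a handful of discrete
*polymerization foci*, each pushing the membrane outward for a few seconds
before its barbed ends vanish.  `spinesim` couples:

* a **stochastic focus model** — per time-step, every filament with an
  uncapped barbed end can branch, be capped (removed), have its minus end
  uncapped, or be severed.  Branching is attenuated by the membrane load
  through a Brownian ratchet,
  `γ_branch = φ·k_on·δ·a · exp(−‖F_mem‖δ/(k_B T B)) / B`,
  so `B = 0` is absorbing and foci have finite lifetimes;
* a **Helfrich-type membrane** — a closed polygon with energy
  `E = P·Ω + τ·S + 2κ Σ H²ds`, fixed PSD and neck chords, moved by the
  overdamped force balance `dx/dt = ζ(F_mem + F_fil)` with classical RK4,
  adaptive interval halving at a displacement tolerance, and edge-based
  remeshing;
* an **analysis stack** — area mean/SD/autocorrelation, bootstrap errors,
  Welch tests across replicate ensembles, and a recursive estimator that
  predicts the area trace from the focus count alone:
  `Ā(t_j) = Ā(t_{j−1}) − Φ(Ā(t_{j−1}) − A_s) + m·n_f(t_j) + b`.

See `vignette("spine-shape-fluctuations")` for the model, its assumptions,
and the numerical choices.

## Worked example

```r
library(spinesim)

params <- spine_params()                   # reference parameter set
rest   <- relax_to_rest(init_spine_mesh(params), params)
rest$A_s
#> [1] 0.5009704

# five simulated minutes with four initial foci and ongoing nucleation
tr <- run_simulation(params, 5 * 60, seed = 2,
                     mesh = rest$mesh, A_s = rest$A_s)
tr
#> <spine_trace> 2401 records over 300.0 s; area 0.5010-1.1043 um^2 (A_s = 0.5010); 31 foci died

s <- area_statistics(tr)
round(c(mean = s$mean_area, sd = s$sd_area, lifetime = s$mean_lifetime), 3)
#>     mean       sd lifetime
#>    0.724    0.188    4.270
```

The spine relaxes to a resting area `A_s ≈ 0.50 μm²`, and transiently
active foci push the area up to values fluctuating well above it; each
focus lives a few seconds.  Single-focus ensembles reproduce the
deterministic steady state of the barbed-end count:

```r
steady_state_barbed_ends(0, params)        # rate-equation fixed point
#> [1] 7.15589
set.seed(1)
mean(replicate(50, simulate_focus(10, 0, params, max_steps = 8e4)$mean_B))
#> [1] 7.089757
```

A command-line front end is installed with the package
(`system.file("cli", "spinesim", package = "spinesim")`) with subcommands
`run`, `sweep`, `focus`, `stats`, and `fit-estimator`.

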