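# oscflow

Discrete-element simulation and analysis of **self-propelled soft disks
with actively oscillating radii flowing through a narrow constriction**,
in two dimensions.

The package is aimed at researchers in active matter, granular flow and
collective cell migration who want to study how *active deformation*
changes clogging at a bottleneck. Densely packed crowds of motile cells
(lymphocytes in lymphoid organs are the motivating example) keep flowing
under conditions where rigid grains would jam; the idealised model here
isolates one candidate mechanism — periodic shape change — in the
simplest possible setting: disks whose radii oscillate as

r_i(t) = r0 (1 + A sin(ω t + φ_i)),

driven toward a bottom orifice by a Helbing–Farkas–Vicsek-type force
m(v_f e_d − v)/τ with e_d = (0, −1), and interacting by linear elastic
repulsion plus velocity-proportional tangential friction,

F_c = Σ_j g(ξ_ij) [ k_n e^n + k_t ((v_j − v_i)·e^t) e^t ] + boundary terms,

with overlap ξ_ij = (r_i + r_j) − d_ij and g(z) = max(z, 0). The
reference system (all defaults of `sim_config()`) has N = 200 disks,
k_n = 500, k_t = 2k_n, v_f = 3.3 in a 20 × 150 box with an orifice of
width D = 2.8 — just 40% wider than one particle diameter. Exiting
particles are recycled to the top, so the discharge is stationary.

Two headline phenomena are reproducible with the package:

* **Clog-to-flow transition**: rigid disks (A = 0) arrest; the flow rate
  grows monotonically with the oscillation amplitude.
* **Flow-rate resonance**: at fixed amplitude the flow rate is maximised
  at an optimal frequency ω\* that tracks the contact natural frequency
  √(k_n/m) (≈ 22 for the reference stiffness), as for a driven damped
  harmonic oscillator.

The analysis stack mirrors the standard granular-discharge toolkit:
flow rate from discharge-curve regression with 95% CI and the identity
Q = 1/⟨dt_out⟩, Clauset–Shalizi–Newman power-law fits of the inter-exit
time tail (α, dt_out^min), burst/clog decomposition and the flowing
parameter Φ = ⟨dt_f⟩/(⟨dt_c⟩+⟨dt_f⟩) (forced to 0 when α ≤ 2), bulk
contact observables (⟨P_free⟩, ⟨ρ⟩, ⟨n_c⟩, ⟨ξ_c⟩) in the region
x ∈ [2,18], y ∈ [2,30], and sweep orchestration with ω\* location and
the ω\* = k_n^γ scaling fit.

## Worked example

```r
library(oscflow)

cfg <- scaled_config(A = 0.15, omega = 25, T = 500, seed = 1)  # N = 60 column
sim <- run_simulation(cfg)
sim
#> <oscflow_sim>
#>   N = 60, T = 500, A = 0.15, omega = 25, k_n = 500, seed = 1
#>   exits: 169, recycled: 164
#>   frames: 1001 (every dt_k = 0.5)

analyze_events(sim$events, T = cfg$T)
#> flow analysis: 169 exits
#>   Q = 0.322 [0.3166, 0.3274], exits/T = 0.338
#>   alpha = 2.59, dt_out_min = 1.9, Phi = 0.33 (intermittent)
```

169 particles passed the orifice in 500 time units. The discharge-curve
slope gives a flow rate Q = 0.322 particles per time unit (tight 95% CI:
the flow is steady on average), the inter-exit-time tail follows a power
law with exponent α = 2.59 — above 2, so the mean clog duration is
finite — and the system spends Φ ≈ 33% of its time in flowing bursts:
an intermittent state. Setting `A = 0` in the same configuration arrests
the flow within a few exits (Φ = 0); sweeping `omega` via
`run_sweep()`/`find_omega_star()` shows the flow-rate maximum near
ω\* ≈ 25.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/oscflow.R simulate --config my.yaml --out run1/
Rscript inst/cli/oscflow.R analyze --events run1/events.csv --T 500 --out run1/analysis.json
Rscript inst/cli/oscflow.R sweep --param omega --values 5,15,25,40,60 --seeds 3 --out sweep1/
```

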