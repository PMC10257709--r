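---
title: "Methods: simulating constriction flow of self-propelled, radius-oscillating disks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating constriction flow of self-propelled, radius-oscillating disks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscflow)
```

## The model

`oscflow` simulates a two-dimensional crowd of `N` self-propelled soft
disks driven toward a narrow orifice at the bottom of a rectangular box.
The model is motivated by densely packed collectives of motile cells
(e.g. lymphocytes trafficking through lymphoid tissue), which avoid
jamming despite extreme crowding, plausibly because each cell actively
changes shape as it moves. The model strips this down to the simplest
ingredients: Helbing–Farkas–Vicsek-type driving and contact forces, plus
a prescribed oscillation of each disk's radius.

Each particle obeys

$$ m \,\dot{\mathbf v}_i = \mathbf F_{d,i} + \mathbf F_{c,i}, $$

with a driving force that relaxes the velocity toward a free speed $v_f$
in the fixed goal direction $\mathbf e_d = (0,-1)$ over a time $\tau$:

$$ \mathbf F_{d,i} = m \,\frac{v_f \mathbf e_d - \mathbf v_i}{\tau}, $$

and pairwise/boundary contact forces with linear elastic repulsion and a
velocity-proportional tangential friction, active only at positive
overlap $\xi_{ij} = (r_i + r_j) - d_{ij}$:

$$ \mathbf F_{c,i} = \sum_j g(\xi_{ij})\left[k_n \mathbf e^n_{ij}
   + k_t \big((\mathbf v_j - \mathbf v_i)\cdot \mathbf e^t_{ij}\big)\,
   \mathbf e^t_{ij}\right] + \text{(boundary terms)}, $$

where $g(z) = z$ for $z \ge 0$ and $0$ otherwise, $\mathbf e^n_{ij} =
(\mathbf x_i - \mathbf x_j)/d_{ij}$ points from $j$ to $i$ so the normal
term repels, and $\mathbf e^t = \mathrm{rot90}(\mathbf e^n)$. Boundary
contacts use $\xi_{ib} = r_i - d_{ib}$ and the wall-frame friction
$k_t(-\mathbf v_i \cdot \mathbf e^t)\mathbf e^t$; a disk can touch up to
two boundaries at once and all contributions are summed.

The *active deformation* is a kinematically prescribed radius
oscillation,

$$ r_i(t) = r_0\,\big(1 + A \sin(\omega t + \phi_i)\big), $$

with one fixed random phase $\phi_i \sim U[0, 2\pi)$ per particle. With
$A = 0$ the system is monodisperse and rigid; with $\omega = 0$ it is a
static polydisperse mixture (radii frozen at distinct values).

All quantities are dimensionless with $m = r_0 = \tau = 1$. The
reference system is `sim_config()`: $N = 200$, $k_n = 500$,
$k_t = 2 k_n$, $v_f = 3.3$, a $20 \times 150$ box whose bottom wall has
a centred orifice of width $D = 2.8$ (only 40% wider than one particle
diameter, so rigid disks clog readily). Particles falling below
$y = -15$ are reinjected at a random non-overlapping position with
$x \in (2, 18)$, $y \in (100, 150)$, so $N$ is conserved and the
discharge reaches a statistically stationary state.

## Numerical scheme

* **Integrator.** Velocity Verlet with time step $dt = 10^{-4}$. The
  driving and friction forces depend on velocity, so the end-of-step
  force is evaluated with the predictor velocity
  $\mathbf v + \mathbf a\,dt$; the resulting $O(dt)$ inconsistency is
  negligible because $dt$ is far below every force timescale ($\tau = 1$,
  stiff-contact period $2\pi\sqrt{m/k_n} \approx 0.28$ at the reference
  stiffness, fastest oscillation period $2\pi/100 \approx 0.063$). The
  end-of-step acceleration is cached, so the loop costs one force
  evaluation per step.
* **Pair search.** A Verlet neighbour list (cutoff $2 r_0 (1+A)$, skin
  $0.4\,r_0$) built through a uniform cell grid and rebuilt only when
  some particle has moved more than half the skin. Forces are identical
  to an all-pairs evaluation; the test suite asserts this against a pure
  R oracle assembled from the exported scalar force functions.
* **Boundaries.** The walls are four segments (two sides, two bottom
  pieces flanking the orifice); contacts use the point–segment distance,
  so the orifice lips — the inner endpoints of the bottom segments — act
  as corner points with the same contact law, which is the standard
  discrete-element treatment. A particle centre exactly on a wall line is
  a degenerate-geometry error.
* **Radii.** The per-particle $\sin/\cos$ pair is advanced by an exact
  rotation each step and refreshed from `sin()`/`cos()` every 4096 steps,
  so the recorded radii match the closed form to ~1e-12 and never leave
  $[r_0(1-A),\, r_0(1+A)]$.
* **Events and recording.** An exit event is logged whenever a particle
  centre crosses $y = 0$ moving downward, with the crossing time linearly
  interpolated inside the step; a particle that re-enters and crosses
  again is counted again. Frames (`t, id, x, y, vx, vy, r`) are recorded
  every $dt_k = 0.5$.
* **Initialisation and recycling.** Sequential rejection sampling places
  particles at least one radius from every boundary with no overlaps;
  initial velocities are zero. Reinjected particles are also placed by
  rejection sampling; their velocity is reset to zero by default
  (configurable via `recycle_keep_velocity`) — zeroing avoids injecting
  kinetic energy at the top of the column. If the reinjection region is
  transiently too crowded (cap of 10^4 draws), the particle is parked
  below the removal line and retried next step, never dropped.
* **Determinism.** All randomness (phases, placement, recycling) flows
  through R's RNG seeded from `config$seed`; identical configurations
  give byte-identical event logs and trajectories.

## Flow statistics

The discharge is characterised from the exit-event log:

* `flow_rate()` fits a least-squares line to the cumulative exit count
  over an analysis window (default: from $t = 100$ or the first exit,
  whichever is later — the filling transient is not part of the
  stationary discharge) and reports the slope $Q$ with its 95%
  confidence interval, alongside the identity estimator
  $Q = 1/\langle dt_{out} \rangle$. The regression curve is anchored at
  the window edges so arrested stretches reduce the slope.
* `fit_power_law()` implements the Clauset–Shalizi–Newman estimator for
  the inter-exit-interval tail: continuous MLE
  $\hat\alpha = 1 + n \big[\sum \ln(x_i/x_{min})\big]^{-1}$ with
  $x_{min}$ chosen to minimise the Kolmogorov–Smirnov distance over the
  unique sample values (ties toward smaller $x_{min}$, i.e. the larger
  tail). The optional parametric bootstrap goodness-of-fit p-value is
  off by default. Note that the selected $x_{min}$ carries substantial
  sampling variance — on mixture samples it tends to land above the true
  onset of the power law — which propagates into the burst/clog
  decomposition; the synthetic-log tests therefore validate the
  decomposition at the generator's stored cutoff and the blind CSN
  pipeline separately.
* `decompose_bursts_clogs()` calls an interval a *clog* when
  $dt_{out} \ge dt_{out}^{min}$ and merges maximal runs of sub-cutoff
  intervals into single *bursts*; burst and clog durations sum exactly to
  the spanned log time.
* `flowing_parameter()` computes
  $\Phi = \langle dt_f\rangle / (\langle dt_c\rangle + \langle
  dt_f\rangle)$ and forces $\Phi = 0$ when the fitted $\alpha \le 2$,
  because the clog-time mean then diverges: the state is clogged in the
  long-run limit even if finite runs show bursts. Labels: clogged
  ($\Phi = 0$), intermittent, flowing ($\Phi = 1$). Note that $\Phi$ with
  mean-based numerators is *not* monotone under adding an arbitrary clog
  (a clog shorter than the current clog mean raises $\Phi$); the property
  tests assert the forms that do hold.
* `bulk_observables()` evaluates, per recorded frame, the contactless
  probability $P_{free}$, number density $\rho = n/(16 \times 28)$,
  number of contacting particles $n_c$, and mean overlap $\xi_c$ in the
  bulk region $x \in [2,18]$, $y \in [2,30]$. Membership is by particle
  centre; contact status counts partners outside the region too (a
  particle is "free" only if it touches nothing). $\xi_c$ averages, per
  contacting in-region particle, the summed overlap with all its
  partners, so an isolated touching pair contributes its overlap once per
  member.
* `resonance_amplitude()` is the driven damped oscillator amplitude
  $1/\sqrt{(2\omega\omega_0\zeta)^2 + (\omega^2 - \omega_0^2)^2}$, a
  closed-form reference curve for interpreting the flow-rate resonance.

## Experiments

`run_sweep()` runs one simulation per (grid value, replicate seed) for a
swept parameter in $\{A, \omega, v_f, k_n\}$ (with $k_t = 2k_n$ enforced
when $k_n$ is swept, keeping the friction force roughly constant as
overlaps shrink), analyses each event log, and aggregates seed means.
Per-run seeds derive deterministically from the master seed and grid
position; with an output directory the sweep is resumable.

`find_omega_star()` locates the flow-rate optimum as the grid argmax of
the seed-mean $Q$ (ties toward lower $\omega$). Its uncertainty combines
half the local grid spacing with a bootstrap-over-seeds spread of the
argmax, in quadrature — a package-level substitute for a more elaborate
error analysis, chosen because the argmax on a finite grid has exactly
those two error sources. Flat responses and boundary optima are flagged.

`fit_scaling()` fits $\omega^* = k_n^\gamma$ by zero-intercept least
squares in log–log space (the headline one-parameter form), together
with a two-parameter variant $\omega^* = c\,k_n^\gamma$ and the fixed
$\gamma = 1/2$ prefactor of $\omega^* = c\sqrt{k_n}$, which expresses
the hypothesis that the optimum tracks the contact natural frequency
$\omega_0 = \sqrt{k_n/m}$.

## Synthetic fixtures

The `make_scenario()` registry provides millisecond-scale deterministic
initial conditions (free particle, overlapping pair, wall press, lip
touch, a three-disk arch spanning the orifice, an oscillating
singleton). The arch coordinates are a hand-placed wedged triple that
relaxes under the contact law into a force-balanced symmetric arch and
blocks the exit for at least 50 time units; the relaxed symmetric arch is
itself an unstable equilibrium (it collapses on ~100 time-unit horizons
from rounding-level asymmetry), which is why the wedged placement — whose
blocking behaviour is the property the fixture exists to provide — was
frozen instead of the relaxed coordinates.

`sample_power_law()` draws from a pure power law by inversion,
$x = x_{min} u^{-1/(\alpha - 1)}$, and `sample_intermittent_log()`
assembles event logs alternating exponential-gap bursts with power-law
clogs, storing the generating parameters (including the analytic
$\Phi$) as an attribute so tests never re-derive ground truth.

## What the synthetic and scaled systems do and do not show

Test and acceptance runs use two problem sizes, chosen once as the
package's standard study conditions:

* a **scaled column** (`scaled_config()`: $N = 60$, box $20 \times 60$,
  reinjection $y \in (40, 60)$, runs of $T = 500$) preserving the
  constriction physics — same $D$, $k_n$, $v_f$, $dt$, particle
  properties — at ~20x lower cost. It cleanly reproduces the clog-to-flow
  transition in amplitude and the flow-rate resonance near
  $\omega^* \approx 25$ at the reference stiffness.
* the **reference-size column** ($N = 200$) run for shorter times
  ($T = 300$–$1000$) for the quantities that need full column depth: the
  $\omega = 0$ arrest statistics, the bulk contact observables (the
  measurement region must sit inside the packing; in the shallow scaled
  column it pokes out above the pile and $P_{free}$ is inflated), and the
  $\omega^*$–$k_n$ ordering (at the highest stiffness the scaled column's
  resonance curve is flat-topped within seed noise over a broad frequency
  band, so its argmax does not resolve the scaling; the deep column
  does).

Neither setting emulates biology: disks are not volume-conserving cells,
the oscillation is kinematic rather than force-driven, and there is no
substrate adhesion or overdamped limit. Passing tests establish the
mechanics and statistics of this idealised model, not claims about real
tissue. Short runs also carry finite-run caveats: flow rates at strongly
clogged parameters are biased by the arrest time, and CSN exponents from
few pooled events (e.g. the $\omega = 0$ case) have large sampling
error.

## Known limitations

* The tangential force is a velocity-proportional friction with no
  static (Coulomb) component, so static arches are stabilised by normal
  geometry alone and are typically metastable.
* The CSN $x_{min}$ selection is noisy on mixture distributions, and the
  burst/clog decomposition is sensitive to it (see above).
* `find_omega_star()` reports a grid argmax; plateau-shaped resonance
  curves yield argmax positions with uncertainty of order the plateau
  width, which the bootstrap component of the reported uncertainty
  captures only partially.
* Flow-rate confidence intervals come from an ordinary least-squares fit
  to an autocorrelated counting process; this is the conventional
  discharge-curve analysis, but it understates the true seed-to-seed
  variability, which is why sweeps replicate over seeds.
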