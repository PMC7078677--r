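---
title: "Modelling spontaneous shape fluctuations of dendritic spines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spontaneous shape fluctuations of dendritic spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinesim)
```

## The model

Dendritic spines — the micrometre-scale protrusions that carry most
excitatory synapses — show large, asymmetric shape fluctuations even in the
absence of synaptic plasticity.  `spinesim` implements a two-dimensional
mechanochemical model of these fluctuations in which the only drivers are a
handful of discrete actin polymerization foci pushing against a
Helfrich-type membrane.

**Membrane.**  The spine head contour is a closed, counterclockwise polygon
of vertices at target spacing $\delta_s$.  Two morphological constraints of
mature spines are built into the initial circle of radius $r_s$: vertices
above the chord at the post-synaptic density (PSD) radius are projected onto
that chord and frozen, and likewise below the neck chord.  The membrane
energy is

$$E = P\,\Omega + \tau S + 2\kappa \sum_k H_k^2\, ds_k,$$

with enclosed area $\Omega$, boundary length $S$, pressure difference $P$,
line tension $\tau$ and bending modulus $\kappa$.  The discrete curvature
$H_k$ is the signed inverse circumradius of a vertex and its two
neighbours — a second-order operator that is exact on circles — and $ds_k$
is half the sum of the adjacent edge lengths.  The membrane force is the
exact negative gradient of this *discretised* energy (analytic for all
three terms), so the force is consistent with the energy to machine
precision; the test suite verifies it against a central finite-difference
gradient.

**Actin foci.**  Each polymerization focus tracks only two integers: the
number of filaments with uncapped barbed ends whose minus end is capped
($m_c$) or uncapped ($m_u$); $B = m_c + m_u$ barbed ends generate force.
Per time-step $\Delta_t = 1/8$ s, every filament can (in this order)
branch, have its barbed end capped (which removes it), have its minus end
uncapped, and be severed if the minus end is uncapped.  The branching rate
per filament,

$$\gamma_{branch} = \phi k_{on} \delta a\,
  e^{-\lVert F_{mem}\rVert \delta / (k_B T B)} / B,$$

is a Brownian-ratchet attenuation of the free treadmilling velocity by the
membrane force at the focus centre, shared across the $B$ barbed ends.
Because branching is the only source of new barbed ends, $B = 0$ is
absorbing and every focus has a finite lifetime.  A deterministic
rate-equation twin (`steady_state_barbed_ends()`) gives the stationary $B$
the stochastic model fluctuates around; the acceptance suite checks the two
agree within Monte-Carlo error.

**Coupling.**  The foci push the membrane outward through a Gaussian kernel
of amplitude $\alpha$ and width $\sigma$ centred on the focus centre (a
membrane vertex), directed away from the focus nucleation point.  Vertices
move by an overdamped force balance $\dot x = \zeta (F_{mem} + F_{fil})$,
integrated per tick with classical Runge-Kutta (the actin force held
constant within a tick), and edges are split/collapsed to stay near
$\delta_s$.  New foci nucleate at rate $\gamma_f$ at membrane-proximal
(within 0.1 μm), PSD-distal (beyond 0.1 μm) points, weighted by
$e^{-d/\lambda}$ in the PSD distance $d$.

## Parameters

All defaults live in `spine_params()`.  The ones most worth knowing:

| parameter | default | unit | role |
|---|---|---|---|
| `dt` | 1/8 | s | time-step of the stochastic sweep and movement |
| `delta_s` | 0.03 | μm | target edge length; remeshing keeps edges in `[3/5, 4/3]·delta_s` |
| `r_s`, `r_PSD`, `r_neck` | 0.5, 0.3571, 0.0995 | μm | initial radius and the two chord constraints |
| `phi` | 75 | μm⁻² | branching amplitude; the free treadmilling velocity is `phi·k_on·delta·a ≈ 7.27 s⁻¹` |
| `gamma_cap`, `gamma_uncap`, `gamma_sever` | 1, 1/30, 1 | s⁻¹ | filament turnover |
| `gamma_f` | 0.1 | s⁻¹ | focus nucleation rate |
| `lam` | 0.025 | μm | PSD-distance scale of nucleation (small = near the PSD) |
| `alpha`, `sigma` | 3.8, 0.3 | pN, – | actin force kernel; peak per barbed end `alpha/(sigma√(2π)) ≈ 5.05` pN |
| `P`, `tau`, `kappa` | 85.7143, 15, 0.18 | pN μm⁻², pN μm⁻¹, pN μm | membrane energy coefficients |
| `zeta` | 0.002 | μm² s⁻¹ pN⁻¹ | mobility |
| `d_tol` | 1e-4 | μm | per-interval displacement tolerance of the integrator |

The 2D units are taken at face value: $P$ multiplies an area and $\tau$ a
length, so $E$ is not strictly an energy dimensionally — only force balance
matters, and all forces are consistent gradients of the same functional.

## Numerical choices

*Integration.*  Each tick is integrated with classical RK4; if any free
vertex would move farther than `d_tol` within an interval, the interval is
halved recursively and both halves are integrated (membrane force
re-evaluated at every stage and at interval boundaries).  The discretised
bending term makes edge-scale zigzag modes stiff: their rate is roughly
$\zeta\,16\kappa/\ell^3$ for edge length $\ell$, which exceeds $10^3\,
\mathrm{s^{-1}}$ at the remeshing lower bound.  The integrator therefore
pre-splits each tick to the depth required by both the displacement
tolerance and a linear-stability estimate for that mode; this changes
nothing about which intervals are accepted (every accepted interval still
satisfies the displacement bound) but avoids discovering the required depth
through failed trials.

*Resting shape.*  With the actin force off, the constrained membrane flows
to a characteristic resting shape whose area $A_s$ (≈ 0.50 μm² at
defaults) is the baseline of all fluctuation statistics.  Two facts make a
pure displacement criterion unreachable: vertices drift tangentially along
the contour indefinitely (the energy is invariant under reparametrisation,
so nothing pins their spacing), and the resulting remeshing events inject
small kinks.  `relax_to_rest()` therefore stops when the per-tick net
displacement falls below the requested tolerance *or* when the enclosed
area has been stationary to within 10⁻³ μm² over a 200-iteration window —
an operational stationarity criterion; the residual vertex jitter after the
plateau is below 10⁻³ μm per tick.

*Remeshing.*  Edges longer than $d_{max}$ are split at their midpoint
(midpoints of plateau edges are fixed like their endpoints); edges shorter
than $d_{min}$ lose one endpoint — never a fixed vertex, and the second in
cyclic order when both are free.  Fixed-vertex positions are never altered,
only copied.  A focus whose centre vertex disappears in a collapse is
re-centred on the nearest surviving vertex.

*Nucleation.*  1,000 uniform candidate points are drawn by rejection
sampling inside the polygon; candidates farther than 0.1 μm from the
membrane or within 0.1 μm of the PSD segment (the chord spanned by the
fixed PSD vertices) are discarded; one survivor is drawn with probability
$\propto e^{-d/\lambda}$; the focus centre is a uniformly chosen membrane
vertex within 0.1 μm of the nucleation point.  A nucleated focus seeds one
filament in the minus-capped (nascent Arp2/3) state: the seed count is not
fixed by the biology we model, one filament is the minimal choice, and it
is configurable through `nucleate_focus(initial_filaments = )`.  When the
focus centre later needs a membrane load, we use the Euclidean norm of the
membrane force at the centre vertex.

*Degenerate inputs.*  Three collinear vertices have zero curvature (not an
error); duplicate consecutive vertices are a geometry error; a collapse
that would leave fewer than three vertices is an error; candidate filters
that empty simply produce no focus that tick.

## What the simulations show — and what they cannot

A default run relaxes to the resting shape, inserts `n_f0 = 4` foci with
the standard nucleation rule, and then couples the stochastic actin sweep
to membrane motion.  Foci live for seconds (their death is a first passage
to $B=0$, accelerated by the membrane force their own pushing generates),
so with $\gamma_f = 0.1\,\mathrm{s^{-1}}$ the spine carries 0–3 foci at a
time and its area fluctuates asymmetrically around a value well above
$A_s$.  The area trace, focus count, mean barbed-end count, focus lifetime
log and periodic mesh snapshots are all recorded per run.

The analysis layer computes temporal mean and SD of the area, its
autocorrelation function (biased normalisation, lags to 10 min), a 50-fold
bootstrap SD of the mean (i.i.d. resampling of time points — an optimistic
uncertainty under autocorrelation, noted here deliberately), Welch tests
between replicate ensembles, and the recursive area estimator

$$\bar A(t_j) = \bar A(t_{j-1}) - \Phi(\bar A(t_{j-1}) - A_s)
  + m\,n_f(t_j) + b,$$

fitted by Levenberg–Marquardt least squares (`minpack.lm`), with
$\Phi \in [0,1]$ enforced and the start at
$(m, b, \Phi, \bar A_0) = (10^{-3}, 0, 10^{-3}, \text{first area})$.  The
$\Phi$ and $m$ fitted to different runs need not coincide even when their
printed values look similar; nothing in the package assumes they do.

Because the exact finite-element operators of the original formulation are
not part of this implementation, quantities that depend on the absolute
force scale at the discretisation level — resting area, mean spine area,
focus lifetime — should be read as this discretisation's realization of the
model, not as bit-compatible reproductions.  Statistical structure (focus
count distributions, the direction of parameter effects, the
area-vs-focus-count coupling exploited by the estimator) is the robust,
transferable content.

## Problem sizes used by the tests and the acceptance script

The upstream protocol analyses one 90-minute simulation per parameter value
plus fifteen 15-minute replicates.  A 90-minute default run costs roughly a
quarter of an hour on one CPU with this integrator, so the shipped checks
use scaled versions chosen once as the package's own test design:

* acceptance script: two independent 24-minute runs (fit on minutes 1–16,
  hold-out 16–24, transfer to the second run), 15 die-out replicates;
* test suite: a 10-minute and a 6-minute run for the estimator checks, 50
  die-out replicates, and parameter sweeps with 5 replicates per value at
  90 s (branching amplitude, nucleation rate) or 45 s (kernel width,
  nucleation distance) per replicate, using common random numbers (the
  same seed set for every value of the swept parameter) so that seed luck
  cancels from the comparison of value-level means.

The low-to-high direction of every swept response survives this scaling;
three-point monotonicity across all intermediate values does not (the
middle value sits within noise of its neighbours at this replicate
length), so the sweep tests assert the end-to-end directions.

## Known limitations

* 2D only: the model trades realism for the tractability that makes
  replicate statistics affordable; no 3D mesh, no projections.
* No plasticity: G-actin concentration and all rates are constant.
* No explicit filament geometry: lengths, branch angles and spatial
  filament positions are abstracted into the focus kernel.
* The neck is a hard constraint; neck-length dynamics are out of scope.
* The bootstrap SD ignores temporal autocorrelation (by design, documented
  above).
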