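---
title: "Forward modeling of extracellular potentials with lfpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modeling of extracellular potentials with lfpsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpsim)
```

## The model

Extracellular potentials in brain tissue are generated by the transmembrane
currents of nearby cells. `lfpsim` computes them in two steps.

**Step 1 — compartmental cable dynamics.** A morphology is split into `N`
compartments, each small enough that its membrane potential can be taken as
uniform. Kirchhoff's current law at each node gives, for a passive membrane,

$$C_n \frac{dV_n}{dt} = -g_{L,n}(V_n - E_L) - \sum_s g_s(t)(V_n - E_s)
  + I_{inj,n}(t) + \sum_{m \in \mathrm{adj}(n)} g_{nm}(V_m - V_n),$$

with axial conductances $g_{nm} = 1/(R_{h}(n) + R_{h}(m))$ from half-cylinder
resistances $R_h = R_a (L/2)/(\pi d^2/4)$. The net transmembrane current of
compartment $n$ — capacitive plus ionic plus synaptic — is what drives the
extracellular field. We compute it from the discrete identity

$$I_{mem,n} = \text{(axial inflow into } n\text{)} + I_{inj,n},$$

evaluated at the solved step, rather than by differentiating $V$: axial flows
cancel pairwise, so $\sum_n I_{mem,n} = \sum_n I_{inj,n}$ holds to floating
point at every step. A neuron with no electrode current is therefore exactly
current-conserving (a single compartment can generate no extracellular
potential at all; the simplest radiating configuration is the two-compartment
current dipole), while an intracellular electrode makes the cell a monopole,
because injected charge arrives through a wire rather than through the
membrane.

**Step 2 — volume-conductor forward model.** The tissue is treated as an
infinite, homogeneous, isotropic, purely ohmic medium with scalar
conductivity $\sigma$ (quasistatic approximation; potentials referenced to
zero at infinity). A point current $I$ at distance $r$ then contributes
$\phi = I/(4\pi\sigma r)$. Three source models map compartment currents to
potentials:

- *point source*: the current acts at the compartment midpoint;
- *line source*: the current is spread uniformly along the straight segment
  axis and the $1/r$ kernel is integrated in closed form,
  $\phi \propto \frac{1}{\Delta s}\log\frac{\sqrt{h^2+\rho^2}-h}
  {\sqrt{l^2+\rho^2}-l}$, with $\rho$ the perpendicular distance, $h$ the
  longitudinal distance from the segment end and $l = \Delta s + h$;
- *soma as sphere*: a single-compartment root soma is treated as a spherical
  source, all dendritic compartments as line sources. This method refuses to
  run (rather than silently mis-assigning the sphere) if the soma is not the
  root or spans several compartments.

All methods clamp the relevant distance from below at the compartment radius
(equivalent-sphere radius for spherical somata), so potentials are finite
even on the membrane. Far from the cell the three methods converge; close to
the membrane the line source is the most faithful.

Finite-size contacts average the potential over their uninsulated surface:
we draw `m` points uniformly on a flat disc (radial coordinate
$R\sqrt{u}$) and average the chosen method's point potential.

Because the forward map is linear, the matrix `C` with
`C[k, n] =` potential at contact `k` per unit current in compartment `n`
(the image of the identity current matrix) converts currents to potentials at
run time, `Φ(t) = C I(t)`, removing the need to store the full `N × T`
current matrix — for 1000 compartments sampled at 20 kHz for 1 s in 64-bit
floats, 160 MB of raw storage (`storage_estimate()`, 1 MB = 10⁶ bytes).

## Units

µm (length), ms (time), mV (voltage), nA (current), µS (conductance), nF
(capacitance), Ω·cm (axial resistivity), µF/cm² (specific capacitance),
S/cm² (conductance density), S/m (extracellular σ). This closure makes
$\phi[\mathrm{mV}] = I[\mathrm{nA}]/(4\pi\sigma[\mathrm{S/m}]\,r[\mathrm{µm}])$
hold without conversion factors.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| `Ra` | 150 Ω·cm | field-standard cytoplasmic resistivity |
| `cm` | 1 µF/cm² | near-universal membrane capacitance |
| `g_pas` | 1/30000 S/cm² | passive τ_m = 30 ms, typical pyramidal value |
| `e_pas`, `v_init` | −65 mV | resting potential |
| `sigma` | 0.3 S/m | standard cortical tissue conductivity |
| `d_lambda`, `f` | 0.1, 100 Hz | inter-node spacing ≤ 0.1 of the AC length constant λ_f = 10⁵√(d/(4πfR_a c_m)) µm; the count is always odd |
| `dt` | 0.0625 ms | power of two, exactly representable; resolves τ_m by three orders |
| synapse `tau`, `e_rev` | 2 ms, 0 mV | single-exponential excitatory conductance synapse |

The passive set (`comp_params()`) was fixed once as the standard passive
pyramidal parameterization; every quantitative check in the package runs
under it.

## What the synthetic morphologies emulate

`make_ball_and_stick()` (spherical soma + straight dendrite) and
`make_stick()` (pure cable) reproduce the geometry of the classic analytic
test cases: they have exact line-source representations and known
closed-form limits, which is precisely why they are used for validation.
They do **not** emulate real dendritic trees: no branching statistics, no
diameter taper, no spines, no active conductances. Passing tests on them
demonstrates that the discretization, solver and forward kernels are
correct — not that any particular biological LFP is reproduced. For real
morphologies, `read_swc()` accepts the standard 7-column SWC format (with an
optional `.rot` sidecar of default rotation angles, applied about the soma
center before any user rotation).

## Numerical choices

- **Solver.** Backward Euler (first order) is the default for robustness;
  Crank–Nicolson (second order) is used where spectral fidelity matters,
  e.g. the sinusoidal stick validation. Both are unconditionally stable on
  the branched system, solved per step by a sparse Cholesky factorization
  (refactored per step only when synaptic conductances make the diagonal
  time-dependent). Solver order is verified against the single-compartment
  RC closed form under dt-halving.
- **Synaptic conductances** are advanced by the exact event-decay recursion
  $g_{k+1} = g_k e^{-\Delta t/\tau} + \sum_{\text{spikes} \in (t_k,t_{k+1}]}
  w\,e^{-(t_{k+1}-t_s)/\tau}$, so no spike is lost between grid points;
  spikes before the simulation start contribute their decayed conductance.
  Recorded synapse currents use the post-step voltage.
- **Warm-up.** `tstart < 0` simulates but discards samples before `t = 0`,
  the standard way to remove onset transients; `t = 0` must lie on the time
  grid (checked).
- **Line-source evaluation** uses a three-case form of the closed-form
  integral (projection before / alongside / beyond the segment),
  algebraically identical to the single log expression but numerically
  stable in all regimes; it is validated against a dense Simpson quadrature
  of point sources over randomized segment/point configurations to a
  relative error below 10⁻⁶. Zero-length segments fall back to the point
  kernel. Clamping is applied per evaluation point, including each sample
  point of a surface average.
- **Surface sampling** uses a dedicated seeded RNG stream, fixed per contact
  (the sampled geometry is time-invariant), and restores the global RNG
  state so it cannot perturb stimulus randomness. Re-drawing the locations
  per time step would only add unbiased noise; fixing them keeps runs
  reproducible.
- **Degenerate inputs** are errors, not silent repairs: empty morphologies,
  single-point non-soma sections, forward/cyclic SWC parent references,
  multiple roots, mismatched `v_ext` shapes, non-commensurate recording
  grids, and `soma_as_point` on an unsuitable morphology all raise typed
  conditions.

## Design decisions where the design was open

- *Compartment diameter vs. 3D profile*: within a compartment the diameter
  profile is collapsed to its arc-length-weighted mean (radius) while the
  reported membrane area keeps the exact frustum value, so areas are
  conserved under refinement even though the radius is a summary.
- *Compartment indexing* is a counter in a nested loop over sections then
  within-section compartments, 1-based as is natural in R; section names
  follow SWC type codes (`soma[0]`, `dend[1]`, …).
- *`.rot` sidecars* are applied before user rotations (the sidecar is a
  property of the reconstruction, the user rotation of the experiment).
- *Input correlation* is operationalized as the Pearson correlation of 5 ms
  binned summed input counts; for selections of `n` from `N` shared Poisson
  trains its expectation is `n/N`, independent of the bin width, which only
  sets the estimator's variance. The bin width is configurable.
- *Parallelism is a contract, not an API*: population cells are simulated by
  forked workers or serially, with per-cell seeds derived as
  `(master·69069 + 30103·index + 7919·stream + 1) mod (2³¹−1)`, so the
  execution mode cannot change the result.
- *Serialization*: RDS is the lossless binary format; CSV (fixed `%.10g`
  formatting, streamable row by row with byte-identical output) is the text
  format.

## The independent stick oracle

For a uniform passive cable of length $L$ with sealed ends driven at one end
by a sinusoidal current $I_0 e^{i\omega t}$, the frequency-domain cable
equation $\lambda_c^2 V'' = V$ with
$\lambda_c = \lambda/\sqrt{1 + i\omega\tau_m}$ gives the transmembrane
current density in closed form,

$$i_m(x) = I_0\,\frac{\cosh((L-x)/\lambda_c)}{\lambda_c \sinh(L/\lambda_c)},$$

which integrates to $I_0$ exactly (all injected current leaves through the
membrane). `analytic_stick_lfp()` integrates this density against the
point-source kernel with an adaptive composite-Simpson rule (panels doubled
until successive estimates differ by < 10⁻⁹ mV). The oracle deliberately
shares no code with the cable or forward modules. Sealed-end boundary
conditions match a stick with no leak paths at its tips; the drive is a
current (the matching pipeline stimulus is a sinusoidal current clamp).

`run_stick_validation()` compares the full pipeline against this oracle: the
stick is simulated with Crank–Nicolson after a 300 ms warm-up (ten membrane
time constants), the line-source potential is projected onto the drive
frequency over five whole periods, and amplitudes are compared point by
point. The shipped check uses `nseg = 401`, `dt = 0.025` ms and lateral
points 50–500 µm; the discrepancy decreases monotonically under refinement
of `nseg` and `dt` (tested), and the problem sizes were chosen at the knee
of that convergence curve.

## Problem sizes used in the checks

Unit and property tests run on cells of 1–50 compartments and simulations of
tens of milliseconds; the randomized line-source property uses 10³
configurations against a 10⁴-point quadrature; the population checks use
3 cells × 5–32 compartments; the input-correlation check uses 1000 trains
over 100 s and ≥ 20 selection pairs; the stick validation uses 401
compartments × 14 000 steps. These sizes were chosen as the smallest at
which each property is sharply testable.

## Known limitations

- Passive membranes only: no Hodgkin–Huxley-type channels, so extracellular
  action-potential waveforms from active models are out of scope.
- The medium is infinite, homogeneous, isotropic and ohmic: no layered or
  anisotropic conductivity, no tissue interfaces, no frequency dependence,
  no electrode impedance model.
- The cable step assumes a constant extracellular potential (the scheme is
  not self-consistent); ephaptic feedback is not modeled, although an
  externally imposed field can be applied with `insert_v_ext()`.
- Cells in a population are independent — no synaptic connectivity between
  them.
- SWC is the only morphology input format.
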