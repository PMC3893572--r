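# lfpsim

Forward modeling of extracellular potentials around morphologically detailed
neurons, in R.

Extracellular recordings — spikes and local field potentials (LFPs) — arise
from the transmembrane currents of nearby neurons. `lfpsim` implements the
standard two-step biophysical scheme linking the two:

1. **Cable step.** The neuron morphology (SWC file or a built-in synthetic
   generator) is discretized into `N` compartments by the d_lambda rule, and
   the passive branched cable equation

   `g_{n,n+1}(V_{n+1} − V_n) − g_{n−1,n}(V_n − V_{n−1}) = C_n dV_n/dt + Σ_j I_nj`

   is advanced with an unconditionally stable implicit solver (backward Euler
   or Crank–Nicolson), with exponential-conductance synapses and
   current-clamp electrodes as stimuli. The recorded transmembrane currents
   `I_n(t)` satisfy Kirchhoff's sum rule `Σ_n I_n(t) = Σ_n I_inj,n(t)` to
   solver precision (exactly zero without electrode injection).

2. **Forward step.** In an infinite, homogeneous, isotropic, ohmic medium of
   conductivity σ, each compartment current contributes
   `φ(r, t) = I_n(t) / (4πσ |r − r_n|)`. Three source models are provided:
   point source (current at the compartment midpoint), line source (current
   spread along the segment axis, integrated in closed form), and the mixed
   soma-as-sphere method. Distances are clamped at the compartment radius, so
   potentials are finite everywhere. Finite-size contacts are handled by
   averaging over `m` seeded random locations on a flat circular disc, and a
   precomputed coefficient matrix `C` (`Φ(t) = C·I(t)`) lets potentials be
   accumulated at run time without storing currents.

Populations of independent cells share a Poisson spike-train pool; each cell
selects `n_select` of `n_trains` trains without replacement, which sets the
pairwise input correlation to `n_select/n_trains`, and single-cell potentials
add linearly into the population signal.

Units: µm, ms, mV, nA, µS, nF, Ω·cm, µF/cm², σ in S/m — a closure in which
`φ[mV] = I[nA]/(4πσ r[µm])` holds with no conversion factor.

## Worked example

A passive ball-and-stick cell receives one excitatory synaptic input on the
dendrite (70 % of the way up, i.e. around z ≈ 710 µm) firing at t = 20 ms;
two contacts record at soma level and near the synapse:

```r
library(lfpsim)

m    <- make_ball_and_stick(soma_diameter = 20, stick_length = 1000, stick_diameter = 2)
cell <- compartmentalize(m)                    # d_lambda rule -> 32 compartments
cell <- attach_exp_synapse(cell, comp_index_at(cell, "dend", 0.7),
                           weight = 0.002, tau = 2, e_rev = 0, spike_times = 20)

el  <- electrode_array(x = c(-130, -220), y = c(0, 0), z = c(0, 700),
                       sigma = 0.3, method = "line_source")
C   <- compute_coefficient_matrix(cell, el)    # 2 x 32, computed once
res <- simulate_cell(cell, sim_control(tstop = 100), method = "crank_nicolson",
                     runtime_sinks = list(C))
phi <- res$sinks[[1]]                          # 2 x 1601 mV
```

Printed extremes:

```
contact 1: extreme phi = +1.55e-05 mV at t = 23.06 ms
contact 2: extreme phi = -2.28e-05 mV at t = 20.88 ms
```

Contact 2, next to the synapse, sees a fast negative deflection — the
synaptic current sink. Contact 1, at soma level, sees a slower positive
deflection — the passive return (source) current leaving the proximal
membrane. This sink/source dipole pattern is the elementary building block
of the LFP. Amplitudes of ~10⁻⁵ mV for a single 2 nS input are why measured
LFPs reflect thousands of synchronous synapses.

The same run is available from the shell via the YAML-driven CLI:

```sh
inst/exec/lfpsim simulate config.yaml     # writes phi.csv
inst/exec/lfpsim estimate-storage --n-comp 1000 --duration-s 1 --rate-hz 20000
# -> 160 MB for raw currents; the coefficient-matrix scheme needs ~N/N_contacts less
```

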