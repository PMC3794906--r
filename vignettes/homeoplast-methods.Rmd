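---
title: "Homeostatic structural plasticity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic structural plasticity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`homeoplast` simulates a two-dimensional recurrent cortical network in which
*connectivity itself* is the plastic variable. Synapses have fixed strength
and there is no associative plasticity of any kind; instead, every neuron
grows and deletes discrete *synaptic elements* — axonal boutons ("plugs"),
excitatory dendritic spines and inhibitory postsynaptic densities
("sockets") — as a function of its own average activity, and synapses appear
when vacant complementary elements merge. Cortical reorganization after a
focal loss of input (the lesion projection zone, LPZ, of a focal retinal
lesion) then emerges from purely neuron-centric rules.

The model has three coupled layers, separated by time scale:

1. **Electrical activity (milliseconds).** Each of the 400 neurons (80%
   excitatory on a 20×16 grid, 20% inhibitory interleaved on a 10×8 grid,
   grid spacing 100 µm, placement jittered by a normal perturbation) is an
   Izhikevich neuron, `dv/dt = 0.04v² + 5v + 140 − u + I`,
   `du/dt = a(bv − u)`, with the regular-spiking constants
   `a = 0.02, b = 0.2, c = −65, d = 8` for *all* neurons: excitatory and
   inhibitory cells differ only in the sign of the synaptic current they
   deliver. Input is the sum of white-noise external drive
   (`N(mu_ext, sigma_ext²)` per millisecond, per-neuron multiplier in
   [0, 1]; deafferentation = multiplier 0) and the exponentially filtered
   spike trains of presynaptic neurons, weighted by the synapse counts
   `omega[i, j]` and a fixed strength `w_syn` (no delays).
2. **Calcium trace (seconds).** Each spike increments a calcium
   concentration by `beta`; otherwise it decays exponentially with
   `tau_ca`. The trace is the neuron's time-averaged activity sensor: at a
   steady rate r it averages `beta * r * tau_ca`.
3. **Structure (minutes of simulated activity; weeks of biological time).**
   Between connectivity updates (every 100 ms of simulated activity) the
   continuous element counts of the three classes integrate Gaussian growth
   curves `nu(2 exp(−((Ca − xi)/zeta)²) − 1)` with zeros at a minimum
   activity `eta` and a homeostatic set-point `eps`, the center
   `xi = (eta + eps)/2` and width `zeta = (eps − eta)/(2 sqrt(ln 2))` — the
   unique Gaussian-affine shape with those zeros, bounded to ±`nu`. At each
   update, discrete element records are reconciled to `floor(z)`: deletions
   draw uniformly from bound and vacant elements alike (breaking the
   synapse of a bound victim and leaving the counterpart element vacant on
   its owner), vacant elements decay with time constant `tau_vac` updates,
   new vacant records are instantiated for growth, and finally all vacant
   axonal elements are randomly matched into all vacant sign-matched
   dendritic elements (the smaller list into the larger), each proposed
   pair forming a synapse with the Gaussian distance probability
   `exp(−d²/(2 sigma_k²))`. Autapses are rejected; elements that fail the
   kernel test simply wait, vacant, for the next round.

The deletion and formation steps have analytic twins used as test oracles:
the expected synapse loss per partner under uniform deletion is
`n_delete * omega / n_total`, and the expected formation matrix is
`a_vac[i] d_vac[j] / max(sum a, sum d) * K(i, j)`, which the implemented
matching scheme reproduces in expectation (this was the criterion for
choosing "uniform matching of the scarcer side plus kernel acceptance"
among the matching schemes the verbal description admits).

# Parameters, defaults, and why

| parameter | default | units | rationale |
|---|---|---|---|
| `a,b,c,d,v_spike` | RS set, 30 | model/mV | one parameter set for all neurons |
| `dt` | 1 | ms | forward Euler; membrane advanced in two 0.5 ms half-steps (the classical practice for this neuron model) |
| `mu_ext, sigma_ext` | 2.5, 3 | current | see "Calibration" below |
| `w_syn` | 3 | current | calibrated so the intact network fires ~5–10 Hz |
| `tau_syn` | 5 | ms | standard fast-synapse filter |
| `beta, tau_ca` | 1.5e-4, 4e4 | —, ms | set-point rate ≈ 8.3 Hz; see below |
| `nu` | 3e-4 | elements/ms | full-size equilibrium by ~3000 updates, comfortably before lesion onset; post-lesion repair completes within the 5000-update post phase |
| `eps` | 0.05 | calcium | homeostatic set-point, shared by all classes |
| `eta` (axonal) | 0.5·eps | calcium | axons need substantial activity to grow |
| `eta` (dendritic) | 0.01·eps | calcium | must lie *below* the residual activity of the deprived center (see below) |
| `tau_vac` | 20 | updates | see "Calibration" |
| `sigma_k` | 2·spacing (1.25 scaled) | µm | rewiring range of a few hundred µm |
| lesion onset / post | 8000 / 5000 | updates | equilibrium is reached well before onset; 5000 post-updates map linearly to 72 days |

The analysis phases are the first 1000 (early), 2000–3000 (middle) and
4000–5000 (late) post-lesion updates, scaled proportionally when a protocol
runs a different post-lesion length.

# Calibration choices

Several constants are only weakly constrained by the biology and had to be
fixed by the package's own calibration, *before* the acceptance checks were
run. Three deserve explanation because naive choices make the model
qualitatively wrong:

**External drive.** The homeostatic narrative requires that external input
alone leaves neurons *below* the set-point (otherwise no recurrent
connectivity ever forms) but *above* the axonal threshold `eta_A`
(otherwise nothing ever grows from the empty initial state). For the
regular-spiking neuron at 1 ms noise steps this bracket is satisfied by
`mu_ext = 2.5, sigma_ext = 3` (≈ 6.3 Hz alone, calcium ≈ 0.038, between
`eta_A = 0.025` and `eps = 0.05`). A mean drive of 5 — the naive reading of
the "5 mV delivered on average every millisecond" estimate — puts the
*unconnected* neuron at ≈ 12 Hz, twice the set-point, and the structural
dynamics never start.

**Calcium sensor noise.** A Poisson-driven exponential trace has relative
standard deviation `sqrt(beta / (2 eps))` at the set-point — independent of
`tau_ca`. With the common textbook choice `beta = 1e-3` this is exactly
10%, so at most ~68% of neurons can ever sit inside a ±10% band around
`eps` and "the network is at the set-point" is not a well-defined state.
The default `beta = 1.5e-4` brings the intrinsic fluctuation to 3.9%
(and the homeostatic loop compresses it further); `tau_ca = 4e4` ms then
places the set-point rate at ≈ 8.3 Hz, inside the plausible 5–10 Hz band.

**Vacancy decay and the dendritic threshold.** Two failure modes frame
`tau_vac` and `eta_D`. If vacant elements decay much faster than the
pairing process can match them (mean matching wait ≈ 1/average kernel ≈ 10
updates), the axon surplus produced by the peri-LPZ after a lesion is
destroyed before it can bind into the LPZ and repair starves. If decay is
far slower than that, the pipeline of unbound elements keeps binding after
the population reaches the set-point and the network overshoots into slow
relaxation oscillations. `tau_vac = 20` updates sits between the two. For
`eta_D`, the deprived LPZ *center* retains only a trickle of horizontal
drive (calcium ≈ 0.001–0.005); a dendritic threshold above that residual
makes center dendrites retract, after which the center can never re-acquire
input — the no-repair phenotype — even under the "physiological" curve
ordering. `eta_D = 0.01 eps` keeps the ordering `eta_D < eta_A < eps` while
staying below the center's residual.

# The scaled scenario

`scaled_scenario()` is the package's test-scale world: a 100-neuron network
(10×8 excitatory grid), kernel width 1.25 spacings so the 5-spacing lesion
square still spans ≈ 4 kernel widths (preserving a genuinely deprived
center and the border-then-center repair sequence), and a shortened
protocol (2000 pre- + 4500 post-lesion updates). All qualitative
regimes of the full protocol — homeostatic maturation, sequential repair,
the no-repair and recurrent-self-repair growth-rule regimes, the axonal
overshoot, the peri-LPZ input manipulations and the remapping contrast —
reproduce at this size, and the test suite demonstrates them across seeds.

What a green test does **not** establish: quantitative agreement with
in-vivo element counts or rates (element counts per neuron are in the tens,
orders of magnitude below real spine counts); fidelity of the large-LPZ
boundary (the scaled large lesion covers ~60% of the plane rather than
~82%); and any behavior of the biological system outside the modeled
mechanism (no synaptic-weight plasticity, no conductance synapses, no
delays, no neuromodulation, no explicit retina/thalamus — the lesion is
purely the removal of external drive).

# Operationalized outcomes

The qualitative outcome matrix (repair / sequential repair / large-LPZ
repair / remapping) needs numeric cutoffs; these are this package's
operationalizations, config-exposed and deliberately coarse:

* **recovered** neuron: calcium ≥ 0.9·eps sustained for 5 consecutive
  snapshots (avoids flicker classification); **repair** = ≥ 90% of LPZ
  neurons recovered by the end of the run.
* **sequential** = the median recovery time of the border precedes the
  center's by more than one snapshot interval.
* **remapping** = ≥ 50% of LPZ excitatory neurons are responsive
  (≥ `theta_resp` spikes to their best stimulus), *selective* (best
  response ≥ 2× their median response across stimuli plus one spike), and
  prefer an input area outside the LPZ — with no single area holding ≥ 60%
  of those preferences. The selectivity and diversity conditions separate
  genuine retinotopic filling (adjacent representations enlarging into the
  LPZ from different sides) from the collective ignition of a recurrently
  self-repaired cluster, where one stimulus lights up the whole LPZ and the
  argmax label carries no spatial information.
* **overshoot** = the lesion/control ratio of mean peri-LPZ axonal elements
  exceeds 1.05, peaks in the middle phase, declines from its peak and stays
  above 1 in the late phase.
* **synchrony** contrast: the recurrent self-repair regime is detected by
  the prominence of the spectral peak of the binned LPZ population rate
  (plus a CV increase relative to its own pre-lesion state), not by the
  raw CV ordering between scenarios, which at the scaled size is within
  noise because the physiologically repaired small LPZ also synchronizes
  somewhat.

During the remapping assay connectivity is frozen, membrane state is reset
per stimulus, non-stimulated neurons receive zero external input (isolating
horizontal propagation), the stimulated area's current is scaled by each
neuron's input multiplier (so deafferented neurons receive no test input),
and the passed network object is never modified. Ties in the preferred-area
argmax break toward the lowest area index.

# Numerical choices

* Forward Euler with `dt = 1` ms, membrane equation in two half-steps;
  calcium and synaptic-filter decays use the exact per-step exponential
  factor, keeping the closed-form steady states tight.
* A spike first reaches postsynaptic membranes at the following
  millisecond step, at full (undecayed) strength.
* "Rounded off to the smallest integer" is implemented as `floor()`;
  discrete records are always reconciled *to* `floor(z)` (deletion
  shortfalls are `records − floor(z)`, creations are `floor(z) − records`),
  so continuous growth and discrete bookkeeping cannot drift apart.
* Randomness flows through four named streams derived from one master seed
  (placement, membrane noise, rewiring, assay), so the assay can never
  perturb the main trajectory and runs replay bit-exactly; the compiled
  integrator draws from R's RNG in the same order as the pure-R reference
  integrator and matches it bit for bit (floating-point contraction is
  disabled in the compiled code for exactly this purpose).
* Degenerate inputs: empty rasters, zero-length windows, empty vacancy
  lists and empty lesion squares are all defined (empty results or
  immediate errors, never silent misbehavior).

# Known limitations

* The full-size (400-neuron) default world reproduces the lesion
  phenomenology (verified for the equilibrium, sequential-repair, overshoot
  and remapping outcomes on spot checks), but the test suite validates the
  scaled scenario across seeds; seed-to-seed robustness at full size is not
  exhaustively tested.
* The border/center split of the scaled LPZ contains few neurons, so
  region medians are coarse; per-neuron outputs are exported so any
  re-split is possible post hoc.
* The matching step treats all vacant elements of one class as one global
  pool (proposals are uniform before the kernel test); schemes with
  locality-biased proposals would form synapses faster at equal expected
  topology but are not what the expectation formula describes.
* Simulation cost is dominated by the millisecond loop; wall time is
  roughly linear in `n * simulated-ms` plus rewiring churn.
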