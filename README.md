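# homeoplast

Homeostatic structural plasticity in a spiking cortical network: an R
package that simulates how a cortex-like recurrent network rewires itself —
synapse by synapse — after a focal loss of sensory input.

## The science

Neurons in the adult visual cortex continually form and retract dendritic
spines and axonal boutons, and after a focal retinal lesion the deprived
cortical region (the lesion projection zone, LPZ) reorganizes massively:
spine turnover rises most in the LPZ center, axons from the surrounding
intact cortex overshoot and are later pruned, and the retinotopic map fills
the LPZ back in from its border. `homeoplast` implements a model in which
all of this follows from one neuron-centric rule: each neuron aims for
homeostasis of its own average electrical activity.

Every neuron carries pools of discrete *synaptic elements* — axonal
boutons, excitatory spines, inhibitory postsynaptic densities. Their
continuous counts z follow Gaussian growth curves of the neuron's calcium
trace Ca (an exponentially filtered spike count):

    dz/dt = nu * (2 * exp(-((Ca - xi)/zeta)^2) - 1)

with zeros at a minimum activity `eta` and a homeostatic set-point `eps`
(`xi = (eta+eps)/2`, `zeta = (eps-eta)/(2*sqrt(ln 2))`). Below `eta` and
above `eps` elements are deleted; in between they grow. Vacant complementary
elements across the network are then randomly merged into synapses with a
distance-dependent Gaussian kernel `exp(-d^2/(2*sigma_k^2))`; deleting a
bound element breaks its synapse and frees the partner element. Electrical
activity is millisecond-scale Izhikevich spiking with fixed-weight synapses
— there is no synaptic-weight plasticity anywhere.

Whether the network repairs a lesion, repairs it sequentially from border
to center, repairs arbitrarily large lesions, and recovers a retinotopic
map turns out to depend only on the ordering of the thresholds `eta` for
axonal vs dendritic elements (low dendritic + high axonal threshold =
cortex-like behavior); the package reproduces that scenario matrix and the
associated element-dynamics signatures.

## Worked example

```r
library(homeoplast)

# 100-neuron rendition of the focal-lesion protocol: 2000 updates of
# self-organizing maturation, lesion, 4500 updates of reorganization,
# with a matched no-lesion control branched from the same network.
runs <- run_protocol_variants(scaled_scenario("physiological"), seed = 1,
                              variants = c("lesion", "control"))
summary(runs$lesion)
classify_outcome(runs$lesion)
overshoot_profile(runs$lesion, runs$control)$overshoot
```

```
plasticity run: scenario 'physiological', seed 1, 6500 updates (2000 pre + 4500 post)
  final: 647 synapses, mean calcium 0.0495 (set-point 0.050)
  per-region state at end of run:
     region  n    mean_ca at_setpoint
 lpz_border 19 0.05056697   1.0000000
 lpz_center 13 0.04620284   0.9230769
    outside  5 0.05067821   1.0000000
   peri_lpz 63 0.04973161   0.9841270
outcome: repair Yes | sequential Yes | large-LPZ repair - | remapping Yes
  (97% of LPZ recovered; border median 1550 vs center 1750; 93% remapped)
[1] TRUE
```

Reading the output: after the lesion removed all external input from the 32
LPZ neurons, horizontal rewiring restored 97% of them to within 10% of the
calcium set-point; the border's median recovery time (update 1550
post-lesion) precedes the center's (1750) — the wound heals from the rim
inward; at the final frozen-connectivity mapping assay 93% of LPZ neurons
acquired a selective preference for an input area outside the LPZ (the
retinotopic map filled in); and the peri-LPZ axonal element count
overshot its matched control with a middle-phase peak (the bouton
overshoot-and-pruning signature, `TRUE` from `overshoot_profile()`).

Key objects: `scenario_config()` / `scaled_scenario()` build protocols
(named scenarios: `physiological`, `aberrant_dendritic_high`,
`aberrant_both_low`, `large_lpz`, `peri_reduction_20`, `peri_blockade`,
`high_density`, `control`); `run_protocol()` returns a `plasticity_run`
with snapshots, checkpoints, rasters and logs; `element_dynamics()`,
`overshoot_profile()`, `remapping_assay()`, `synchrony_profile()` and
`classify_outcome()` compute the reported quantities; `save_run_outputs()`
/ `replay()` give manifest-checked bit-exact reproducibility. A thin CLI
lives at `inst/cli/homeoplast` (subcommands `run`, `assay`, `metrics`,
`replay`, `validate-config`).

## Acceptance script

`scripts/acceptance.R` rebuilds the default 400-neuron network under 200
independent placement seeds, applies the standard lesion square, and
recomputes from scratch the mean number of excitatory and inhibitory
neurons it encloses, writing the results as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The package vignette (`vignettes/homeoplast-methods.Rmd`) documents the
model equations, every tunable parameter with units and rationale, the
calibration analysis behind the defaults, the scaled test world, the
operationalization of the outcome matrix, and known limitations.
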