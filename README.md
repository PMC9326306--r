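# snnweaver

Data-driven construction of spiking neural network (SNN) models, and
deterministic generation of NEST-3 simulation scripts, in R.

Computational neuroscientists who build network models from the literature
face the same bookkeeping problem every time: neuron counts, post-synaptic
potential (PSP) amplitudes, dendritic geometry, bouton counts and
projection percentages come from many papers, in many units, often with
several conflicting values per quantity -- and all of it must end up as
simulator parameters (weights in pA, indegrees, masks, devices).
snnweaver keeps the whole model in one JSON document in which every
attribute carries its contributed values, data flags (`fixed`,
`to_optimize`, `objective`, `deactivated`) and references, and provides a
deterministic build that resolves the contributions collectively and
converts biology to simulator parameters through explicit transfer
functions.

The core conversions:

* **PSP to weight** -- for a leaky integrate-and-fire membrane
  (τ_m, C_m) with current-based alpha synapses of time constant τ_s, the
  peak PSC amplitude *w* that yields a requested peak PSP *V* is computed
  in closed form through the Lambert W function (verified in tests against
  an independently integrated membrane ODE to 0.5%).
* **Dendritic attenuation** -- a synapse at proportion *r* of dendritic
  extent *l* attenuates its weight by exp(−r·l/λ) with the electrotonic
  length λ = √(d·R_m / 4R_a); `r = None` disables attenuation.
* **Anatomy to connectivity** -- with *P*% projecting source neurons, α
  boutons per axon and redundancy ρ, the fixed indegree is
  K = round(P/100 · N_src · α / (N_tgt · ρ)); outdegree, Bernoulli and
  Gaussian-distance rules are also supported, and a model-level `scale`
  adjusts all counts at build time.
* **Stimulus aggregation** -- n independent per-synapse Poisson trains at
  f Hz superpose to one n·f Hz generator.

Realization (`realize_model(spec, scale, seed)`) is a pure function of its
arguments; `emit_script()` renders byte-identical four-section PyNEST
scripts for equal realizations, and `package_outputs()` packs description
and script into a zip.  Importers map connectome node/edge JSON files to
populations/projections and NEST model templates to parameter tables, and
`grid_search()` implements two-stage weight calibration against
firing-rate target intervals.  The package emits simulation code but never
executes it; running NEST is your step.

## Worked example

The packaged balanced cortical network: 10,000 excitatory and 2,500
inhibitory neurons, PSPs of J = 1.4 mV (AMPA) and g·J = 5.6 mV (GABA)
with 0.5 ms rise time, bouton counts α = ε·N_target with ε = 0.1, 100%
projecting neurons, redundancy 1, proximal synapses on 600 μm / 1.6 μm
dendrites.

```r
library(snnweaver)

spec <- build_cortical_example(J = 1.4, g = 4)
validate_model(spec)
#> <validation report> no violations

real <- realize_model(spec, scale = 1, seed = 42)
real
#> <realization> cortical-balanced-network @ scale 1, seed 42
#>   population exc (excitatory): n = 10000
#>   population inh (inhibitory): n = 2500
#>   exc -> exc [fixed_indegree = 1000] w = 288.94
#>   exc -> inh [fixed_indegree = 1000] w = 288.94
#>   inh -> exc [fixed_indegree = 250] w = -1155.76
#>   inh -> inh [fixed_indegree = 250] w = -1155.76
```

Reading the output: every population receives ε·N_src afferents (1,000
excitatory, 250 inhibitory) -- exactly the ε = 0.1 random-network
expectation.  A 1.4 mV PSP on a τ_m = 10 ms, C_m = 250 pF membrane
converts to a 313.68 pA alpha-PSC peak; the proximal synapse position
(r = 0.1 of 600 μm, λ ≈ 730 μm) attenuates it by 0.9211 to +288.94 pA,
and the inhibitory weight is 4× larger and negative.  Collective
resolution works the same everywhere:

```r
resolve_attribute(list(param_entry(2), param_entry(4),
                       param_entry(100, flag = "deactivated")))
#> <resolved> 3  (2 contributions)
```

`emit_script(real)` then yields the runnable PyNEST script, and
`build_model(spec, out_dir = "out", zip = TRUE)` writes
`model_description.json`, `simulation.py` and `model_outputs.zip`.

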