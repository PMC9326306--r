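---
title: "From anatomical data to a runnable spiking network: the snnweaver workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From anatomical data to a runnable spiking network: the snnweaver workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snnweaver)
```

## The problem

Building a biologically grounded spiking neural network (SNN) model means
turning heterogeneous published measurements -- neuron counts, post-synaptic
potential (PSP) amplitudes, dendritic geometry, bouton counts, projection
percentages -- into the concrete parameters a simulator needs: synaptic
weights in pA, indegrees, connection masks, device wiring.  Doing this by
hand is error-prone and untraceable.  snnweaver makes the passage explicit:
a model lives in a single JSON document where every attribute carries its
contributed values, data flags and literature references; a deterministic
build resolves those contributions, applies transfer functions, and emits a
resolved description plus a PyNEST script for NEST 3.

The document partitions into six entity groups: the model header, neuronal
data (populations), connectomic data (projections), citations and notes,
simulator model templates, and simulations.  `load_model()` /
`save_model()` move it to and from canonical JSON (sorted keys, so equal
models are byte-identical on disk), and `validate_model()` reports every
violated invariant with its entity path rather than failing fast.

## Data flags and collective resolution

Any attribute may hold several entries, each flagged:

* `fixed` -- high-confidence values (neuron numbers, dendrite geometry,
  PSPs);
* `to_optimize` -- exploration ranges `[lo, hi]` (bouton counts, receptor
  locations);
* `objective` -- target behaviours (firing-rate ranges, spike-train
  metrics); these never feed parameter values, only calibration targets and
  script comments;
* `deactivated` -- excluded outliers, kept for the record.

`resolve_attribute()` computes the collective outcome at build time: the
unweighted mean for numeric entries (the source material says only
"average", so no weighting by recency or contributor is attempted), and for
categories the most frequent value by the importance index.  Two choices
were genuinely open and are fixed here as package policy:

* a `to_optimize` range contributes its **midpoint** -- the build must
  produce one runnable value, and the range is preserved in the resolved
  description (`optimizable_ranges`) for a future optimizer;
* importance-index **ties break toward the earliest-inserted** category,
  which keeps resolution deterministic under any entry ordering.

Adding a deactivated entry never changes an outcome, and resolving a
singleton returns it exactly; both properties are enforced by tests.

## Transfer functions

### PSP amplitude to synaptic weight

Populations declare receptor ports (AMPA, NMDA, GABA) with a PSP amplitude
$V$ (mV) and rise time $\tau_s$ (ms).  Synapses are current-based
alpha functions: a spike injects
$i(t) = w \, e \, (t/\tau_s) \, \exp(-t/\tau_s)$, a PSC of peak amplitude
$w$ at $t = \tau_s$.  For a leaky integrate-and-fire membrane with time
constant $\tau_m$ and capacitance $C_m$ (read from the neuron template's
`tau_m` / `C_m`), the membrane equation is linear, so the peak PSP is
proportional to $w$; `psp_to_weight()` returns the $w$ whose peak
deflection is exactly $V$.  The peak time solves a transcendental equation
through the secondary real branch of the Lambert W function
(`pracma::lambertWn`); the degenerate case $\tau_m = \tau_s$ uses the limit
form $V_{peak} = 2\tau w/(eC_m)$.  With ms/pF/pA/mV units no conversion
factors are needed.  The conversion is verified against an independently
integrated membrane ODE (Euler, 1 microsecond steps) to within 0.5% over a
grid of $\tau_m \in \{5,10,20\}$ ms, $C_m \in \{150,250\}$ pF,
$\tau_s \in \{0.2,0.5,2\}$ ms.

The rise time recorded with a PSP is interpreted as the alpha-function
synaptic time constant (the PSC time-to-peak).  Conductance-based neuron
templates (recognised by `cond` in the model name) are accepted in the
schema, but PSP conversion refuses them -- their PSP peak depends on the
driving force -- and requires an explicit `weight_override` on the
projection.

### Dendritic attenuation

A projection's receptor location $r \in [0,1]$ is the mean synapse distance
to the soma as a proportion of the target's dendritic extent $l$;
categorical values map to interval midpoints (proximal $\to$ 0.1, medial
$\to$ 0.4, distal $\to$ 0.8).  The weight is attenuated by a passive
exponential cable factor

$$a(r) = \exp\!\left(-\frac{r\,l}{\lambda}\right), \qquad
\lambda = \sqrt{\frac{d\,R_m}{4\,R_a}},$$

with dendrite diameter $d$, membrane resistivity $R_m$ (default 20,000
Ohm cm^2) and axial resistivity $R_a$ (default 150 Ohm cm); both constants
are exposed in `inst/extdata/cable_constants.conf` and through
`cable_constants()`.  With the generic cortical geometry ($l$ = 600 um,
$d$ = 1.6 um) $\lambda \approx 730$ um, so a proximal synapse loses about
8% of its weight.  Setting $r$ to None removes attenuation entirely.  A
single exponential is a deliberate simplification of full two-port cable
attenuation; `dendritic_attenuation()` takes a `factor_fn` argument so the
strategy can be swapped without touching the builder.

### Connection rules, redundancy and scale

Anatomical wiring converts to simulator connection rules.  For a projection
with $P$% projecting neurons, mean bouton count $\alpha$ per axon and
redundancy $\rho$ (contacts one axon makes on one dendritic tree),

$$K_{in} = \mathrm{round}\!\left(\frac{(P/100)\,N_{src}\,\alpha}{N_{tgt}\,\rho}\right),
\qquad K_{out} = \mathrm{round}\!\left(\frac{(P/100)\,\alpha}{\rho}\right),$$

rounded half-to-even and clamped at zero.  Redundancy both divides the
connection count and multiplies the weight (the $\rho$ contacts act
together), so the total synaptic drive is conserved.  Bernoulli and
Gaussian-distance rules take their `p` / `sigma` directly.  The formulas
are pinned by a consistency check: with $\alpha = \epsilon N_{tgt}$,
$P = 100$, $\rho = 1$ -- the balanced-random-network parameterization --
the indegree onto any population equals $\epsilon N_{src}$, exactly the
Erdos-Renyi expectation, and explicit instantiation on a 100x smaller
instance counts exactly $K$ afferents per target.

The model-header `scale` multiplies all neuron counts at build time
(`scale_count()`, clamped at 1); indegrees are then recomputed from the
scaled counts, since $\alpha$ is per-axon anatomy and does not shrink with
the model.  Because reduced networks are not dynamically equivalent to
full-scale ones, any build at `scale < 1` carries a warning.

### Stimuli

External drive is modelled as Poisson generators.  Independent per-synapse
trains superpose: $n$ synapses at $f$ Hz are one generator at $n f$ Hz
(`aggregate_poisson_rate()`).  A stimulus is either global or scoped to a
centre and radius; scoped member sets are precomputed from the realized
positions rather than left to a simulator-side mask, so the emitted script
is explicit about which neurons are driven.

## Realization and determinism

`realize_model(spec, scale, seed)` is a pure function: it validates,
selects the active simulation (or the first if none is marked), sizes and
places every population (uniform positions within the declared 2D/3D
bounds), overlays resolved parameter overrides on template defaults
(unresolved Nones keep the simulator defaults), resolves every projection,
and fixes stimuli and recordables.  One user-facing seed governs all
randomness; sub-seeds are derived with fixed per-purpose offsets
(placement per population, recordable selection), so adding a recordable
does not shift neuron positions.  Spatial masks follow the axon
organization: focused projections mask at the axon-domain radius; diffused
projections keep a finite-domain mask but drop it once the domain covers
the arena diagonal, which is how the wide-domain cortical example emulates
a spatially unstructured random network.  Self-connections and multapses
are disallowed for the degree-based rules (mirroring common simulator
defaults) and left to the simulator for probabilistic rules.  If no delay
is given, the synapse template's default applies, and failing that 1 ms
with a warning.

## Code generation

`emit_script()` renders a realization into a four-section PyNEST script --
initialization; creation of neural populations; network building; stimuli,
recordables, and simulation -- with kernel resolution, thread count and
seed set from the simulation settings, objectives as comments, and
populations/projections in declaration order.  Neuron positions are
emitted as literal coordinate lists (they are part of the realization, and
scoped stimuli depend on them); numbers use a fixed-locale shortest
practical decimal form, so equal realizations give byte-identical scripts.
Multisynapse templates receive one `tau_syn` entry per declared receptor
port, and connections address their port by index.  Template names pass
through verbatim; the emitter does not validate against an installed
simulator, and the package never executes the generated code -- running
NEST is the user's step.  The script's syntax is checked in tests by a
Python parser, not by execution.  `package_outputs()` packs description
and script into an uncompressed zip with stable member names (written
directly by the package, byte-deterministic including a fixed timestamp).

## Calibration

`grid_search()` implements the two-stage weight-calibration pattern: per
population and stimulation regime a target firing-rate interval is
declared, the error of an observed rate is its distance to the interval
centre normalized by the half-width -- "normalized" is fixed here so that
the interval boundary maps to error 1 -- and the per-pair errors are
summed by default (`combine` switches to mean or max).  The search
exhaustively evaluates the Cartesian product, holds `frozen` parameters
constant (stage two freezes the stage-one optimum), records failures as
infinite error, and breaks ties toward the first point in lexicographic
grid order.  The evaluator is an injected function -- typically "run the
emitted script, parse rates", in tests an analytic surrogate -- because
the package never launches a simulator.

## The example models and what they do (not) show

`build_cortical_example(J, g)` constructs the balanced two-population
network: 10,000 excitatory and 2,500 inhibitory LIF neurons, alpha
synapses with a common 0.5 ms rise time, PSPs $J$ mV (AMPA) and $gJ$ mV
(GABA), generic dendrites (600 um, 1.6 um), proximal synapses, all four
projections fixed-indegree with $\alpha = \epsilon N_{tgt}$,
$\epsilon = 0.1$, $P = 100$%, $\rho = 1$, diffuse wide-domain axons;
2,000 ms at 0.1 ms resolution in the unit square with Poisson drive for
the first 1,000 ms.  The drive's rate and weight are not fixed by the
reference description ("constant rate" only); the fixture uses 12,000 Hz
aggregate at 20 pA as a generic suprathreshold background, chosen once --
no reported quantity depends on them.

`build_striatal_example()` constructs five populations -- 38,237 dSPN,
38,237 iSPN, 1,047 FS, 644 LTS, 886 ChIN -- in a unit cube standing for
1 mm^3, all LIF with AMPA/GABA ports, connection PSPs as projection-level
weight overrides, a generic 0.2 ms delay, fixed-indegree rules with
spherical masks, and two-stage drive: a 300 Hz baseline generator per
population (150 synapses x 2 Hz) for the whole 1,500 ms and a 1,200 Hz
generator (150 x 8 Hz) superimposed from 1,000 to 1,500 ms -- the baseline
continues through the elevated phase, since the elevated input is
described as superimposed and baseline activity resumes unchanged
afterwards.  Connection-level numbers that the reference description does
not print -- bouton counts, mask radii, per-connection PSP weights, neuron
electrical constants -- are documented placeholders at plausible orders of
magnitude; only the population counts, delays and input rates above are
load-bearing.

`random_model(seed, n_pops, connectivity_density)` generates
invariant-respecting random models (multiple entries per attribute,
including deactivated and to-optimize ones; all four connection rules) for
property tests.

What passing tests show: the plumbing and the transfer mathematics are
exact -- sizes, indegrees, weights, attenuation, aggregation, determinism.
What they do not show: that the emitted models reproduce any particular
dynamical state (self-sustained activity lifetimes, striatal raster
statistics).  Those depend on running NEST and on the placeholder
parameters above, and are outside the package's scope.

## Numerical choices and problem sizes

* Degree rounding: half-to-even (R's `round`), clamped at 0; scaled counts
  clamped at 1.
* The Lambert-W branch point $\tau_m = \tau_s$ switches to the limit form
  below a relative difference of 1e-9.
* Canonical JSON uses full-precision numbers; python floats are emitted
  with R's 15-significant-digit shortest form.
* Tests integrate the PSP oracle at 1 us steps over 30 membrane time
  constants; realization tests run the worked examples at full scale
  (79,051 and 12,500 neurons -- both build in well under a second) and
  instantiation checks on the 100x smaller balanced instance.

## Known limitations

Single-valued parameters only (no distributions); Poisson spike trains are
the only stimulus modality; a subset of connection rules; no NMDA voltage
dependence, multi-compartment dendrites or short-term plasticity; no
simulator execution or HPC dispatch; model versioning and multi-user
ownership are carried as labels but not enforced.
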