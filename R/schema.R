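#' Model-description schema
#'
#' A model description partitions into six entity groups: the model header,
#' neuronal data (populations), connectomic data (projections), citations
#' and notes, simulator model templates, and simulations.  The constructors
#' below build the in-memory form; [load_model()] / [save_model()] move it
#' to and from its JSON file form, and [validate_model()] checks the
#' cross-cutting invariants.
#'
#' @name model_schema
NULL

REGIMES       <- c("excitatory", "inhibitory")
TRANSMITTERS  <- c("AMPA", "NMDA", "GABA")
CONN_RULES    <- c("fixed_indegree", "fixed_outdegree", "bernoulli_const_p",
                   "gaussian_distance")
AXON_ORGS     <- c("focused", "diffused")
RATE_STATES   <- c("resting", "excitation", "maximum", "disease")
RECORD_KINDS  <- c("spikes", "membrane_potential")
TEMPLATE_KINDS <- c("neuron", "synapse")
RECEPTOR_CATEGORIES <- c("proximal", "medial", "distal")

#' Create a literature reference
#'
#' @param doi_or_url DOI or URL of the source (must be non-empty).
#' @param description Free-text description.
#' @export
snn_reference <- function(doi_or_url, description = "") {
  if (!is_scalar_string(doi_or_url) || !nzchar(doi_or_url))
    stop("a reference requires a non-empty DOI or URL", call. = FALSE)
  structure(list(doi_or_url = doi_or_url, description = description),
            class = "snn_reference")
}

#' Create a modelling note
#' @param text Note text.
#' @param owner Owner label.
#' @param timestamp Free-text timestamp (kept verbatim for determinism).
#' @export
snn_note <- function(text, owner = "", timestamp = "") {
  structure(list(text = text, owner = owner, timestamp = timestamp),
            class = "snn_note")
}

#' Create a receptor specification
#'
#' Declares a receptor port available on a population: its transmitter, the
#' post-synaptic potential amplitude a single spike evokes at the synapse
#' (mV), and the rise time of the alpha-shaped response (ms).  A
#' population's receptor list describes the ports incoming projections may
#' attach to, so an excitatory population routinely also carries a GABA
#' port for its inhibitory afferents.
#'
#' @param transmitter `"AMPA"`, `"NMDA"` or `"GABA"`.
#' @param psp_amplitude_mv,rise_time_ms Entry lists (see [param_entry()]).
#' @export
receptor_spec <- function(transmitter, psp_amplitude_mv = list(),
                          rise_time_ms = list()) {
  if (!is_scalar_string(transmitter) || !(transmitter %in% TRANSMITTERS))
    stop("transmitter must be one of: ", paste(TRANSMITTERS, collapse = ", "),
         call. = FALSE)
  structure(list(transmitter = transmitter,
                 psp_amplitude_mv = psp_amplitude_mv,
                 rise_time_ms = rise_time_ms),
            class = "snn_receptor")
}

#' Create a firing-rate target
#'
#' A biologically plausible range of mean firing rates for one activity
#' state.  Firing-rate targets are objectives: they never feed parameter
#' values, but are emitted as comments on the simulation script and drive
#' calibration.
#'
#' @param state `"resting"`, `"excitation"`, `"maximum"` or `"disease"`.
#' @param lo_hz,hi_hz Range bounds in Hz, `0 <= lo_hz <= hi_hz`.
#' @export
firing_target <- function(state, lo_hz, hi_hz) {
  if (!is_scalar_string(state) || !(state %in% RATE_STATES))
    stop("state must be one of: ", paste(RATE_STATES, collapse = ", "),
         call. = FALSE)
  structure(list(state = state, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "snn_firing_target")
}

#' Create an objective/metric specification
#' @param metric Free-text metric name (e.g. "coefficient of variation").
#' @param target_value A number or `c(lo, hi)` range.
#' @param reference Optional [snn_reference()].
#' @export
objective_spec <- function(metric, target_value = NULL, reference = NULL) {
  structure(list(metric = metric, target_value = target_value,
                 reference = reference),
            class = "snn_objective")
}

#' Create a neural population
#'
#' @param name Population (cell-type) name, unique within a model.
#' @param regime `"excitatory"` or `"inhibitory"`; determines the sign of
#'   all outgoing connection weights.  May be `NULL` on freshly imported
#'   fragments, but must be set before realization.
#' @param number Entry list: neuron count at real scale, single hemisphere.
#' @param receptors List of [receptor_spec()] ports, in declaration order.
#' @param dendrite_extent_um,dendrite_diameter_um Entry lists (micrometres):
#'   mean maximal dendritic-field extent and mean dendrite diameter.
#' @param firing_targets List of [firing_target()] objects.
#' @param template_ref Name of a neuron simulator template in the model.
#' @param param_overrides Named list mapping template parameter names to
#'   entry lists; unresolved (None) overrides leave template defaults.
#' @param objectives List of [objective_spec()] objects.
#' @param annotations Named list of pass-through annotations (e.g. from a
#'   connectome import).
#' @export
snn_population <- function(name, regime = NULL, number = list(),
                           receptors = list(),
                           dendrite_extent_um = list(),
                           dendrite_diameter_um = list(),
                           firing_targets = list(),
                           template_ref = NULL,
                           param_overrides = setNames(list(), character(0)),
                           objectives = list(),
                           annotations = setNames(list(), character(0))) {
  if (!is_scalar_string(name) || !nzchar(name))
    stop("a population requires a non-empty name", call. = FALSE)
  if (!is.null(regime) && !(is_scalar_string(regime) && regime %in% REGIMES))
    stop("regime must be 'excitatory' or 'inhibitory'", call. = FALSE)
  structure(list(name = name, regime = regime, number = number,
                 receptors = receptors,
                 dendrite_extent_um = dendrite_extent_um,
                 dendrite_diameter_um = dendrite_diameter_um,
                 firing_targets = firing_targets,
                 template_ref = template_ref,
                 param_overrides = param_overrides,
                 objectives = objectives,
                 annotations = annotations),
            class = "snn_population")
}

#' Create a projection
#'
#' Source-to-target wiring attributes.  Anatomical attributes (percentage
#' of projecting neurons, mean bouton count per axon, receptor location
#' along the dendrite, redundancy) are converted into simulator connection
#' rules and weights by the transfer functions at build time.
#'
#' @param source,target Population names.
#' @param rule Connection rule: `"fixed_indegree"`, `"fixed_outdegree"`,
#'   `"bernoulli_const_p"` or `"gaussian_distance"`.
#' @param rule_params Named list: `p` for the Bernoulli rule, `sigma` for
#'   the Gaussian-distance rule.
#' @param axon_organization Entry list over `"focused"` / `"diffused"`.
#' @param axon_domain_radius `list(value =, unit =)`: mean radius of the
#'   circle/sphere approximating the axonal arbor, in `"coord"` (simulation
#'   coordinate) units by default, or `"mm"`.
#' @param pct_projecting Entry list, percent of source neurons whose axons
#'   reach the target, in `[0, 100]`.
#' @param bouton_count Entry list, mean boutons per axon (often a
#'   `to_optimize` range).
#' @param receptor_location Entry list: category (`"proximal"`, `"medial"`,
#'   `"distal"`) or a proportion of dendritic extent in `[0, 1]`; leave
#'   empty (None) to disable attenuation.
#' @param redundancy Entry list, mean synaptic contacts one axon makes on
#'   one dendritic tree, `>= 1`.
#' @param delay_ms Entry list, axonal communication delay (ms).
#' @param weight_override Entry list, explicit synaptic weight in simulator
#'   units; when resolved it bypasses PSP-to-weight conversion.
#' @param synapse_template_ref Name of a synapse simulator template.
#' @param synapse_overrides Named list mapping synapse parameter names to
#'   entry lists.
#' @param annotations Pass-through annotations.
#' @export
snn_projection <- function(source, target, rule = "fixed_indegree",
                           rule_params = setNames(list(), character(0)),
                           axon_organization = list(),
                           axon_domain_radius = list(value = NULL,
                                                     unit = "coord"),
                           pct_projecting = list(), bouton_count = list(),
                           receptor_location = list(), redundancy = list(),
                           delay_ms = list(), weight_override = list(),
                           synapse_template_ref = NULL,
                           synapse_overrides = setNames(list(), character(0)),
                           annotations = setNames(list(), character(0))) {
  if (!is_scalar_string(source) || !is_scalar_string(target))
    stop("a projection requires source and target population names",
         call. = FALSE)
  if (!is_scalar_string(rule) || !(rule %in% CONN_RULES))
    stop("rule must be one of: ", paste(CONN_RULES, collapse = ", "),
         call. = FALSE)
  structure(list(source = source, target = target, rule = rule,
                 rule_params = rule_params,
                 axon_organization = axon_organization,
                 axon_domain_radius = axon_domain_radius,
                 pct_projecting = pct_projecting,
                 bouton_count = bouton_count,
                 receptor_location = receptor_location,
                 redundancy = redundancy, delay_ms = delay_ms,
                 weight_override = weight_override,
                 synapse_template_ref = synapse_template_ref,
                 synapse_overrides = synapse_overrides,
                 annotations = annotations),
            class = "snn_projection")
}

#' Create a simulator model template
#'
#' A named neuron or synapse model of the target simulator, holding its
#' parameter names, descriptions and default values.  Templates are
#' immutable at the model level: populations and projections override
#' parameter values through their own entry lists, never by mutating the
#' template.
#'
#' @param name Simulator model name (passed through verbatim to the
#'   generated code).
#' @param kind `"neuron"` or `"synapse"`.
#' @param parameters Named list mapping parameter name to
#'   `list(default =, description =)`.
#' @export
simulator_template <- function(name, kind,
                               parameters = setNames(list(), character(0))) {
  if (!is_scalar_string(kind) || !(kind %in% TEMPLATE_KINDS))
    stop("template kind must be 'neuron' or 'synapse'", call. = FALSE)
  if (anyDuplicated(names(parameters)))
    stop("template '", name, "' has duplicate parameter names", call. = FALSE)
  parameters <- lapply(parameters, function(p)
    list(default = if (is.numeric(p$default)) as.numeric(p$default)
                   else p$default,
         description = p$description %||% ""))
  # parameter order is not semantic; keep it canonical (sorted) so that
  # construction and file round-trips agree byte-for-byte downstream
  if (length(parameters) > 0L)
    parameters <- parameters[order(names(parameters), method = "radix")]
  structure(list(name = name, kind = kind, parameters = parameters),
            class = "snn_template")
}

#' Create a stimulus specification
#'
#' A Poisson spike-train generator wired to one target population, with a
#' firing rate, connection weight, delay and start/stop times.  The scope
#' is either `"global"` (all neurons of the target) or a spatially bounded
#' subset given by a centre point and radius.
#'
#' @param target Target population name.
#' @param rate_hz Poisson rate (Hz), `>= 0`.
#' @param weight Connection weight in simulator units.
#' @param delay_ms Delay (ms).
#' @param start_ms,stop_ms Stimulation window (ms), `start_ms <= stop_ms`;
#'   `stop_ms = NULL` means "until the end of the simulation".
#' @param scope `"global"` or `list(center = c(...), radius = r)`.
#' @export
stimulus_spec <- function(target, rate_hz, weight = 1, delay_ms = 1,
                          start_ms = 0, stop_ms = NULL, scope = "global") {
  structure(list(target = target, rate_hz = rate_hz, weight = weight,
                 delay_ms = delay_ms, start_ms = start_ms, stop_ms = stop_ms,
                 scope = scope),
            class = "snn_stimulus")
}

#' Create a recordable specification
#'
#' @param target Target population name.
#' @param kind `"spikes"` (spike times of all neurons of the target) or
#'   `"membrane_potential"` (one neuron selected at random).
#' @export
recordable_spec <- function(target, kind = "spikes") {
  if (!is_scalar_string(kind) || !(kind %in% RECORD_KINDS))
    stop("recordable kind must be 'spikes' or 'membrane_potential'",
         call. = FALSE)
  structure(list(target = target, kind = kind), class = "snn_recordable")
}

#' Create a simulation specification
#'
#' @param description Free-text description.
#' @param dt_ms Simulation time resolution (ms), `> 0`.
#' @param duration_ms Simulated biological time (ms), `> 0`.
#' @param threads Number of computational threads.
#' @param space_dim Spatial dimensionality of neuron placement, 2 or 3.
#' @param bounds List of per-axis `c(min, max)` coordinate bounds.
#' @param synaptic_gain Multiplicative synaptic scaling gain applied to the
#'   absolute value of every connection weight, `> 0`.
#' @param active Whether this simulation drives code generation; if none is
#'   marked active the first one is used.
#' @param stimuli List of [stimulus_spec()] objects.
#' @param recordables List of [recordable_spec()] objects.
#' @export
simulation_spec <- function(description = "", dt_ms = 0.1,
                            duration_ms = 1000, threads = 1,
                            space_dim = 2,
                            bounds = list(c(0, 1), c(0, 1)),
                            synaptic_gain = 1, active = TRUE,
                            stimuli = list(), recordables = list()) {
  structure(list(description = description, dt_ms = dt_ms,
                 duration_ms = duration_ms, threads = threads,
                 space_dim = space_dim, bounds = bounds,
                 synaptic_gain = synaptic_gain, active = active,
                 stimuli = stimuli, recordables = recordables),
            class = "snn_simulation")
}

#' Create a model specification
#'
#' The top-level editable model: header (identifier, species, name,
#' description, scale), populations, projections, simulator templates,
#' simulations, references and notes.
#'
#' @param name Model name.
#' @param species Species free text.
#' @param description Free-text description.
#' @param scale Scale relative to biological size, in `(0, 1]`; all neuron
#'   numbers are multiplied by it at code-generation time.
#' @param model_id Opaque identifier; defaults to the name.
#' @param populations,projections,templates,simulations,references,notes
#'   Entity lists (see the respective constructors).
#' @return A list of class `snn_model_spec`.
#' @export
snn_model <- function(name, species = "", description = "", scale = 1,
                      model_id = NULL, populations = list(),
                      projections = list(), templates = list(),
                      simulations = list(), references = list(),
                      notes = list()) {
  if (!is_scalar_string(name) || !nzchar(name))
    stop("a model requires a non-empty name", call. = FALSE)
  structure(
    list(model = list(model_id = model_id %||% name, species = species,
                      name = name, description = description,
                      scale = scale),
         populations = populations, projections = projections,
         templates = templates, simulations = simulations,
         references = references, notes = notes),
    class = "snn_model_spec"
  )
}

#' @export
print.snn_model_spec <- function(x, ...) {
  cat("<model spec> ", x$model$name, " (", x$model$species, ")\n", sep = "")
  cat("  scale: ", x$model$scale,
      " | populations: ", length(x$populations),
      " | projections: ", length(x$projections),
      " | templates: ", length(x$templates),
      " | simulations: ", length(x$simulations), "\n", sep = "")
  invisible(x)
}

find_population <- function(spec, name) {
  for (p in spec$populations) if (identical(p$name, name)) return(p)
  NULL
}

find_template <- function(spec, name) {
  for (t in spec$templates) if (identical(t$name, name)) return(t)
  NULL
}

active_simulation <- function(spec) {
  if (length(spec$simulations) == 0L) return(NULL)
  for (s in spec$simulations) if (isTRUE(s$active)) return(s)
  spec$simulations[[1]]
}
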