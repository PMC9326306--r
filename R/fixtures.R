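#' Example model builders
#'
#' Programmatic constructors for two fully specified example models -- a
#' balanced cortical network with excitatory and inhibitory populations,
#' and a striatal microcircuit -- plus a randomized generator for
#' property tests.  These are the package's data source: every model is
#' built in code from its printed parameters, with no external downloads.
#'
#' @name fixtures
NULL

lif_multisyn_template <- function(tau_m = 10, c_m = 250, t_ref = 2,
                                  e_l = -70, v_th = -55, v_reset = -70) {
  simulator_template("iaf_psc_alpha_multisynapse", "neuron", list(
    C_m = list(default = c_m, description = "Membrane capacitance (pF)"),
    tau_m = list(default = tau_m, description = "Membrane time constant (ms)"),
    t_ref = list(default = t_ref, description = "Refractory period (ms)"),
    E_L = list(default = e_l, description = "Resting potential (mV)"),
    V_th = list(default = v_th, description = "Spike threshold (mV)"),
    V_reset = list(default = v_reset, description = "Reset potential (mV)"),
    I_e = list(default = 0, description = "Constant input current (pA)")
  ))
}

static_synapse_template <- function(delay = 1) {
  simulator_template("static_synapse", "synapse", list(
    weight = list(default = 1, description = "Synaptic weight (pA)"),
    delay = list(default = delay, description = "Transmission delay (ms)")
  ))
}

#' Build the balanced cortical network example
#'
#' A two-population random network: 10,000 excitatory and 2,500
#' inhibitory leaky integrate-and-fire neurons with alpha-function
#' synapses of common rise time 0.5 ms.  PSP amplitudes are `J` mV on
#' AMPA receptors and `g * J` mV on GABA receptors; dendrites have a
#' generic 600 um extent and 1.6 um diameter, and synapses sit proximally
#' on the dendrite.  Every pairwise projection uses a fixed-indegree rule
#' with 100% projecting neurons, bouton count `epsilon * N_target`
#' (`epsilon = 0.1`) and redundancy 1, with diffuse wide-domain axons so
#' the wiring emulates an Erdos-Renyi random network of connection
#' probability epsilon.  The simulation runs 2,000 ms at 0.1 ms
#' resolution in the unit square, with Poisson drive to both populations
#' for the first 1,000 ms.
#'
#' @param J Excitatory PSP amplitude (mV), `> 0`.
#' @param g Relative inhibitory strength (inhibitory PSP is `g * J` mV),
#'   `> 0`.
#' @param epsilon Connection probability emulated by the bouton counts.
#' @param stimulus_rate_hz Rate of the Poisson drive per population (Hz).
#' @param stimulus_weight Weight of the Poisson drive (pA).
#' @return A valid `snn_model_spec`.
#' @examples
#' spec <- build_cortical_example(J = 1.4, g = 4)
#' validate_model(spec)
#' @export
build_cortical_example <- function(J = 1.4, g = 4, epsilon = 0.1,
                                   stimulus_rate_hz = 12000,
                                   stimulus_weight = 20) {
  if (J <= 0 || g <= 0) stop("J and g must be > 0", call. = FALSE)
  n_exc <- 10000
  n_inh <- 2500
  rise <- 0.5
  ref <- snn_reference("https://doi.org/10.1023/A:1008925309027",
                       "balanced random network reference parameters")
  make_pop <- function(name, regime, n) {
    snn_population(
      name = name, regime = regime,
      number = entries(n, reference = ref),
      receptors = list(
        receptor_spec("AMPA", psp_amplitude_mv = entries(J),
                      rise_time_ms = entries(rise)),
        receptor_spec("GABA", psp_amplitude_mv = entries(g * J),
                      rise_time_ms = entries(rise))
      ),
      dendrite_extent_um = entries(600),
      dendrite_diameter_um = entries(1.6),
      template_ref = "iaf_psc_alpha_multisynapse"
    )
  }
  make_proj <- function(src, tgt, n_tgt) {
    snn_projection(
      source = src, target = tgt, rule = "fixed_indegree",
      axon_organization = entries("diffused"),
      axon_domain_radius = list(value = 10, unit = "coord"),
      pct_projecting = entries(100),
      bouton_count = entries(epsilon * n_tgt),
      receptor_location = entries("proximal"),
      redundancy = entries(1),
      delay_ms = entries(1.5),
      synapse_template_ref = "static_synapse"
    )
  }
  sim <- simulation_spec(
    description = "self-sustained activity run",
    dt_ms = 0.1, duration_ms = 2000, threads = 1,
    space_dim = 2, bounds = list(c(0, 1), c(0, 1)),
    synaptic_gain = 1, active = TRUE,
    stimuli = list(
      stimulus_spec("exc", rate_hz = stimulus_rate_hz,
                    weight = stimulus_weight, delay_ms = 1.5,
                    start_ms = 0, stop_ms = 1000),
      stimulus_spec("inh", rate_hz = stimulus_rate_hz,
                    weight = stimulus_weight, delay_ms = 1.5,
                    start_ms = 0, stop_ms = 1000)
    ),
    recordables = list(recordable_spec("exc", "spikes"),
                       recordable_spec("inh", "spikes"))
  )
  snn_model(
    name = "cortical-balanced-network",
    species = "rodent",
    description = paste0("Excitatory/inhibitory random network with ",
                         "self-sustained asynchronous-irregular activity"),
    scale = 1,
    populations = list(make_pop("exc", "excitatory", n_exc),
                       make_pop("inh", "inhibitory", n_inh)),
    projections = list(make_proj("exc", "exc", n_exc),
                       make_proj("exc", "inh", n_inh),
                       make_proj("inh", "exc", n_exc),
                       make_proj("inh", "inh", n_inh)),
    templates = list(lif_multisyn_template(),
                     static_synapse_template(delay = 1.5)),
    simulations = list(sim),
    references = list(ref),
    notes = list(snn_note(paste0("generic dendrite extent and diameter ",
                                 "assumed for both populations"),
                          owner = "builder"))
  )
}

#' Build the striatal microcircuit example
#'
#' Five striatal populations -- 38,237 direct-pathway and 38,237
#' indirect-pathway projection neurons (dSPN, iSPN), 1,047 fast-spiking
#' (FS) and 644 low-threshold-spiking (LTS) interneurons, and 886
#' cholinergic interneurons (ChIN) -- placed uniformly in a unit cube
#' standing for 1 mm^3 of striatum.  All neurons are leaky
#' integrate-and-fire with AMPA and GABA alpha-synapse ports; connection
#' PSPs are supplied as weight overrides at the projection level, wiring
#' uses fixed-indegree rules with spherical masks, and all axonal delays
#' are a generic 0.2 ms.
#'
#' External drive models 150 AMPA synapses per neuron: a 2 Hz per-synapse
#' baseline gives one 300 Hz Poisson generator per population for the
#' whole 1,500 ms, and an 8 Hz cortical-activation phase superimposes a
#' 1,200 Hz generator from 1,000 to 1,500 ms while the baseline
#' continues.
#'
#' Connection-level details not fixed by the population counts and input
#' rates (bouton numbers, mask radii, per-connection PSP weights, neuron
#' electrical constants) are documented placeholder values chosen at
#' plausible orders of magnitude.
#'
#' @return A valid `snn_model_spec`.
#' @export
build_striatal_example <- function() {
  counts <- c(dSPN = 38237, iSPN = 38237, FS = 1047, LTS = 644, ChIN = 886)
  regimes <- c(dSPN = "inhibitory", iSPN = "inhibitory", FS = "inhibitory",
               LTS = "inhibitory", ChIN = "excitatory")
  delay <- 0.2
  baseline_hz <- aggregate_poisson_rate(150, 2)   # 300 Hz
  elevated_hz <- aggregate_poisson_rate(150, 8)   # 1200 Hz

  make_pop <- function(name) {
    snn_population(
      name = name, regime = regimes[[name]],
      number = entries(counts[[name]]),
      receptors = list(
        receptor_spec("AMPA", rise_time_ms = entries(2)),
        receptor_spec("GABA", rise_time_ms = entries(5))
      ),
      dendrite_extent_um = entries(250),
      dendrite_diameter_um = entries(1.0),
      firing_targets = list(firing_target("resting", 0.1, 2),
                            firing_target("excitation", 2, 20)),
      template_ref = "iaf_psc_alpha_multisynapse"
    )
  }

  # placeholder synaptic weights (pA magnitudes) and bouton counts; the
  # mask radius approximates axonal plus dendritic field size in
  # coordinate (1 mm) units
  make_proj <- function(src, tgt, weight_pa, boutons, mask = 0.3) {
    snn_projection(
      source = src, target = tgt, rule = "fixed_indegree",
      axon_organization = entries("focused"),
      axon_domain_radius = list(value = mask, unit = "coord"),
      pct_projecting = entries(100),
      bouton_count = entries(boutons),
      redundancy = entries(1),
      delay_ms = entries(delay),
      weight_override = entries(weight_pa),
      synapse_template_ref = "static_synapse"
    )
  }
  projections <- list(
    make_proj("dSPN", "dSPN", 25, 150),
    make_proj("dSPN", "iSPN", 25, 150),
    make_proj("iSPN", "dSPN", 30, 150),
    make_proj("iSPN", "iSPN", 30, 150),
    make_proj("FS", "dSPN", 120, 500, mask = 0.35),
    make_proj("FS", "iSPN", 120, 500, mask = 0.35),
    make_proj("LTS", "dSPN", 40, 300, mask = 0.6),
    make_proj("LTS", "iSPN", 40, 300, mask = 0.6),
    make_proj("ChIN", "LTS", 30, 200, mask = 0.5)
  )

  stim <- function(pop) list(
    stimulus_spec(pop, rate_hz = baseline_hz, weight = 5, delay_ms = delay,
                  start_ms = 0, stop_ms = 1500),
    stimulus_spec(pop, rate_hz = elevated_hz, weight = 5, delay_ms = delay,
                  start_ms = 1000, stop_ms = 1500)
  )
  sim <- simulation_spec(
    description = "baseline and cortical-activation regimes",
    dt_ms = 0.1, duration_ms = 1500, threads = 1,
    space_dim = 3, bounds = list(c(0, 1), c(0, 1), c(0, 1)),
    synaptic_gain = 1, active = TRUE,
    stimuli = do.call(c, lapply(names(counts), stim)),
    recordables = c(lapply(names(counts), recordable_spec, kind = "spikes"),
                    list(recordable_spec("dSPN", "membrane_potential")))
  )
  snn_model(
    name = "striatal-microcircuit",
    species = "mouse",
    description = "Point-neuron model of local striatal microcircuitry",
    scale = 1,
    populations = lapply(names(counts), make_pop),
    projections = projections,
    templates = list(lif_multisyn_template(tau_m = 12, c_m = 200,
                                           e_l = -80, v_th = -45),
                     static_synapse_template(delay = delay)),
    simulations = list(sim),
    references = list(
      snn_reference("https://doi.org/10.1073/pnas.2000671117",
                    "striatal microcircuit reference model"))
  )
}

#' Generate a random valid model for property tests
#'
#' Produces a randomized but invariant-respecting model: `n_pops`
#' populations with randomized sizes, regimes, receptors and dendrites
#' (some attributes intentionally carry multiple entries, including
#' deactivated and to-optimize ones, to exercise collective resolution),
#' and projections drawn for each ordered pair with probability
#' `connectivity_density` and a randomly chosen connection rule.
#' Reproducible per seed.
#'
#' @param seed Integer seed.
#' @param n_pops Number of populations, `>= 1`.
#' @param connectivity_density Probability of each ordered pair being
#'   connected, in `[0, 1]`.
#' @return A valid `snn_model_spec`.
#' @export
random_model <- function(seed, n_pops = 3, connectivity_density = 0.5) {
  stopifnot(n_pops >= 1, connectivity_density >= 0,
            connectivity_density <= 1)
  with_seed(subseed(seed, 3L), {
    pop_names <- paste0("pop", seq_len(n_pops))
    regs <- sample(REGIMES, n_pops, replace = TRUE)
    pops <- lapply(seq_len(n_pops), function(i) {
      n_entries <- sample(1:3, 1)
      number <- lapply(seq_len(n_entries), function(k)
        param_entry(round(stats::runif(1, 50, 1000)),
                    flag = if (k > 1 && stats::runif(1) < 0.3)
                      "deactivated" else "fixed"))
      snn_population(
        name = pop_names[i], regime = regs[i], number = number,
        receptors = list(
          receptor_spec("AMPA",
                        psp_amplitude_mv = entries(stats::runif(1, 0.2, 2)),
                        rise_time_ms = entries(stats::runif(1, 0.3, 2))),
          receptor_spec("GABA",
                        psp_amplitude_mv = entries(stats::runif(1, 0.5, 5)),
                        rise_time_ms = entries(stats::runif(1, 0.5, 4)))
        ),
        dendrite_extent_um = entries(round(stats::runif(1, 300, 800))),
        dendrite_diameter_um = entries(round(stats::runif(1, 1, 2), 2)),
        template_ref = "iaf_psc_alpha_multisynapse"
      )
    })
    projs <- list()
    for (s in pop_names) for (t in pop_names) {
      if (stats::runif(1) >= connectivity_density) next
      rule <- sample(CONN_RULES, 1)
      rp <- switch(rule,
                   bernoulli_const_p = list(p = round(stats::runif(1), 3)),
                   gaussian_distance = list(sigma =
                                              round(stats::runif(1, 0.05, 0.5), 3)),
                   setNames(list(), character(0)))
      boutons <- if (stats::runif(1) < 0.5)
        entries(round(stats::runif(1, 20, 200)))
      else
        entries(sort(round(stats::runif(2, 20, 400))), flag = "to_optimize")
      rloc <- if (stats::runif(1) < 0.3) list()
      else if (stats::runif(1) < 0.5)
        entries(sample(RECEPTOR_CATEGORIES, 1))
      else entries(round(stats::runif(1), 2))
      projs[[length(projs) + 1L]] <- snn_projection(
        source = s, target = t, rule = rule, rule_params = rp,
        axon_organization = entries(sample(AXON_ORGS, 1)),
        axon_domain_radius = list(value = round(stats::runif(1, 0.2, 2), 2),
                                  unit = "coord"),
        pct_projecting = entries(round(stats::runif(1, 50, 100))),
        bouton_count = boutons,
        receptor_location = rloc,
        redundancy = entries(sample(1:3, 1)),
        delay_ms = entries(round(stats::runif(1, 0.5, 2), 2)),
        synapse_template_ref = "static_synapse"
      )
    }
    sim <- simulation_spec(
      description = "random property-test simulation",
      dt_ms = 0.1, duration_ms = 500, threads = 1,
      space_dim = 2, bounds = list(c(0, 1), c(0, 1)),
      stimuli = list(stimulus_spec(pop_names[1], rate_hz = 1000,
                                   weight = 10, delay_ms = 1,
                                   start_ms = 0, stop_ms = 500)),
      recordables = list(recordable_spec(pop_names[1], "spikes"))
    )
    snn_model(
      name = paste0("random-model-", seed),
      species = "synthetic",
      description = "randomized invariant-respecting test model",
      populations = pops, projections = projs,
      templates = list(lif_multisyn_template(), static_synapse_template()),
      simulations = list(sim)
    )
  })
}
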