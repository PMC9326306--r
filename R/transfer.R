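#' Biological-to-simulator transfer functions
#'
#' Deterministic mappings from anatomical and physiological attributes to
#' simulator parameters: PSP-amplitude-to-weight conversion for
#' current-based leaky integrate-and-fire neurons with alpha synapses,
#' passive dendritic cable attenuation, indegree/outdegree derivation from
#' bouton counts, neuron-count scaling, and Poisson input aggregation.
#'
#' @name transfer
NULL

#' Passive cable constants
#'
#' Membrane resistivity and axial resistivity of the passive dendritic
#' cable used for attenuation.  Defaults (Rm = 20000 Ohm cm^2,
#' Ra = 150 Ohm cm) are generic cortical-pyramidal values; both can be set
#' from a key=value constants file (see [read_cable_constants()]).
#'
#' @param membrane_resistivity Rm in Ohm cm^2, `> 0`.
#' @param axial_resistivity Ra in Ohm cm, `> 0`.
#' @export
cable_constants <- function(membrane_resistivity = 20000,
                            axial_resistivity = 150) {
  if (membrane_resistivity <= 0 || axial_resistivity <= 0)
    stop("cable constants must be positive", call. = FALSE)
  structure(list(membrane_resistivity = membrane_resistivity,
                 axial_resistivity = axial_resistivity),
            class = "snn_cable")
}

#' Read cable constants and tolerances from a key=value file
#'
#' Recognised keys: `membrane_resistivity`, `axial_resistivity`.  Lines
#' starting with `#` are comments.  The packaged default file is at
#' `system.file("extdata", "cable_constants.conf", package = "snnweaver")`.
#'
#' @param path Path to the constants file.
#' @return A [cable_constants()] object.
#' @export
read_cable_constants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed constants line: ",
                              paste(p, collapse = "="), call. = FALSE)
    vals[[trimws(p[1])]] <- as.numeric(trimws(p[2]))
  }
  cable_constants(
    membrane_resistivity = vals$membrane_resistivity %||% 20000,
    axial_resistivity = vals$axial_resistivity %||% 150
  )
}

#' Neuron electrical parameters
#'
#' The membrane time constant and capacitance of the target neuron, read
#' from its simulator template, that govern the PSP-to-weight conversion.
#'
#' @param tau_m_ms Membrane time constant (ms), `> 0`.
#' @param c_m_pf Membrane capacitance (pF), `> 0`.
#' @export
neuron_electrical <- function(tau_m_ms, c_m_pf) {
  if (!is_scalar_number(tau_m_ms) || tau_m_ms <= 0 ||
      !is_scalar_number(c_m_pf) || c_m_pf <= 0)
    stop("tau_m and C_m must be positive numbers", call. = FALSE)
  structure(list(tau_m_ms = tau_m_ms, c_m_pf = c_m_pf),
            class = "snn_electrical")
}

# Peak membrane deflection (mV) of a LIF neuron at rest driven by an
# alpha-shaped PSC of unit peak amplitude (1 pA) and time constant tau_s:
#   i(t) = e * t / tau_s * exp(-t / tau_s)
#   C dV/dt = -C/tau_m V + i(t)
# The peak time solves a transcendental equation through the secondary
# branch of the Lambert W function; tau_m == tau_s uses the limit form
# V_peak = 2 tau / (e C).
alpha_psp_peak <- function(tau_m_ms, c_m_pf, tau_s_ms) {
  if (tau_m_ms <= 0 || tau_s_ms <= 0)
    stop("time constants must be positive", call. = FALSE)
  if (abs(tau_m_ms - tau_s_ms) < 1e-9 * tau_m_ms)
    return(2 * tau_s_ms * exp(-1) / c_m_pf)
  a <- tau_m_ms / tau_s_ms
  b <- 1 / tau_s_ms - 1 / tau_m_ms
  t_max <- (1 / b) * (-pracma::lambertWn(-exp(-1 / a) / a) - 1 / a)
  (exp(1) / (tau_s_ms * c_m_pf * b)) *
    ((exp(-t_max / tau_m_ms) - exp(-t_max / tau_s_ms)) / b -
       t_max * exp(-t_max / tau_s_ms))
}

#' Convert a PSP amplitude to a synaptic weight
#'
#' Returns the peak amplitude `w` (pA) of an alpha-shaped post-synaptic
#' current with time constant `rise_ms` such that, injected into a leaky
#' integrate-and-fire membrane (`tau_m`, `C_m`) at rest, the membrane
#' deflection peaks at exactly `psp_mv`.  The conversion is linear in
#' `psp_mv` and preserves its sign.  It applies to current-based synapse
#' models only; conductance-based templates require an explicit weight
#' override instead.
#'
#' @param psp_mv Desired peak PSP amplitude (mV); may be negative.
#' @param rise_ms Alpha-function synaptic time constant (ms), i.e. the
#'   time-to-peak of the PSC, `> 0`.
#' @param electrical A [neuron_electrical()] object.
#' @return Weight in pA.
#' @examples
#' el <- neuron_electrical(tau_m_ms = 10, c_m_pf = 250)
#' psp_to_weight(1, 0.5, el)
#' @export
psp_to_weight <- function(psp_mv, rise_ms, electrical) {
  stopifnot(inherits(electrical, "snn_electrical"))
  if (!is_scalar_number(rise_ms) || rise_ms <= 0)
    stop("rise_ms must be > 0", call. = FALSE)
  if (psp_mv == 0) return(0)
  psp_mv / alpha_psp_peak(electrical$tau_m_ms, electrical$c_m_pf, rise_ms)
}

#' Electrotonic length constant of a passive dendrite
#'
#' `lambda = sqrt(d * Rm / (4 * Ra))` with the diameter in micrometres and
#' the result in micrometres.
#'
#' @param diameter_um Mean dendrite diameter (micrometres), `> 0`.
#' @param cable A [cable_constants()] object.
#' @return Lambda in micrometres.
#' @export
electrotonic_length_um <- function(diameter_um, cable = cable_constants()) {
  if (!is_scalar_number(diameter_um) || diameter_um <= 0)
    stop("diameter must be > 0", call. = FALSE)
  # d [um] -> cm, lambda [cm] -> um
  d_cm <- diameter_um * 1e-4
  lam_cm <- sqrt(d_cm * cable$membrane_resistivity /
                   (4 * cable$axial_resistivity))
  lam_cm * 1e4
}

#' Dendritic attenuation of a connection weight
#'
#' Multiplicative attenuation factor for a synapse placed at proportion
#' `r` of the dendritic extent from the soma, under a passive exponential
#' cable: `exp(-(r * extent) / lambda)` with the electrotonic length
#' `lambda = sqrt(d * Rm / (4 * Ra))`.  `r = NULL` (None) removes
#' attenuation entirely; the factor is 1 at `r = 0` and strictly
#' decreasing in `r`.  The cable model is swappable through `factor_fn`
#' for users who prefer e.g. a full two-port attenuation.
#'
#' @param r Proportion of dendritic extent in `[0, 1]`, or `NULL` for no
#'   attenuation.
#' @param extent_um Mean maximal dendritic extent (micrometres), `> 0`.
#' @param diameter_um Mean dendrite diameter (micrometres), `> 0`.
#' @param cable A [cable_constants()] object.
#' @param factor_fn Optional replacement strategy: a function of
#'   `(path_length_um, lambda_um)` returning a factor in `(0, 1]`.
#' @return Attenuation factor in `(0, 1]`.
#' @examples
#' dendritic_attenuation(0.1, 600, 1.6)
#' dendritic_attenuation(NULL, 600, 1.6)  # 1: attenuation disabled
#' @export
dendritic_attenuation <- function(r, extent_um, diameter_um,
                                  cable = cable_constants(),
                                  factor_fn = NULL) {
  if (is.null(r)) return(1.0)
  if (!is_scalar_number(r) || r < 0 || r > 1)
    stop("receptor location r must be in [0, 1] or NULL", call. = FALSE)
  if (!is_scalar_number(extent_um) || extent_um <= 0)
    stop("dendritic extent must be > 0", call. = FALSE)
  lam <- electrotonic_length_um(diameter_um, cable)
  x <- r * extent_um
  if (!is.null(factor_fn)) return(factor_fn(x, lam))
  exp(-x / lam)
}

#' Midpoint proportion of a categorical receptor location
#'
#' Maps the categorical synapse-to-soma distances to the midpoint of the
#' corresponding proportion interval: proximal \[0, 0.2) to 0.1, medial
#' \[0.2, 0.6) to 0.4, distal \[0.6, 1\] to 0.8.
#'
#' @param category `"proximal"`, `"medial"` or `"distal"`.
#' @return Proportion r of dendritic extent.
#' @export
categorical_receptor_location <- function(category) {
  switch(category,
         proximal = 0.1,
         medial = 0.4,
         distal = 0.8,
         stop("unknown receptor-location category '", category, "'",
              call. = FALSE))
}

#' Indegree from projection anatomy
#'
#' Number of afferent connections per target neuron implied by the
#' anatomical attributes: `pct/100 * n_source` projecting axons each carry
#' `boutons` synaptic sites, spread over `n_target` dendritic trees, with
#' `redundancy` contacts per axon-dendrite pair counted as one connection:
#' `K = round(pct/100 * n_source * boutons / (n_target * redundancy))`
#' (round half to even, clamped at 0).
#'
#' @param pct Percentage of projecting source neurons, in `[0, 100]`.
#' @param n_source,n_target Population sizes (counts, `>= 1`).
#' @param boutons Mean boutons per axon.
#' @param redundancy Mean contacts per axon on one dendritic tree, `>= 1`.
#' @return Integer indegree K.
#' @export
compute_indegree <- function(pct, n_source, boutons, n_target, redundancy) {
  check_degree_args(pct, boutons, redundancy)
  if (!is_scalar_number(n_target) || n_target < 1)
    stop("n_target must be a count >= 1", call. = FALSE)
  if (!is_scalar_number(n_source) || n_source < 1)
    stop("n_source must be a count >= 1", call. = FALSE)
  k <- round((pct / 100) * n_source * boutons / (n_target * redundancy))
  max(0L, as.integer(k))
}

#' Outdegree from projection anatomy
#'
#' Number of distinct targets per source neuron:
#' `K = round(pct/100 * boutons / redundancy)`.
#'
#' @inheritParams compute_indegree
#' @return Integer outdegree K.
#' @export
compute_outdegree <- function(pct, boutons, redundancy) {
  check_degree_args(pct, boutons, redundancy)
  max(0L, as.integer(round((pct / 100) * boutons / redundancy)))
}

check_degree_args <- function(pct, boutons, redundancy) {
  if (!is_scalar_number(pct) || pct < 0 || pct > 100)
    stop("pct must be in [0, 100]", call. = FALSE)
  if (!is_scalar_number(boutons) || boutons < 0)
    stop("bouton count must be >= 0", call. = FALSE)
  if (!is_scalar_number(redundancy) || redundancy < 1)
    stop("redundancy must be >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Scale a neuron count
#'
#' `round(n * scale)`, clamped to at least one neuron, so that reduced
#' builds remain runnable.
#'
#' @param n Count at real scale, `>= 1`.
#' @param scale Scale factor in `(0, 1]`.
#' @return Integer scaled count, `>= 1`.
#' @export
scale_count <- function(n, scale) {
  if (!is_scalar_number(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is_scalar_number(scale) || scale <= 0 || scale > 1)
    stop("scale must be in (0, 1]", call. = FALSE)
  max(1L, as.integer(round(n * scale)))
}

#' Effective connection weight
#'
#' Combines a base weight with dendritic attenuation, redundancy and the
#' global synaptic scaling gain, and applies the sign convention:
#' `|w| = |base| * attenuation * redundancy * gain`, negative exactly when
#' the source population is inhibitory.
#'
#' @param base Base weight (simulator units); its sign is ignored.
#' @param regime `"excitatory"` or `"inhibitory"` regime of the source.
#' @param attenuation Factor in `(0, 1]`.
#' @param redundancy Mean contacts per axon-dendrite pair, `>= 1`.
#' @param gain Synaptic scaling gain, `> 0`.
#' @return Signed effective weight.
#' @export
effective_weight <- function(base, regime, attenuation = 1, redundancy = 1,
                             gain = 1) {
  if (!(regime %in% REGIMES))
    stop("regime must be 'excitatory' or 'inhibitory'", call. = FALSE)
  if (attenuation <= 0 || attenuation > 1)
    stop("attenuation must be in (0, 1]", call. = FALSE)
  if (redundancy < 1) stop("redundancy must be >= 1", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  mag <- abs(base) * attenuation * redundancy * gain
  if (identical(regime, "inhibitory")) -mag else mag
}

#' Aggregate independent Poisson inputs into one generator rate
#'
#' By superposition of independent Poisson processes, `n` synapses each
#' receiving an independent `per_synapse_hz` spike train are equivalent to
#' a single generator of rate `n * per_synapse_hz`.
#'
#' @param n_synapses Number of synapses, `>= 0`.
#' @param per_synapse_hz Rate per synapse (Hz), `>= 0`.
#' @return Aggregate rate (Hz).
#' @examples
#' aggregate_poisson_rate(150, 2)  # 300
#' @export
aggregate_poisson_rate <- function(n_synapses, per_synapse_hz) {
  if (n_synapses < 0 || per_synapse_hz < 0)
    stop("counts and rates must be non-negative", call. = FALSE)
  n_synapses * per_synapse_hz
}
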