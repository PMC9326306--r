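#' Realizing a model at a given scale and seed
#'
#' Realization applies collective aggregation and the transfer functions to
#' a model description, producing fully resolved populations (scaled
#' counts, positions, simulator parameters), connection-rule parameter
#' sets with signed weights and delays, stimuli with precomputed scoped
#' target sets, and recordables.  It is a pure function of
#' `(spec, scale, seed)`.
#'
#' @name realization
NULL

# purpose offsets for sub-seed derivation
SEED_PLACEMENT  <- 1L
SEED_RECORDABLE <- 2L

#' Place neurons uniformly within spatial bounds
#'
#' Independent uniform draws per axis, reproducible for equal seeds.
#'
#' @param n Number of neurons, `>= 0`.
#' @param bounds List of per-axis `c(min, max)` pairs.
#' @param dim 2 or 3; must match `length(bounds)`.
#' @param seed Integer seed.
#' @return An `n x dim` numeric matrix of coordinates.
#' @export
place_neurons <- function(n, bounds, dim = length(bounds), seed = 1L) {
  if (!(dim %in% c(2, 3))) stop("dim must be 2 or 3", call. = FALSE)
  if (length(bounds) != dim)
    stop("bounds must give one [min, max] pair per axis", call. = FALSE)
  if (n == 0L) return(matrix(numeric(0), nrow = 0, ncol = dim))
  with_seed(seed, {
    cols <- lapply(seq_len(dim), function(a)
      stats::runif(n, bounds[[a]][1], bounds[[a]][2]))
    do.call(cbind, cols)
  })
}

#' Select neurons within a stimulus scope
#'
#' Indices of positions whose Euclidean distance from `center` is at most
#' `radius` -- the neurons inside the circular (2D) or spherical (3D)
#' stimulation scope.
#'
#' @param positions An `n x dim` coordinate matrix.
#' @param center Numeric centre of length `dim`.
#' @param radius Scope radius, `> 0`.
#' @return Integer vector of (1-based) neuron indices.
#' @export
select_stimulus_targets <- function(positions, center, radius) {
  if (!is_scalar_number(radius) || radius <= 0)
    stop("radius must be > 0", call. = FALSE)
  if (length(center) != ncol(positions))
    stop("centre dimension (", length(center),
         ") does not match positions (", ncol(positions), ")", call. = FALSE)
  if (nrow(positions) == 0L) return(integer(0))
  d2 <- rowSums((positions - matrix(center, nrow(positions),
                                    length(center), byrow = TRUE))^2)
  which(d2 <= radius^2)
}

resolve_or_null <- function(entries) resolve_attribute(entries)$value

# template defaults overlaid with resolved overrides; unresolved (None)
# overrides leave the simulator defaults in place.
overlay_params <- function(template, overrides) {
  params <- lapply(template$parameters, `[[`, "default")
  for (nm in names(overrides)) {
    v <- resolve_or_null(overrides[[nm]])
    if (!is.null(v)) params[[nm]] <- v
  }
  params
}

#' Realize one neural population
#'
#' Resolves the neuron number, applies the scale, places the neurons, and
#' overlays resolved parameter overrides on the neuron template defaults.
#' Receptor ports are ordered by declaration; their 1-based index is the
#' simulator receptor port used by incoming connections.
#'
#' @param pop A `snn_population`.
#' @param spec The enclosing `snn_model_spec` (for template lookup).
#' @param scale Scale in `(0, 1]`.
#' @param seed Integer seed for placement.
#' @param sim The governing `snn_simulation` (bounds and dimension).
#' @param index Population index (used to derive the placement sub-seed).
#' @return A list of class `snn_realized_population`.
#' @export
realize_population <- function(pop, spec, scale, seed, sim, index = 1L) {
  if (is.null(pop$regime))
    stop("population '", pop$name, "' has no excitatory/inhibitory regime; ",
         "set it before building", call. = FALSE)
  n_res <- resolve_or_null(pop$number)
  if (is.null(n_res))
    stop("population '", pop$name, "' has no active number entry; ",
         "cannot size it", call. = FALSE)
  tmpl <- find_template(spec, pop$template_ref %||% "")
  if (is.null(tmpl) || tmpl$kind != "neuron")
    stop("population '", pop$name, "' references no neuron template",
         call. = FALSE)
  n_scaled <- scale_count(n_res, scale)
  positions <- place_neurons(n_scaled, sim$bounds, sim$space_dim,
                             subseed(seed, SEED_PLACEMENT, index))
  ports <- lapply(pop$receptors, function(r)
    list(transmitter = r$transmitter,
         rise_ms = resolve_or_null(r$rise_time_ms)))
  structure(
    list(name = pop$name, regime = pop$regime, n_scaled = n_scaled,
         positions = positions, template = tmpl$name,
         resolved_params = overlay_params(tmpl, pop$param_overrides),
         receptor_ports = ports),
    class = "snn_realized_population"
  )
}

match_receptor_port <- function(tgt_real, source_regime) {
  wanted <- if (identical(source_regime, "inhibitory")) "GABA"
            else c("AMPA", "NMDA")
  for (i in seq_along(tgt_real$receptor_ports)) {
    if (tgt_real$receptor_ports[[i]]$transmitter %in% wanted) return(i)
  }
  NA_integer_
}

is_conductance_template <- function(name) grepl("cond", name %||% "")

arena_diameter <- function(bounds) {
  sqrt(sum(vapply(bounds, function(b) (b[2] - b[1])^2, numeric(1))))
}

#' Realize one projection
#'
#' Resolves the connection rule (indegrees/outdegrees from the scaled
#' population counts via the transfer functions; Bernoulli and Gaussian
#' rules from their stated parameters), the signed effective weight
#' (weight override if resolved, otherwise PSP-to-weight conversion
#' through the matching target receptor, attenuated by the target's
#' dendritic cable), the delay, and the spatial mask.
#'
#' A focused axon organization applies a mask of the axon-domain radius; a
#' diffused organization keeps a finite-domain mask but drops it once the
#' domain covers the whole arena.
#'
#' @param proj A `snn_projection`.
#' @param src_real,tgt_real Realized endpoint populations.
#' @param spec The enclosing model spec.
#' @param gain Synaptic scaling gain.
#' @param cable A [cable_constants()] object.
#' @param sim The governing simulation (arena bounds).
#' @param src_pop,tgt_pop The raw population specs (dendrite attributes).
#' @return A list of class `snn_realized_projection`.
#' @export
realize_projection <- function(proj, src_real, tgt_real, spec, gain, cable,
                               sim, src_pop, tgt_pop) {
  tag <- paste0("projection ", proj$source, " -> ", proj$target)
  regime <- src_real$regime

  ## connection rule
  pct <- resolve_or_null(proj$pct_projecting) %||% 100
  rho <- resolve_or_null(proj$redundancy) %||% 1
  rule_value <- switch(
    proj$rule,
    fixed_indegree = {
      boutons <- resolve_or_null(proj$bouton_count)
      if (is.null(boutons))
        stop(tag, ": fixed_indegree requires a resolved bouton count",
             call. = FALSE)
      compute_indegree(pct, src_real$n_scaled, boutons, tgt_real$n_scaled,
                       rho)
    },
    fixed_outdegree = {
      boutons <- resolve_or_null(proj$bouton_count)
      if (is.null(boutons))
        stop(tag, ": fixed_outdegree requires a resolved bouton count",
             call. = FALSE)
      compute_outdegree(pct, boutons, rho)
    },
    bernoulli_const_p = proj$rule_params$p,
    gaussian_distance = proj$rule_params$sigma,
    stop(tag, ": unsupported rule '", proj$rule, "'", call. = FALSE)
  )

  ## weight
  port <- match_receptor_port(tgt_real, regime)
  w_over <- resolve_or_null(proj$weight_override)
  syn_tmpl <- if (!is.null(proj$synapse_template_ref))
    find_template(spec, proj$synapse_template_ref) else NULL
  if (is.null(w_over)) {
    if (is_conductance_template(tgt_real$template))
      stop(tag, ": target uses a conductance-based model; PSP conversion ",
           "is current-based only -- provide a weight_override",
           call. = FALSE)
    if (is.na(port))
      stop(tag, ": no ", if (identical(regime, "inhibitory")) "GABA"
           else "AMPA/NMDA",
           " receptor on target '", proj$target,
           "' and no weight_override", call. = FALSE)
    rec <- tgt_pop$receptors[[port]]
    psp <- resolve_or_null(rec$psp_amplitude_mv)
    rise <- resolve_or_null(rec$rise_time_ms)
    if (is.null(psp) || is.null(rise))
      stop(tag, ": target receptor lacks a resolved PSP amplitude or ",
           "rise time", call. = FALSE)
    tau_m <- tgt_real$resolved_params$tau_m
    c_m <- tgt_real$resolved_params$C_m
    if (is.null(tau_m) || is.null(c_m))
      stop(tag, ": target template provides no tau_m / C_m for PSP ",
           "conversion", call. = FALSE)
    base <- psp_to_weight(psp, rise, neuron_electrical(tau_m, c_m))
  } else {
    base <- w_over
  }

  ## attenuation from the synapse position on the target dendrite
  r_res <- resolve_or_null(proj$receptor_location)
  if (is.character(r_res)) r_res <- categorical_receptor_location(r_res)
  atten <- if (is.null(r_res)) 1.0 else {
    extent <- resolve_or_null(tgt_pop$dendrite_extent_um)
    diam <- resolve_or_null(tgt_pop$dendrite_diameter_um)
    if (is.null(extent) || is.null(diam))
      stop(tag, ": receptor location set but target '", proj$target,
           "' has unresolved dendrite extent/diameter", call. = FALSE)
    dendritic_attenuation(r_res, extent, diam, cable)
  }
  weight <- effective_weight(base, regime, atten, rho, gain)

  ## delay: resolved entries, else the synapse template default, else 1 ms
  delay <- resolve_or_null(proj$delay_ms)
  if (is.null(delay) && !is.null(syn_tmpl))
    delay <- syn_tmpl$parameters$delay$default
  if (is.null(delay)) {
    warning(tag, ": no delay specified and no template default; using 1 ms",
            call. = FALSE)
    delay <- 1.0
  }

  ## spatial mask
  org <- resolve_or_null(proj$axon_organization) %||% "diffused"
  radius <- proj$axon_domain_radius$value
  mask_radius <- if (identical(org, "focused")) {
    if (is.null(radius))
      stop(tag, ": focused axon organization requires an axon domain ",
           "radius", call. = FALSE)
    radius
  } else {
    if (is.null(radius) || radius >= arena_diameter(sim$bounds)) NULL
    else radius
  }

  structure(
    list(source = proj$source, target = proj$target, rule_kind = proj$rule,
         rule_value = rule_value, mask_radius = mask_radius,
         weight = weight, delay_ms = delay,
         receptor_port = port,
         synapse_template = if (!is.null(syn_tmpl)) syn_tmpl$name
                            else "static_synapse",
         synapse_params = if (!is.null(syn_tmpl))
           overlay_params(syn_tmpl, proj$synapse_overrides)
           else list()),
    class = "snn_realized_projection"
  )
}

collect_objectives <- function(spec) {
  out <- character(0)
  for (p in spec$populations) {
    for (ft in p$firing_targets)
      out <- c(out, paste0("population ", p$name, ": ", ft$state,
                           " firing rate target [", fmt_num(ft$lo_hz), ", ",
                           fmt_num(ft$hi_hz), "] Hz"))
    for (ob in p$objectives) {
      tv <- if (is.null(ob$target_value)) ""
            else paste0(" = ", paste(fmt_num(ob$target_value),
                                     collapse = " .. "))
      out <- c(out, paste0("population ", p$name, ": ", ob$metric, tv))
    }
  }
  out
}

#' Realize a full model
#'
#' Validates the spec, selects the active simulation (or the first when
#' none is marked active), and composes population, projection, stimulus
#' and recordable realization into a complete network realization -- a
#' deterministic function of `(spec, scale, seed)`.
#'
#' @param spec A valid `snn_model_spec`.
#' @param scale Scale in `(0, 1]`; defaults to the model header's scale.
#' @param seed Integer seed governing neuron placement and recordable
#'   selection (sub-seeds are derived per purpose).
#' @param cable A [cable_constants()] object.
#' @return A list of class `snn_realization`.
#' @export
realize_model <- function(spec, scale = NULL, seed = 1L,
                          cable = cable_constants()) {
  stopifnot(inherits(spec, "snn_model_spec"))
  report <- validate_model(spec)
  if (nrow(report) > 0L)
    stop("cannot realize an invalid model:\n",
         paste0("  - ", report$path, ": ", report$message, collapse = "\n"),
         call. = FALSE)
  scale <- scale %||% spec$model$scale
  if (!is_scalar_number(scale) || scale <= 0 || scale > 1)
    stop("scale must be in (0, 1]", call. = FALSE)
  sim <- active_simulation(spec)
  if (is.null(sim))
    stop("model '", spec$model$name, "' defines no simulation; ",
         "add one before building", call. = FALSE)
  if (scale < 1)
    warning("building at scale ", scale, ": reduced networks are not ",
            "dynamically equivalent to full-scale ones; interpret with ",
            "care", call. = FALSE)

  pops <- vector("list", length(spec$populations))
  names(pops) <- vapply(spec$populations, `[[`, character(1), "name")
  for (i in seq_along(spec$populations))
    pops[[i]] <- realize_population(spec$populations[[i]], spec, scale,
                                    seed, sim, index = i)

  projs <- lapply(spec$projections, function(pr)
    realize_projection(pr, pops[[pr$source]], pops[[pr$target]], spec,
                       sim$synaptic_gain, cable, sim,
                       find_population(spec, pr$source),
                       find_population(spec, pr$target)))

  stimuli <- lapply(sim$stimuli, function(st) {
    out <- unclass(st)
    out$stop_ms <- st$stop_ms %||% sim$duration_ms
    if (!identical(st$scope, "global")) {
      out$target_indices <- select_stimulus_targets(
        pops[[st$target]]$positions, st$scope$center, st$scope$radius)
    }
    out
  })

  recordables <- lapply(seq_along(sim$recordables), function(i) {
    r <- sim$recordables[[i]]
    out <- unclass(r)
    if (identical(r$kind, "membrane_potential")) {
      n <- pops[[r$target]]$n_scaled
      out$neuron_index <- with_seed(subseed(seed, SEED_RECORDABLE, i),
                                    sample.int(n, 1L))
    }
    out
  })

  structure(
    list(model_id = spec$model$model_id, model_name = spec$model$name,
         scale = scale, seed = as.integer(seed),
         populations = pops, projections = projs,
         stimuli = stimuli, recordables = recordables,
         objectives = collect_objectives(spec),
         simulation = list(dt_ms = sim$dt_ms, duration_ms = sim$duration_ms,
                           threads = sim$threads, space_dim = sim$space_dim,
                           bounds = sim$bounds,
                           synaptic_gain = sim$synaptic_gain)),
    class = "snn_realization"
  )
}

#' @export
print.snn_realization <- function(x, ...) {
  cat("<realization> ", x$model_name, " @ scale ", x$scale,
      ", seed ", x$seed, "\n", sep = "")
  for (p in x$populations)
    cat("  population ", p$name, " (", p$regime, "): n = ", p$n_scaled,
        "\n", sep = "")
  for (pr in x$projections)
    cat("  ", pr$source, " -> ", pr$target, " [", pr$rule_kind, " = ",
        fmt_num(pr$rule_value), "] w = ", fmt_num(signif(pr$weight, 6)),
        "\n", sep = "")
  invisible(x)
}
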