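#' Output generation: resolved description and simulation script
#'
#' The build's final step produces two artifacts: a resolved
#' model-description document in which every multi-entry attribute is
#' replaced by its collective outcome (with provenance, objectives and
#' to-optimize ranges carried as labelled sections), and a deterministic
#' PyNEST simulation script for NEST 3 in four fixed sections:
#' initialization, creation of neural populations, network building, and
#' stimuli/recordables/simulation.
#'
#' @name codegen
NULL

resolved_block <- function(entries) {
  r <- resolve_attribute(entries)
  refs <- character(0)
  for (p in r$provenance)
    if (!is.null(p$reference)) refs <- c(refs, p$reference$doi_or_url)
  out <- list(value = r$value %||% NA,
              n_contributions = r$n_contributions)
  if (length(refs)) out$references <- refs
  if (length(r$ranges)) out$optimizable_ranges <- r$ranges
  out
}

#' Build the resolved model description
#'
#' Applies collective aggregation to every attribute of the model and
#' returns the resolved document: attribute values (or `None` where no
#' active entry exists), contribution counts, per-attribute references,
#' to-optimize ranges under `optimizable_ranges`, and objectives under
#' their own section rather than among parameters.
#'
#' @param spec A valid `snn_model_spec`.
#' @param as_json If `TRUE`, return canonical JSON text instead of a list.
#' @return A list (or JSON string) representing the resolved description.
#' @export
build_description <- function(spec, as_json = FALSE) {
  stopifnot(inherits(spec, "snn_model_spec"))
  pops <- lapply(spec$populations, function(p) {
    objectives <- c(
      lapply(p$firing_targets, function(ft)
        list(metric = "mean firing rate", state = ft$state,
             target_range_hz = c(ft$lo_hz, ft$hi_hz))),
      lapply(p$objectives, function(o) drop_empty(list(
        metric = o$metric, target_value = o$target_value,
        reference = if (!is.null(o$reference)) o$reference$doi_or_url
                    else NULL)))
    )
    drop_empty(list(
      name = p$name, regime = p$regime,
      number = resolved_block(p$number),
      dendrite_extent_um = resolved_block(p$dendrite_extent_um),
      dendrite_diameter_um = resolved_block(p$dendrite_diameter_um),
      receptors = lapply(p$receptors, function(r) list(
        transmitter = r$transmitter,
        psp_amplitude_mv = resolved_block(r$psp_amplitude_mv),
        rise_time_ms = resolved_block(r$rise_time_ms))),
      template = p$template_ref,
      template_overrides = if (length(p$param_overrides))
        lapply(p$param_overrides, resolved_block) else NULL,
      objectives = objectives
    ))
  })
  projs <- lapply(spec$projections, function(pr) drop_empty(list(
    source = pr$source, target = pr$target, rule = pr$rule,
    rule_params = if (length(pr$rule_params)) pr$rule_params else NULL,
    axon_organization = resolved_block(pr$axon_organization),
    axon_domain_radius = if (!is.null(pr$axon_domain_radius$value))
      pr$axon_domain_radius else NULL,
    pct_projecting = resolved_block(pr$pct_projecting),
    bouton_count = resolved_block(pr$bouton_count),
    receptor_location = resolved_block(pr$receptor_location),
    redundancy = resolved_block(pr$redundancy),
    delay_ms = resolved_block(pr$delay_ms),
    weight_override = resolved_block(pr$weight_override),
    synapse_template = pr$synapse_template_ref,
    synapse_overrides = if (length(pr$synapse_overrides))
      lapply(pr$synapse_overrides, resolved_block) else NULL
  )))
  sim <- active_simulation(spec)
  desc <- drop_empty(list(
    model = spec$model,
    populations = pops,
    projections = projs,
    simulation = if (!is.null(sim)) unclass(sim) else NULL,
    references = lapply(spec$references, unclass),
    notes = lapply(spec$notes, unclass)
  ))
  if (!as_json) return(desc)
  description_json(desc)
}

description_json <- function(desc) {
  txt <- jsonlite::toJSON(sort_keys(desc), auto_unbox = TRUE, digits = NA,
                          null = "null", na = "null", pretty = 2)
  paste0(as.character(txt), "\n")
}

# ---- PyNEST emission -------------------------------------------------------

py_name <- function(x) {
  s <- gsub("[^A-Za-z0-9_]", "_", x)
  if (grepl("^[0-9]", s)) s <- paste0("p_", s)
  s
}

py_value <- function(v) {
  if (is.character(v)) paste0('"', v, '"')
  else if (is.logical(v)) if (isTRUE(v)) "True" else "False"
  else if (length(v) > 1L)
    paste0("[", paste(fmt_py_float(v), collapse = ", "), "]")
  else if (is.integer(v)) fmt_py_int(v)
  else fmt_py_float(v)
}

py_dict <- function(x) {
  if (length(x) == 0L) return("{}")
  items <- vapply(seq_along(x), function(i)
    paste0('"', names(x)[i], '": ', py_value(x[[i]])), character(1))
  paste0("{", paste(items, collapse = ", "), "}")
}

py_positions <- function(positions) {
  rows <- apply(positions, 1L, function(p)
    paste0("[", paste(fmt_py_float(p), collapse = ", "), "]"))
  paste0("[", paste(rows, collapse = ", "), "]")
}

section_header <- function(title) {
  bar <- strrep("=", 60)
  c(paste0("# ", bar), paste0("# ", title), paste0("# ", bar))
}

emit_population <- function(p) {
  var <- py_name(p$name)
  params <- p$resolved_params
  # multisynapse templates receive one synaptic time constant per
  # declared receptor port, in declaration order
  rises <- vapply(p$receptor_ports, function(q)
    q$rise_ms %||% NA_real_, numeric(1))
  if (length(rises) > 0L && !anyNA(rises) &&
      grepl("multisynapse", p$template))
    params$tau_syn <- rises
  out <- character(0)
  out <- c(out, paste0(var, "_params = ", py_dict(params)))
  out <- c(out, paste0(var, "_positions = nest.spatial.free(",
                       py_positions(p$positions), ")"))
  out <- c(out, paste0(var, ' = nest.Create("', p$template, '", ',
                       fmt_py_int(p$n_scaled),
                       ", params=", var, "_params",
                       ", positions=", var, "_positions)"))
  out
}

emit_connection <- function(pr, dim) {
  conn <- switch(pr$rule_kind,
    fixed_indegree = list(rule = "fixed_indegree",
                          indegree = as.integer(pr$rule_value),
                          allow_autapses = FALSE, allow_multapses = FALSE),
    fixed_outdegree = list(rule = "fixed_outdegree",
                           outdegree = as.integer(pr$rule_value),
                           allow_autapses = FALSE, allow_multapses = FALSE),
    bernoulli_const_p = list(rule = "pairwise_bernoulli",
                             p = pr$rule_value),
    gaussian_distance = list(rule = "pairwise_bernoulli"),
    stop("unsupported rule kind '", pr$rule_kind, "' in code generation",
         call. = FALSE)
  )
  conn_txt <- py_dict(conn)
  if (identical(pr$rule_kind, "gaussian_distance")) {
    conn_txt <- sub("}$", paste0(
      ', "p": nest.spatial_distributions.gaussian(nest.spatial.distance,',
      " std=", fmt_py_float(pr$rule_value), ")}"), conn_txt)
  }
  if (!is.null(pr$mask_radius)) {
    shape <- if (dim == 3) "spherical" else "circular"
    conn_txt <- sub("}$", paste0(
      ', "mask": {"', shape, '": {"radius": ',
      fmt_py_float(pr$mask_radius), "}}}"), conn_txt)
  }
  syn <- list(synapse_model = pr$synapse_template, weight = pr$weight,
              delay = pr$delay_ms)
  if (!is.na(pr$receptor_port))
    syn$receptor_type <- as.integer(pr$receptor_port)
  extra <- pr$synapse_params
  extra <- extra[setdiff(names(extra), c("weight", "delay"))]
  syn <- c(syn, extra)
  syn$synapse_model <- pr$synapse_template
  paste0("nest.Connect(", py_name(pr$source), ", ", py_name(pr$target),
         ", conn_spec=", conn_txt, ", syn_spec=", py_dict(syn), ")")
}

#' Emit the PyNEST simulation script
#'
#' Deterministically renders a realization as a NEST-3 python script with
#' four ordered sections (initialization; creation of neural populations;
#' network building; stimuli, recordables, and simulation).  Objectives
#' and metrics appear as comments in the initialization section.  Equal
#' realizations produce byte-identical scripts.
#'
#' @param real A `snn_realization`.
#' @return The script as a single character string.
#' @export
emit_script <- function(real) {
  stopifnot(inherits(real, "snn_realization"))
  sim <- real$simulation
  L <- character(0)

  L <- c(L, section_header("Initialization"))
  L <- c(L, "import nest", "",
         "nest.ResetKernel()",
         paste0("nest.resolution = ", fmt_py_float(sim$dt_ms)),
         paste0("nest.local_num_threads = ", fmt_py_int(sim$threads)),
         paste0("nest.rng_seed = ", fmt_py_int(max(1, real$seed))))
  if (length(real$objectives) > 0L) {
    L <- c(L, "", "# Objectives / metrics:")
    L <- c(L, paste0("#   ", real$objectives))
  }
  L <- c(L, "")

  L <- c(L, section_header("Creation of neural populations"))
  for (p in real$populations) L <- c(L, emit_population(p), "")

  L <- c(L, section_header("Network building"))
  for (pr in real$projections)
    L <- c(L, emit_connection(pr, sim$space_dim))
  if (length(real$projections) > 0L) L <- c(L, "")

  L <- c(L, section_header("Stimuli, recordables, and simulation"))
  for (i in seq_along(real$stimuli)) {
    st <- real$stimuli[[i]]
    var <- paste0("stim_", i)
    gp <- list(rate = st$rate_hz, start = st$start_ms, stop = st$stop_ms)
    L <- c(L, paste0(var, ' = nest.Create("poisson_generator", params=',
                     py_dict(gp), ")"))
    tgt <- py_name(st$target)
    if (!is.null(st$target_indices)) {
      idx <- paste(fmt_py_int(st$target_indices - 1L), collapse = ", ")
      tgt <- paste0(py_name(st$target), "[[", idx, "]]")
    }
    L <- c(L, paste0("nest.Connect(", var, ", ", tgt, ", syn_spec=",
                     py_dict(list(weight = st$weight,
                                  delay = st$delay_ms)), ")"))
  }
  for (i in seq_along(real$recordables)) {
    r <- real$recordables[[i]]
    var <- paste0("rec_", i)
    if (identical(r$kind, "spikes")) {
      L <- c(L, paste0(var, ' = nest.Create("spike_recorder")'),
             paste0("nest.Connect(", py_name(r$target), ", ", var, ")"))
    } else {
      i0 <- r$neuron_index - 1L
      L <- c(L, paste0(var, ' = nest.Create("voltmeter")'),
             paste0("nest.Connect(", var, ", ", py_name(r$target), "[",
                    fmt_py_int(i0), ":", fmt_py_int(i0 + 1L), "])"))
    }
  }
  L <- c(L, paste0("nest.Simulate(", fmt_py_float(sim$duration_ms), ")"), "")

  paste0(paste(L, collapse = "\n"), "\n")
}

#' Package the build outputs into a zip archive
#'
#' Packs the resolved description and the simulation script into a single
#' uncompressed zip file with stable member names
#' (`model_description.json`, `simulation.py`).
#'
#' @param description The resolved description: a list from
#'   [build_description()] or its JSON text.
#' @param script The script text from [emit_script()].
#' @param path Output zip path.
#' @return `path`, invisibly.
#' @export
package_outputs <- function(description, script, path) {
  if (!is.character(description))
    description <- description_json(description)
  write_stored_zip(path, list(
    "model_description.json" = description,
    "simulation.py" = script
  ))
  invisible(path)
}

#' Run the whole build: description, script, optional archive
#'
#' Convenience wrapper chaining [build_description()], [realize_model()],
#' [emit_script()] and optionally [package_outputs()].
#'
#' @inheritParams realize_model
#' @param out_dir Directory to write `model_description.json` and
#'   `simulation.py` into (created if missing); `NULL` to skip writing.
#' @param zip If `TRUE` also write `model_outputs.zip` in `out_dir`.
#' @return Invisibly, `list(description, realization, script, files)`.
#' @export
build_model <- function(spec, scale = NULL, seed = 1L,
                        cable = cable_constants(), out_dir = NULL,
                        zip = FALSE) {
  desc <- build_description(spec, as_json = TRUE)
  real <- realize_model(spec, scale = scale, seed = seed, cable = cable)
  script <- emit_script(real)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    dpath <- file.path(out_dir, "model_description.json")
    spath <- file.path(out_dir, "simulation.py")
    writeLines(desc, dpath, sep = "")
    writeLines(script, spath, sep = "")
    files <- c(dpath, spath)
    if (zip) {
      zpath <- file.path(out_dir, "model_outputs.zip")
      package_outputs(desc, script, zpath)
      files <- c(files, zpath)
    }
  }
  invisible(list(description = desc, realization = real, script = script,
                 files = files))
}
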