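# JSON (de)serialization of model descriptions.
#
# The on-disk dialect mirrors the in-memory structure one-to-one:
# top-level keys model / populations / projections / templates /
# simulations / references / notes; every multi-entry attribute is an
# array of entry objects.  Serialization is canonical -- object keys
# sorted, arrays in insertion order, empty collections omitted -- so
# equal specs always produce byte-identical text.

io_stop <- function(path, ...) {
  stop("schema error at ", path, ": ", ..., call. = FALSE)
}

check_keys <- function(obj, path, allowed, required = character(0)) {
  if (!is.list(obj)) io_stop(path, "expected a JSON object")
  nm <- names(obj)
  if (length(obj) > 0L && (is.null(nm) || any(!nzchar(nm))))
    io_stop(path, "expected a JSON object with named keys")
  unknown <- setdiff(nm, allowed)
  if (length(unknown) > 0L)
    io_stop(paste0(path, ".", unknown[1]), "unknown key '", unknown[1], "'")
  missing <- setdiff(required, nm)
  if (length(missing) > 0L)
    io_stop(path, "missing required key '", missing[1], "'")
  invisible(TRUE)
}

json_number <- function(x, path) {
  if (!is_scalar_number(x)) io_stop(path, "expected a number")
  as.numeric(x)
}

json_string <- function(x, path) {
  if (!is_scalar_string(x)) io_stop(path, "expected a string")
  x
}

json_enum <- function(x, path, choices) {
  x <- json_string(x, path)
  if (!(x %in% choices))
    io_stop(path, "'", x, "' is not one of: ", paste(choices, collapse = ", "))
  x
}

json_numvec <- function(x, path, len = NULL) {
  if (is.numeric(x)) v <- as.numeric(x)
  else if (is.list(x)) {
    v <- vapply(seq_along(x), function(i)
      json_number(x[[i]], paste0(path, "[", i, "]")), numeric(1))
  } else io_stop(path, "expected an array of numbers")
  if (!is.null(len) && length(v) != len)
    io_stop(path, "expected ", len, " numbers")
  v
}

parse_reference <- function(x, path) {
  check_keys(x, path, c("doi_or_url", "description"), "doi_or_url")
  snn_reference(json_string(x$doi_or_url, paste0(path, ".doi_or_url")),
                x$description %||% "")
}

parse_entry <- function(x, path) {
  check_keys(x, path, c("value", "flag", "owner", "reference", "note"),
             "value")
  v <- x$value
  if (is.list(v)) v <- json_numvec(v, paste0(path, ".value"))
  else if (!is.numeric(v) && !is_scalar_string(v))
    io_stop(paste0(path, ".value"), "expected a number, range or category")
  flag <- json_enum(x$flag %||% "fixed", paste0(path, ".flag"), ENTRY_FLAGS)
  ref <- if (!is.null(x$reference))
    parse_reference(x$reference, paste0(path, ".reference")) else NULL
  param_entry(v, flag = flag, owner = x$owner %||% "", reference = ref,
              note = x$note %||% "")
}

parse_entries <- function(x, path) {
  if (is.null(x)) return(list())
  if (!is.list(x) || !is.null(names(x)))
    io_stop(path, "expected an array of entries")
  lapply(seq_along(x), function(i)
    parse_entry(x[[i]], paste0(path, "[", i, "]")))
}

parse_entry_map <- function(x, path) {
  if (is.null(x) || length(x) == 0L) return(setNames(list(), character(0)))
  check_keys(x, path, names(x))   # named object with arbitrary keys
  out <- lapply(seq_along(x), function(i)
    parse_entries(x[[i]], paste0(path, ".", names(x)[i])))
  names(out) <- names(x)
  out
}

parse_annotations <- function(x, path) {
  if (is.null(x) || length(x) == 0L) return(setNames(list(), character(0)))
  if (!is.list(x) || is.null(names(x)))
    io_stop(path, "expected an object of annotations")
  x
}

parse_receptor <- function(x, path) {
  check_keys(x, path, c("transmitter", "psp_amplitude_mv", "rise_time_ms"),
             "transmitter")
  receptor_spec(
    json_enum(x$transmitter, paste0(path, ".transmitter"), TRANSMITTERS),
    parse_entries(x$psp_amplitude_mv, paste0(path, ".psp_amplitude_mv")),
    parse_entries(x$rise_time_ms, paste0(path, ".rise_time_ms"))
  )
}

parse_firing_target <- function(x, path) {
  check_keys(x, path, c("state", "lo_hz", "hi_hz"),
             c("state", "lo_hz", "hi_hz"))
  firing_target(json_enum(x$state, paste0(path, ".state"), RATE_STATES),
                json_number(x$lo_hz, paste0(path, ".lo_hz")),
                json_number(x$hi_hz, paste0(path, ".hi_hz")))
}

parse_objective <- function(x, path) {
  check_keys(x, path, c("metric", "target_value", "reference"), "metric")
  tv <- x$target_value
  if (!is.null(tv)) tv <- json_numvec(tv, paste0(path, ".target_value"))
  ref <- if (!is.null(x$reference))
    parse_reference(x$reference, paste0(path, ".reference")) else NULL
  objective_spec(json_string(x$metric, paste0(path, ".metric")), tv, ref)
}

parse_population <- function(x, path) {
  check_keys(x, path,
             c("name", "regime", "number", "receptors",
               "dendrite_extent_um", "dendrite_diameter_um",
               "firing_targets", "template_ref", "param_overrides",
               "objectives", "annotations"),
             "name")
  regime <- if (!is.null(x$regime))
    json_enum(x$regime, paste0(path, ".regime"), REGIMES) else NULL
  snn_population(
    name = json_string(x$name, paste0(path, ".name")),
    regime = regime,
    number = parse_entries(x$number, paste0(path, ".number")),
    receptors = lapply(seq_along(x$receptors %||% list()), function(i)
      parse_receptor(x$receptors[[i]], paste0(path, ".receptors[", i, "]"))),
    dendrite_extent_um =
      parse_entries(x$dendrite_extent_um, paste0(path, ".dendrite_extent_um")),
    dendrite_diameter_um =
      parse_entries(x$dendrite_diameter_um,
                    paste0(path, ".dendrite_diameter_um")),
    firing_targets = lapply(seq_along(x$firing_targets %||% list()),
      function(i) parse_firing_target(x$firing_targets[[i]],
                                      paste0(path, ".firing_targets[", i, "]"))),
    template_ref = if (!is.null(x$template_ref))
      json_string(x$template_ref, paste0(path, ".template_ref")) else NULL,
    param_overrides = parse_entry_map(x$param_overrides,
                                      paste0(path, ".param_overrides")),
    objectives = lapply(seq_along(x$objectives %||% list()), function(i)
      parse_objective(x$objectives[[i]], paste0(path, ".objectives[", i, "]"))),
    annotations = parse_annotations(x$annotations,
                                    paste0(path, ".annotations"))
  )
}

parse_projection <- function(x, path) {
  check_keys(x, path,
             c("source", "target", "rule", "rule_params",
               "axon_organization", "axon_domain_radius", "pct_projecting",
               "bouton_count", "receptor_location", "redundancy",
               "delay_ms", "weight_override", "synapse_template_ref",
               "synapse_overrides", "annotations"),
             c("source", "target"))
  adr <- list(value = NULL, unit = "coord")
  if (!is.null(x$axon_domain_radius)) {
    check_keys(x$axon_domain_radius, paste0(path, ".axon_domain_radius"),
               c("value", "unit"))
    if (!is.null(x$axon_domain_radius$value))
      adr$value <- json_number(x$axon_domain_radius$value,
                               paste0(path, ".axon_domain_radius.value"))
    if (!is.null(x$axon_domain_radius$unit))
      adr$unit <- json_enum(x$axon_domain_radius$unit,
                            paste0(path, ".axon_domain_radius.unit"),
                            c("coord", "mm"))
  }
  rp <- setNames(list(), character(0))
  if (!is.null(x$rule_params) && length(x$rule_params) > 0L) {
    check_keys(x$rule_params, paste0(path, ".rule_params"), c("p", "sigma"))
    rp <- lapply(seq_along(x$rule_params), function(i)
      json_number(x$rule_params[[i]],
                  paste0(path, ".rule_params.", names(x$rule_params)[i])))
    names(rp) <- names(x$rule_params)
  }
  snn_projection(
    source = json_string(x$source, paste0(path, ".source")),
    target = json_string(x$target, paste0(path, ".target")),
    rule = json_enum(x$rule %||% "fixed_indegree", paste0(path, ".rule"),
                     CONN_RULES),
    rule_params = rp,
    axon_organization = parse_entries(x$axon_organization,
                                      paste0(path, ".axon_organization")),
    axon_domain_radius = adr,
    pct_projecting = parse_entries(x$pct_projecting,
                                   paste0(path, ".pct_projecting")),
    bouton_count = parse_entries(x$bouton_count,
                                 paste0(path, ".bouton_count")),
    receptor_location = parse_entries(x$receptor_location,
                                      paste0(path, ".receptor_location")),
    redundancy = parse_entries(x$redundancy, paste0(path, ".redundancy")),
    delay_ms = parse_entries(x$delay_ms, paste0(path, ".delay_ms")),
    weight_override = parse_entries(x$weight_override,
                                    paste0(path, ".weight_override")),
    synapse_template_ref = if (!is.null(x$synapse_template_ref))
      json_string(x$synapse_template_ref,
                  paste0(path, ".synapse_template_ref")) else NULL,
    synapse_overrides = parse_entry_map(x$synapse_overrides,
                                        paste0(path, ".synapse_overrides")),
    annotations = parse_annotations(x$annotations, paste0(path, ".annotations"))
  )
}

parse_template <- function(x, path) {
  check_keys(x, path, c("name", "kind", "parameters"), c("name", "kind"))
  params <- setNames(list(), character(0))
  if (!is.null(x$parameters) && length(x$parameters) > 0L) {
    if (is.null(names(x$parameters)))
      io_stop(paste0(path, ".parameters"), "expected an object")
    params <- lapply(seq_along(x$parameters), function(i) {
      p <- x$parameters[[i]]
      pp <- paste0(path, ".parameters.", names(x$parameters)[i])
      check_keys(p, pp, c("default", "description"), "default")
      list(default = p$default, description = p$description %||% "")
    })
    names(params) <- names(x$parameters)
  }
  simulator_template(json_string(x$name, paste0(path, ".name")),
                     json_enum(x$kind, paste0(path, ".kind"), TEMPLATE_KINDS),
                     params)
}

parse_stimulus <- function(x, path) {
  check_keys(x, path,
             c("target", "rate_hz", "weight", "delay_ms", "start_ms",
               "stop_ms", "scope"),
             c("target", "rate_hz"))
  scope <- "global"
  if (!is.null(x$scope) && !identical(x$scope, "global")) {
    check_keys(x$scope, paste0(path, ".scope"), c("center", "radius"),
               c("center", "radius"))
    scope <- list(center = json_numvec(x$scope$center,
                                       paste0(path, ".scope.center")),
                  radius = json_number(x$scope$radius,
                                       paste0(path, ".scope.radius")))
  }
  stimulus_spec(
    target = json_string(x$target, paste0(path, ".target")),
    rate_hz = json_number(x$rate_hz, paste0(path, ".rate_hz")),
    weight = json_number(x$weight %||% 1, paste0(path, ".weight")),
    delay_ms = json_number(x$delay_ms %||% 1, paste0(path, ".delay_ms")),
    start_ms = json_number(x$start_ms %||% 0, paste0(path, ".start_ms")),
    stop_ms = if (!is.null(x$stop_ms))
      json_number(x$stop_ms, paste0(path, ".stop_ms")) else NULL,
    scope = scope
  )
}

parse_simulation <- function(x, path) {
  check_keys(x, path,
             c("description", "dt_ms", "duration_ms", "threads",
               "space_dim", "bounds", "synaptic_gain", "active",
               "stimuli", "recordables"))
  bounds <- list(c(0, 1), c(0, 1))
  if (!is.null(x$bounds)) {
    if (!is.list(x$bounds)) io_stop(paste0(path, ".bounds"),
                                    "expected an array of [min, max] pairs")
    bounds <- lapply(seq_along(x$bounds), function(i)
      json_numvec(x$bounds[[i]], paste0(path, ".bounds[", i, "]"), len = 2))
  }
  simulation_spec(
    description = x$description %||% "",
    dt_ms = json_number(x$dt_ms %||% 0.1, paste0(path, ".dt_ms")),
    duration_ms = json_number(x$duration_ms %||% 1000,
                              paste0(path, ".duration_ms")),
    threads = json_number(x$threads %||% 1, paste0(path, ".threads")),
    space_dim = json_number(x$space_dim %||% length(bounds),
                            paste0(path, ".space_dim")),
    bounds = bounds,
    synaptic_gain = json_number(x$synaptic_gain %||% 1,
                                paste0(path, ".synaptic_gain")),
    active = isTRUE(x$active %||% FALSE),
    stimuli = lapply(seq_along(x$stimuli %||% list()), function(i)
      parse_stimulus(x$stimuli[[i]], paste0(path, ".stimuli[", i, "]"))),
    recordables = lapply(seq_along(x$recordables %||% list()), function(i) {
      r <- x$recordables[[i]]
      rp <- paste0(path, ".recordables[", i, "]")
      check_keys(r, rp, c("target", "kind"), "target")
      recordable_spec(json_string(r$target, paste0(rp, ".target")),
                      json_enum(r$kind %||% "spikes", paste0(rp, ".kind"),
                                RECORD_KINDS))
    })
  )
}

parse_note <- function(x, path) {
  check_keys(x, path, c("text", "owner", "timestamp"), "text")
  snn_note(json_string(x$text, paste0(path, ".text")),
           x$owner %||% "", x$timestamp %||% "")
}

#' Load a model description from JSON
#'
#' Parses and structurally checks a model-description document.  Unknown
#' keys, missing required fields, bad enum values and projections whose
#' endpoints do not name an existing population are rejected with the JSON
#' path of the offending element.  Numerical invariants beyond structure
#' are the business of [validate_model()].
#'
#' @param x A file path or a JSON string.
#' @return A `snn_model_spec`.
#' @seealso [save_model()], [validate_model()]
#' @export
load_model <- function(x) {
  txt <- x
  if (is_scalar_string(x) && !grepl("^[[:space:]]*[{]", x)) {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(jsonlite::parse_json(txt),
                  error = function(e)
                    stop("parse error: ", conditionMessage(e), call. = FALSE))
  check_keys(doc, "$",
             c("model", "populations", "projections", "templates",
               "simulations", "references", "notes"),
             "model")
  m <- doc$model
  check_keys(m, "$.model",
             c("model_id", "species", "name", "description", "scale"),
             "name")
  spec <- snn_model(
    name = json_string(m$name, "$.model.name"),
    species = m$species %||% "",
    description = m$description %||% "",
    scale = json_number(m$scale %||% 1, "$.model.scale"),
    model_id = if (!is.null(m$model_id))
      json_string(m$model_id, "$.model.model_id") else NULL,
    populations = lapply(seq_along(doc$populations %||% list()), function(i)
      parse_population(doc$populations[[i]],
                       paste0("$.populations[", i, "]"))),
    projections = lapply(seq_along(doc$projections %||% list()), function(i)
      parse_projection(doc$projections[[i]],
                       paste0("$.projections[", i, "]"))),
    templates = lapply(seq_along(doc$templates %||% list()), function(i)
      parse_template(doc$templates[[i]], paste0("$.templates[", i, "]"))),
    simulations = lapply(seq_along(doc$simulations %||% list()), function(i)
      parse_simulation(doc$simulations[[i]],
                       paste0("$.simulations[", i, "]"))),
    references = lapply(seq_along(doc$references %||% list()), function(i)
      parse_reference(doc$references[[i]], paste0("$.references[", i, "]"))),
    notes = lapply(seq_along(doc$notes %||% list()), function(i)
      parse_note(doc$notes[[i]], paste0("$.notes[", i, "]")))
  )
  # Referential integrity is checked at load: a projection endpoint that
  # names no population is a schema error, not a mere report line.
  pop_names <- vapply(spec$populations, `[[`, character(1), "name")
  for (i in seq_along(spec$projections)) {
    pr <- spec$projections[[i]]
    for (side in c("source", "target")) {
      if (!(pr[[side]] %in% pop_names))
        io_stop(paste0("$.projections[", i, "].", side),
                "'", pr[[side]], "' is not a declared population")
    }
  }
  spec
}

# ---- serialization ---------------------------------------------------------

drop_empty <- function(x) {
  keep <- vapply(x, function(v) !is.null(v) && length(v) > 0L, logical(1))
  x[keep]
}

entry_to_json <- function(e) {
  drop_empty(list(value = e$value, flag = e$flag, owner = e$owner,
                  reference = if (!is.null(e$reference))
                    unclass(e$reference) else NULL,
                  note = if (nzchar(e$note %||% "")) e$note else NULL))
}

entries_to_json <- function(es) lapply(es, entry_to_json)

entry_map_to_json <- function(m) {
  if (length(m) == 0L) return(NULL)
  out <- lapply(m, entries_to_json)
  out
}

spec_to_jsonlist <- function(spec) {
  pops <- lapply(spec$populations, function(p) drop_empty(list(
    name = p$name, regime = p$regime,
    number = entries_to_json(p$number),
    receptors = lapply(p$receptors, function(r) drop_empty(list(
      transmitter = r$transmitter,
      psp_amplitude_mv = entries_to_json(r$psp_amplitude_mv),
      rise_time_ms = entries_to_json(r$rise_time_ms)))),
    dendrite_extent_um = entries_to_json(p$dendrite_extent_um),
    dendrite_diameter_um = entries_to_json(p$dendrite_diameter_um),
    firing_targets = lapply(p$firing_targets, unclass),
    template_ref = p$template_ref,
    param_overrides = entry_map_to_json(p$param_overrides),
    objectives = lapply(p$objectives, function(o) drop_empty(list(
      metric = o$metric, target_value = o$target_value,
      reference = if (!is.null(o$reference)) unclass(o$reference) else NULL))),
    annotations = if (length(p$annotations)) p$annotations else NULL
  )))
  projs <- lapply(spec$projections, function(pr) drop_empty(list(
    source = pr$source, target = pr$target, rule = pr$rule,
    rule_params = if (length(pr$rule_params)) pr$rule_params else NULL,
    axon_organization = entries_to_json(pr$axon_organization),
    axon_domain_radius = if (!is.null(pr$axon_domain_radius$value))
      list(value = pr$axon_domain_radius$value,
           unit = pr$axon_domain_radius$unit) else NULL,
    pct_projecting = entries_to_json(pr$pct_projecting),
    bouton_count = entries_to_json(pr$bouton_count),
    receptor_location = entries_to_json(pr$receptor_location),
    redundancy = entries_to_json(pr$redundancy),
    delay_ms = entries_to_json(pr$delay_ms),
    weight_override = entries_to_json(pr$weight_override),
    synapse_template_ref = pr$synapse_template_ref,
    synapse_overrides = entry_map_to_json(pr$synapse_overrides),
    annotations = if (length(pr$annotations)) pr$annotations else NULL
  )))
  tmpls <- lapply(spec$templates, function(t) drop_empty(list(
    name = t$name, kind = t$kind,
    parameters = if (length(t$parameters)) t$parameters else NULL
  )))
  sims <- lapply(spec$simulations, function(s) drop_empty(list(
    description = if (nzchar(s$description)) s$description else NULL,
    dt_ms = s$dt_ms, duration_ms = s$duration_ms, threads = s$threads,
    space_dim = s$space_dim, bounds = s$bounds,
    synaptic_gain = s$synaptic_gain, active = s$active,
    stimuli = lapply(s$stimuli, function(st) drop_empty(list(
      target = st$target, rate_hz = st$rate_hz, weight = st$weight,
      delay_ms = st$delay_ms, start_ms = st$start_ms, stop_ms = st$stop_ms,
      scope = if (identical(st$scope, "global")) "global" else st$scope))),
    recordables = lapply(s$recordables, unclass)
  )))
  drop_empty(list(
    model = spec$model,
    populations = pops, projections = projs, templates = tmpls,
    simulations = sims,
    references = lapply(spec$references, unclass),
    notes = lapply(spec$notes, unclass)
  ))
}

sort_keys <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && length(nm) > 0L && all(nzchar(nm)))
      x <- x[order(nm, method = "radix")]
    x <- lapply(x, sort_keys)
  }
  x
}

#' Serialize a model description to canonical JSON
#'
#' Validates the spec (any violation aborts), then writes canonical JSON:
#' object keys sorted, arrays in insertion order, full-precision numbers.
#' Equal specs always serialize to byte-identical text.
#'
#' @param spec A `snn_model_spec`.
#' @param path Optional file path; when given the text is also written
#'   there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
save_model <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "snn_model_spec"))
  report <- validate_model(spec)
  if (nrow(report) > 0L)
    stop("cannot save an invalid model:\n",
         paste0("  - ", report$path, ": ", report$message, collapse = "\n"),
         call. = FALSE)
  lst <- sort_keys(spec_to_jsonlist(spec))
  txt <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = 2)
  txt <- paste0(as.character(txt), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Test two model descriptions for semantic equality
#'
#' Two specs are equal when their canonical serializations coincide.
#' @param a,b `snn_model_spec` objects.
#' @export
model_specs_equal <- function(a, b) {
  identical(save_model(a), save_model(b))
}
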