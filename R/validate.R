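#' Validate a model description
#'
#' Checks every model invariant and returns a report -- one row per
#' violation, with the entity path and a message.  Validation is total: it
#' never raises on a structurally well-formed spec; an empty report means
#' the model is consistent.
#'
#' Checked invariants include: scale in (0, 1]; unique population names;
#' projection endpoints naming existing populations; entry flags and
#' to-optimize ranges; rise times positive; firing-rate ranges ordered and
#' non-negative; projection percentages in \[0, 100\] and redundancy >= 1;
#' receptor locations categorical or in \[0, 1\]; template references
#' resolvable; simulation timing, bounds and gain positive; at most one
#' active simulation; stimulus windows ordered, rates non-negative and
#' scoped radii positive.
#'
#' @param spec A `snn_model_spec`.
#' @return A data frame of class `snn_validation_report` with columns
#'   `path` and `message`; zero rows when the model is valid.
#' @export
validate_model <- function(spec) {
  stopifnot(inherits(spec, "snn_model_spec"))
  paths <- character(0)
  msgs <- character(0)
  flag <- function(path, msg) {
    paths <<- c(paths, path)
    msgs <<- c(msgs, msg)
  }

  sc <- spec$model$scale
  if (!is_scalar_number(sc) || sc <= 0 || sc > 1)
    flag("model.scale", "scale must be in (0, 1]")

  pop_names <- vapply(spec$populations, `[[`, character(1), "name")
  if (anyDuplicated(pop_names))
    flag("populations", paste0("duplicate population name '",
                               pop_names[duplicated(pop_names)][1], "'"))
  tmpl_names <- vapply(spec$templates, `[[`, character(1), "name")
  tmpl_kinds <- vapply(spec$templates, `[[`, character(1), "kind")

  check_entries <- function(es, path, numeric_ok = TRUE, categorical_ok = TRUE,
                            categories = NULL, lo = -Inf, hi = Inf,
                            strict_lo = FALSE) {
    for (i in seq_along(es)) {
      e <- es[[i]]
      p <- paste0(path, "[", i, "]")
      if (!(e$flag %in% ENTRY_FLAGS))
        flag(p, "invalid data flag")
      if (is.numeric(e$value)) {
        if (!numeric_ok) flag(p, "numeric value not allowed here")
        if (length(e$value) == 2L) {
          if (e$flag != "to_optimize")
            flag(p, "range values require the to_optimize flag")
          if (e$value[1] > e$value[2]) flag(p, "range must satisfy lo <= hi")
        }
        bad <- if (strict_lo) any(e$value <= lo) else any(e$value < lo)
        if (bad || any(e$value > hi))
          flag(p, paste0("value outside [", lo, ", ", hi, "]"))
      } else {
        if (!categorical_ok) flag(p, "categorical value not allowed here")
        else if (!is.null(categories) && !(e$value %in% categories))
          flag(p, paste0("category must be one of: ",
                         paste(categories, collapse = ", ")))
      }
    }
  }

  for (k in seq_along(spec$populations)) {
    p <- spec$populations[[k]]
    base <- paste0("populations[", k, "] '", p$name, "'")
    check_entries(p$number, paste0(base, ".number"), categorical_ok = FALSE,
                  lo = 0, strict_lo = TRUE)
    check_entries(p$dendrite_extent_um, paste0(base, ".dendrite_extent_um"),
                  categorical_ok = FALSE, lo = 0, strict_lo = TRUE)
    check_entries(p$dendrite_diameter_um,
                  paste0(base, ".dendrite_diameter_um"),
                  categorical_ok = FALSE, lo = 0, strict_lo = TRUE)
    for (j in seq_along(p$receptors)) {
      r <- p$receptors[[j]]
      rb <- paste0(base, ".receptors[", j, "]")
      check_entries(r$psp_amplitude_mv, paste0(rb, ".psp_amplitude_mv"),
                    categorical_ok = FALSE)
      check_entries(r$rise_time_ms, paste0(rb, ".rise_time_ms"),
                    categorical_ok = FALSE, lo = 0, strict_lo = TRUE)
    }
    for (j in seq_along(p$firing_targets)) {
      ft <- p$firing_targets[[j]]
      fb <- paste0(base, ".firing_targets[", j, "]")
      if (ft$lo_hz < 0 || ft$hi_hz < 0)
        flag(fb, "firing rates must be non-negative")
      if (ft$lo_hz > ft$hi_hz)
        flag(fb, "firing-rate range must satisfy lo_hz <= hi_hz")
    }
    if (!is.null(p$template_ref)) {
      if (!(p$template_ref %in% tmpl_names[tmpl_kinds == "neuron"]))
        flag(paste0(base, ".template_ref"),
             paste0("no neuron template named '", p$template_ref, "'"))
    }
    for (nm in names(p$param_overrides))
      check_entries(p$param_overrides[[nm]],
                    paste0(base, ".param_overrides.", nm))
  }

  for (k in seq_along(spec$projections)) {
    pr <- spec$projections[[k]]
    base <- paste0("projections[", k, "] '", pr$source, "->", pr$target, "'")
    for (side in c("source", "target"))
      if (!(pr[[side]] %in% pop_names))
        flag(paste0(base, ".", side),
             paste0("'", pr[[side]], "' is not a declared population"))
    check_entries(pr$axon_organization, paste0(base, ".axon_organization"),
                  numeric_ok = FALSE, categories = AXON_ORGS)
    check_entries(pr$pct_projecting, paste0(base, ".pct_projecting"),
                  categorical_ok = FALSE, lo = 0, hi = 100)
    check_entries(pr$bouton_count, paste0(base, ".bouton_count"),
                  categorical_ok = FALSE, lo = 0)
    check_entries(pr$receptor_location, paste0(base, ".receptor_location"),
                  categories = RECEPTOR_CATEGORIES, lo = 0, hi = 1)
    check_entries(pr$redundancy, paste0(base, ".redundancy"),
                  categorical_ok = FALSE, lo = 1)
    rr <- resolve_attribute(pr$redundancy)
    if (!is.null(rr$value) && rr$value < 1)
      flag(paste0(base, ".redundancy"), "resolved redundancy must be >= 1")
    pp <- resolve_attribute(pr$pct_projecting)
    if (!is.null(pp$value) && (pp$value < 0 || pp$value > 100))
      flag(paste0(base, ".pct_projecting"),
           "resolved projection percentage must be in [0, 100]")
    check_entries(pr$delay_ms, paste0(base, ".delay_ms"),
                  categorical_ok = FALSE, lo = 0, strict_lo = TRUE)
    check_entries(pr$weight_override, paste0(base, ".weight_override"),
                  categorical_ok = FALSE)
    if (pr$rule == "bernoulli_const_p") {
      pv <- pr$rule_params$p
      if (is.null(pv) || !is_scalar_number(pv) || pv < 0 || pv > 1)
        flag(paste0(base, ".rule_params.p"),
             "bernoulli_const_p requires p in [0, 1]")
    }
    if (pr$rule == "gaussian_distance") {
      sv <- pr$rule_params$sigma
      if (is.null(sv) || !is_scalar_number(sv) || sv <= 0)
        flag(paste0(base, ".rule_params.sigma"),
             "gaussian_distance requires sigma > 0")
    }
    if (!is.null(pr$axon_domain_radius$value) &&
        pr$axon_domain_radius$value <= 0)
      flag(paste0(base, ".axon_domain_radius"), "radius must be > 0")
    if (!is.null(pr$synapse_template_ref) &&
        !(pr$synapse_template_ref %in% tmpl_names[tmpl_kinds == "synapse"]))
      flag(paste0(base, ".synapse_template_ref"),
           paste0("no synapse template named '", pr$synapse_template_ref, "'"))
    for (nm in names(pr$synapse_overrides))
      check_entries(pr$synapse_overrides[[nm]],
                    paste0(base, ".synapse_overrides.", nm))
  }

  n_active <- sum(vapply(spec$simulations, function(s) isTRUE(s$active),
                         logical(1)))
  if (n_active > 1L)
    flag("simulations", "at most one simulation may be active")
  for (k in seq_along(spec$simulations)) {
    s <- spec$simulations[[k]]
    base <- paste0("simulations[", k, "]")
    if (s$dt_ms <= 0) flag(paste0(base, ".dt_ms"), "dt_ms must be > 0")
    if (s$duration_ms <= 0)
      flag(paste0(base, ".duration_ms"), "duration_ms must be > 0")
    if (s$threads < 1) flag(paste0(base, ".threads"), "threads must be >= 1")
    if (!(s$space_dim %in% c(2, 3)))
      flag(paste0(base, ".space_dim"), "space_dim must be 2 or 3")
    if (length(s$bounds) != s$space_dim)
      flag(paste0(base, ".bounds"),
           "bounds must give one [min, max] pair per axis")
    for (j in seq_along(s$bounds))
      if (s$bounds[[j]][1] >= s$bounds[[j]][2])
        flag(paste0(base, ".bounds[", j, "]"), "min must be < max")
    if (s$synaptic_gain <= 0)
      flag(paste0(base, ".synaptic_gain"), "synaptic_gain must be > 0")
    for (j in seq_along(s$stimuli)) {
      st <- s$stimuli[[j]]
      sb <- paste0(base, ".stimuli[", j, "]")
      if (!(st$target %in% pop_names))
        flag(paste0(sb, ".target"),
             paste0("'", st$target, "' is not a declared population"))
      if (st$rate_hz < 0) flag(paste0(sb, ".rate_hz"), "rate must be >= 0")
      if (!is.null(st$stop_ms) && st$start_ms > st$stop_ms)
        flag(sb, "start_ms must be <= stop_ms")
      if (!identical(st$scope, "global")) {
        if (st$scope$radius <= 0)
          flag(paste0(sb, ".scope.radius"), "scoped radius must be > 0")
        if (length(st$scope$center) != s$space_dim)
          flag(paste0(sb, ".scope.center"),
               "centre dimension must match space_dim")
      }
    }
    for (j in seq_along(s$recordables)) {
      r <- s$recordables[[j]]
      if (!(r$target %in% pop_names))
        flag(paste0(base, ".recordables[", j, "].target"),
             paste0("'", r$target, "' is not a declared population"))
    }
  }

  structure(data.frame(path = paths, message = msgs,
                       stringsAsFactors = FALSE),
            class = c("snn_validation_report", "data.frame"))
}

#' @export
print.snn_validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation report> no violations\n")
  } else {
    cat("<validation report> ", nrow(x), " violation(s):\n", sep = "")
    for (i in seq_len(nrow(x)))
      cat("  - ", x$path[i], ": ", x$message[i], "\n", sep = "")
  }
  invisible(x)
}
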