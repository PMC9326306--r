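#' Importing connectomes and simulator templates
#'
#' Connectomic data arrive as two JSON files: nodes, mapped to neural
#' populations, and edges, mapped to projections.  Simulator model
#' templates arrive as one JSON document carrying parameter names,
#' descriptions and default values.  Imports never invent values: any
#' attribute absent from the input is left unresolved for later entry.
#'
#' @name importers
NULL

read_json_doc <- function(x, what) {
  txt <- x
  if (is_scalar_string(x) && !grepl("^[[:space:]]*[\\[{]", x)) {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    txt <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  tryCatch(jsonlite::parse_json(txt),
           error = function(e) stop("parse error in ", what, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Import connectomic data as a model
#'
#' Maps each node to a neural population (name; number and regime when
#' present) and each edge to a projection (source, target; delay and
#' weight when present).  Extra keys are preserved verbatim under
#' `annotations`.  Imported edge weights are stored as weight overrides;
#' their units cannot be verified against the simulator, so a warning is
#' issued when any are present.
#'
#' Node dialect: `[{"name": ..., "number": ..., "regime": ..., ...}]`.
#' Edge dialect: `[{"source": ..., "target": ..., "delay": ...,
#' "weight": ..., ...}]`.
#'
#' @param nodes_doc,edges_doc File paths or JSON strings.
#' @param model_name Name for the created model.
#' @param species Species label.
#' @return A `snn_model_spec` holding the imported populations and
#'   projections (no templates or simulations yet).
#' @export
import_connectome <- function(nodes_doc, edges_doc,
                              model_name = "imported-connectome",
                              species = "") {
  nodes <- read_json_doc(nodes_doc, "nodes document")
  edges <- read_json_doc(edges_doc, "edges document")
  if (!is.list(nodes) || !is.null(names(nodes)))
    stop("nodes document must be a JSON array", call. = FALSE)
  if (!is.list(edges) || !is.null(names(edges)))
    stop("edges document must be a JSON array", call. = FALSE)

  seen <- character(0)
  populations <- lapply(seq_along(nodes), function(i) {
    nd <- nodes[[i]]
    if (is.null(nd$name) || !is_scalar_string(nd$name))
      stop("node ", i, " has no name", call. = FALSE)
    if (nd$name %in% seen)
      stop("duplicate node name '", nd$name, "'", call. = FALSE)
    seen <<- c(seen, nd$name)
    regime <- NULL
    if (!is.null(nd$regime)) {
      if (!(nd$regime %in% REGIMES))
        stop("node '", nd$name, "': regime must be 'excitatory' or ",
             "'inhibitory'", call. = FALSE)
      regime <- nd$regime
    }
    number <- list()
    if (!is.null(nd$number))
      number <- entries(as.numeric(nd$number),
                        note = "imported from connectome nodes")
    extra <- nd[setdiff(names(nd), c("name", "number", "regime"))]
    snn_population(name = nd$name, regime = regime, number = number,
                   annotations = if (length(extra)) extra
                                 else setNames(list(), character(0)))
  })
  node_names <- vapply(populations, `[[`, character(1), "name")

  any_weight <- FALSE
  projections <- lapply(seq_along(edges), function(i) {
    ed <- edges[[i]]
    for (side in c("source", "target")) {
      if (is.null(ed[[side]]))
        stop("edge ", i, " lacks a ", side, call. = FALSE)
      if (!(ed[[side]] %in% node_names))
        stop("edge ", i, " references unknown node '", ed[[side]], "'",
             call. = FALSE)
    }
    delay <- if (!is.null(ed$delay))
      entries(as.numeric(ed$delay), note = "imported from connectome edges")
      else list()
    weight <- list()
    if (!is.null(ed$weight)) {
      any_weight <<- TRUE
      weight <- entries(as.numeric(ed$weight),
                        note = "imported from connectome edges; units unverified")
    }
    extra <- ed[setdiff(names(ed), c("source", "target", "delay", "weight"))]
    snn_projection(source = ed$source, target = ed$target,
                   delay_ms = delay, weight_override = weight,
                   annotations = if (length(extra)) extra
                                 else setNames(list(), character(0)))
  })
  if (any_weight)
    warning("imported edge weights stored as weight overrides; their ",
            "units (tracer strength vs. synaptic weight) are not verified",
            call. = FALSE)

  snn_model(name = model_name, species = species,
            description = "imported from connectome node/edge documents",
            populations = populations, projections = projections)
}

#' Import a simulator model template
#'
#' Reads a neuron or synapse model template: name, kind, and a parameter
#' table of names, default values and descriptions.  Parameters may be
#' given either as an object keyed by name or as an array of
#' `{"name", "default", "description"}` records (where duplicate names
#' are rejected).  Re-importing the same document yields an equal
#' template; model-level overrides never mutate an imported template.
#'
#' @param doc File path or JSON string.
#' @return A `snn_template`.
#' @export
import_simulator_template <- function(doc) {
  x <- read_json_doc(doc, "template document")
  if (is.null(x$kind))
    stop("template document lacks a 'kind' (neuron or synapse)",
         call. = FALSE)
  if (is.null(x$name)) stop("template document lacks a name", call. = FALSE)
  params <- setNames(list(), character(0))
  p <- x$parameters %||% list()
  if (length(p) > 0L) {
    if (!is.null(names(p)) && all(nzchar(names(p)))) {
      params <- lapply(p, function(q) list(default = q$default,
                                           description = q$description %||% ""))
      names(params) <- names(p)
    } else {
      nms <- vapply(p, function(q) q$name %||% "", character(1))
      if (any(!nzchar(nms)))
        stop("template parameter records require a name", call. = FALSE)
      if (anyDuplicated(nms))
        stop("duplicate parameter name '", nms[duplicated(nms)][1],
             "' in template '", x$name, "'", call. = FALSE)
      params <- lapply(p, function(q) list(default = q$default,
                                           description = q$description %||% ""))
      names(params) <- nms
    }
  }
  simulator_template(x$name, x$kind, params)
}
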