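#' Collective resolution of multi-entry attributes
#'
#' When several contributors have supplied values for the same attribute,
#' the build resolves them into a single "collective outcome" at query time.
#' Numeric entries are averaged; categorical entries are tallied into an
#' importance index and the most frequent category wins.  Deactivated
#' entries are never considered, and objective-flagged entries are routed to
#' the objective list rather than into parameter values.
#'
#' @name aggregation
NULL

resolved_value <- function(value, n, provenance = list(), ranges = list(),
                           objectives = list()) {
  structure(
    list(value = value, n_contributions = n, provenance = provenance,
         ranges = ranges, objectives = objectives),
    class = "snn_resolved"
  )
}

#' @export
print.snn_resolved <- function(x, ...) {
  v <- if (is.null(x$value)) "None" else format(x$value)
  cat("<resolved> ", v, "  (", x$n_contributions, " contribution",
      if (x$n_contributions != 1) "s", ")\n", sep = "")
  invisible(x)
}

entry_provenance <- function(e, index) {
  p <- list(index = index, flag = e$flag, owner = e$owner %||% "")
  if (!is.null(e$reference)) p$reference <- e$reference
  if (e$flag == "to_optimize" && is.numeric(e$value) && length(e$value) == 2L)
    p$range <- e$value
  p
}

#' Resolve numeric entries to their collective mean
#'
#' Averages the values of all entries not flagged `deactivated`.  A
#' `to_optimize` range entry contributes its midpoint (the build needs one
#' runnable value; the range itself is preserved in the provenance for a
#' future optimizer).
#'
#' @param entries A list of [param_entry()] objects with numeric values.
#' @return A `snn_resolved` object; its `value` is `NULL` when no active
#'   entry exists.
#' @examples
#' resolve_numeric(list(param_entry(2), param_entry(4)))$value        # 3
#' resolve_numeric(list(param_entry(5), param_entry(100, "deactivated")))$value
#' @export
resolve_numeric <- function(entries) {
  check_entry_list(entries)
  active_idx <- which(vapply(entries, function(e) e$flag != "deactivated",
                             logical(1)))
  vals <- numeric(0)
  prov <- list()
  ranges <- list()
  for (i in active_idx) {
    e <- entries[[i]]
    if (!is.numeric(e$value))
      stop("entry ", i, " is not numeric; cannot resolve numerically",
           call. = FALSE)
    v <- if (length(e$value) == 2L) mean(e$value) else e$value
    vals <- c(vals, v)
    prov[[length(prov) + 1L]] <- entry_provenance(e, i)
    if (e$flag == "to_optimize" && length(e$value) == 2L)
      ranges[[length(ranges) + 1L]] <- e$value
  }
  if (length(vals) == 0L) return(resolved_value(NULL, 0L, ranges = ranges))
  resolved_value(mean(vals), length(vals), prov, ranges = ranges)
}

#' Resolve categorical entries by importance index
#'
#' Tallies the frequency of each category among non-deactivated entries
#' (the "importance index") and returns the most frequent one.  Ties are
#' broken in favour of the earliest-inserted among the tied categories.
#'
#' @param entries A list of [param_entry()] objects with category values.
#' @return A `snn_resolved` object.
#' @examples
#' resolve_categorical(list(param_entry("focused"), param_entry("focused"),
#'                          param_entry("diffused")))$value   # "focused"
#' @export
resolve_categorical <- function(entries) {
  check_entry_list(entries)
  active_idx <- which(vapply(entries, function(e) e$flag != "deactivated",
                             logical(1)))
  vals <- character(0)
  prov <- list()
  for (i in active_idx) {
    e <- entries[[i]]
    if (!is_scalar_string(e$value))
      stop("entry ", i, " is not categorical; cannot resolve as a category",
           call. = FALSE)
    vals <- c(vals, e$value)
    prov[[length(prov) + 1L]] <- entry_provenance(e, i)
  }
  if (length(vals) == 0L) return(resolved_value(NULL, 0L))
  cats <- unique(vals)                       # insertion order
  counts <- vapply(cats, function(cc) sum(vals == cc), numeric(1))
  winner <- cats[[which.max(counts)]]        # first max = earliest inserted
  resolved_value(winner, length(vals), prov)
}

#' Resolve an attribute's entry list
#'
#' The canonical entry point: routes `objective`-flagged entries to the
#' objective list, dispatches the rest to [resolve_numeric()] or
#' [resolve_categorical()] according to their common kind, and records the
#' number of contributions and their provenance.
#'
#' @param entries A list of [param_entry()] objects (possibly empty or
#'   `NULL`).
#' @return A `snn_resolved` object whose `objectives` field carries any
#'   objective-flagged entries verbatim.
#' @export
resolve_attribute <- function(entries) {
  if (is.null(entries) || length(entries) == 0L)
    return(resolved_value(NULL, 0L))
  check_entry_list(entries)
  is_obj <- vapply(entries, function(e) e$flag == "objective", logical(1))
  objectives <- entries[is_obj]
  rest <- entries[!is_obj]
  if (length(rest) == 0L)
    return(resolved_value(NULL, 0L, objectives = objectives))
  kinds <- vapply(rest, function(e) if (is.numeric(e$value)) "num" else "cat",
                  character(1))
  if (length(unique(kinds)) > 1L)
    stop("attribute mixes numeric and categorical entries; ",
         "cannot resolve a heterogeneous list", call. = FALSE)
  out <- if (kinds[1] == "num") resolve_numeric(rest)
         else resolve_categorical(rest)
  out$objectives <- objectives
  out
}

# Bare resolved value (or NULL) -- the common case inside the builder.
resolve_value <- function(entries) resolve_attribute(entries)$value

check_entry_list <- function(entries) {
  if (!is.list(entries))
    stop("expected a list of parameter entries", call. = FALSE)
  for (i in seq_along(entries)) {
    if (!is_entry(entries[[i]]))
      stop("element ", i, " is not a parameter entry", call. = FALSE)
  }
  invisible(TRUE)
}
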