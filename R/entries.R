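#' Parameter entry flags
#'
#' Every model attribute may carry several contributed values ("entries"),
#' each labelled with a data flag: `fixed` for high-confidence values,
#' `to_optimize` for exploration ranges, `objective` for target behaviours
#' used in calibration (never in parameter resolution), and `deactivated`
#' to exclude outliers or low-confidence contributions without deleting them.
#' @export
ENTRY_FLAGS <- c("fixed", "to_optimize", "objective", "deactivated")

#' Create a parameter entry
#'
#' A parameter entry is one contributed value for one model attribute, with
#' its data flag, owner label and optional literature reference.  Attributes
#' store lists of entries even when only one value is known; multiple active
#' entries are combined into a collective outcome by [resolve_attribute()].
#'
#' @param value A single number, a single category string, or -- for
#'   numeric `to_optimize` entries -- a closed range `c(lo, hi)`.
#' @param flag One of `"fixed"`, `"to_optimize"`, `"objective"`,
#'   `"deactivated"`.
#' @param owner Free-text owner label (carried for attribution, never
#'   enforced).
#' @param reference Optional [snn_reference()] documenting the value's
#'   source.
#' @param note Free-text note.
#' @return A list of class `snn_entry`.
#' @examples
#' param_entry(10000)
#' param_entry(c(100, 300), flag = "to_optimize")
#' param_entry("focused", owner = "jdoe")
#' @export
param_entry <- function(value, flag = "fixed", owner = "", reference = NULL,
                        note = "") {
  if (!is_scalar_string(flag) || !(flag %in% ENTRY_FLAGS))
    stop("entry flag must be one of: ", paste(ENTRY_FLAGS, collapse = ", "),
         call. = FALSE)
  if (is.numeric(value)) {
    if (!(length(value) %in% c(1L, 2L)))
      stop("numeric entry value must be a scalar or a [lo, hi] range",
           call. = FALSE)
    if (length(value) == 2L && value[1] > value[2])
      stop("entry range must satisfy lo <= hi", call. = FALSE)
    value <- as.numeric(value)
  } else if (!is_scalar_string(value)) {
    stop("entry value must be numeric or a single category string",
         call. = FALSE)
  }
  structure(
    list(value = value, flag = flag, owner = owner,
         reference = reference, note = note),
    class = "snn_entry"
  )
}

#' Shorthand: wrap a value as a single fixed entry list
#'
#' Convenience used pervasively by the fixture builders: attributes hold
#' lists of entries, and most of the time there is exactly one fixed value.
#' @inheritParams param_entry
#' @return A list holding one `snn_entry`.
#' @export
entries <- function(value, flag = "fixed", owner = "", reference = NULL,
                    note = "") {
  list(param_entry(value, flag = flag, owner = owner, reference = reference,
                   note = note))
}

is_entry <- function(x) inherits(x, "snn_entry")

entry_is_numeric <- function(e) is.numeric(e$value)
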