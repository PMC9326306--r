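#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Evaluate code under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, runs `code`, and restores the state,
#' so that library calls never perturb a caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed per purpose, kept inside the 32-bit integer range.
# One user-facing seed governs placement, recordable selection and sampling;
# each consumer derives its own stream with a distinct purpose offset.
subseed <- function(seed, purpose, index = 0L) {
  stopifnot(is_scalar_number(seed))
  base <- (abs(as.numeric(seed)) %% 1000003) * 2039 + purpose * 101 + index
  as.integer(base %% 2147483647)
}

# Shortest practical decimal text for a double (fixed locale, no scientific
# notation for the magnitudes a model description holds).
fmt_num <- function(x) {
  if (length(x) > 1L) return(vapply(x, fmt_num, character(1)))
  if (is.na(x)) return("None")
  s <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  s
}

# Python float literal: always carries a decimal point.
fmt_py_float <- function(x) {
  if (length(x) > 1L) return(vapply(x, fmt_py_float, character(1)))
  s <- fmt_num(x)
  if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
  s
}

fmt_py_int <- function(x) format(as.integer(round(x)), trim = TRUE, scientific = FALSE)
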