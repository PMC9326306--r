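#' Grid-search calibration against firing-rate target intervals
#'
#' Calibration compares simulated mean firing rates, per population and
#' per stimulation regime, against target intervals of plausible rates.
#' The per-pair error is the distance of the observed rate to the centre
#' of its interval, normalized by the interval half-width (so the interval
#' boundary maps to error 1); the total objective combines the per-pair
#' errors, and an exhaustive grid search over weight values minimizes it.
#' The evaluator that produces rates from parameters is injected by the
#' caller (typically: run the emitted script under the simulator and parse
#' the recorded rates; in tests, an analytic surrogate).
#'
#' @name calibration
NULL

#' Create a rate observation
#'
#' @param population Population name.
#' @param regime_label Stimulation condition label (e.g. `"baseline"`).
#' @param rate_hz Observed mean firing rate, `>= 0`.
#' @export
rate_observation <- function(population, regime_label, rate_hz) {
  if (rate_hz < 0) stop("rate_hz must be >= 0", call. = FALSE)
  structure(list(population = population, regime_label = regime_label,
                 rate_hz = rate_hz),
            class = "snn_rate_observation")
}

#' Normalized distance to the centre of a target interval
#'
#' `|rate - (lo+hi)/2| / ((hi-lo)/2)` for a proper interval, so 0 at the
#' centre and 1 at either bound.  The degenerate point target `lo == hi`
#' uses a relative distance `|rate - lo| / max(lo, 1e-6)`.
#'
#' @param rate_hz Observed rate (Hz).
#' @param lo_hz,hi_hz Target interval bounds, `lo_hz <= hi_hz`.
#' @return Non-negative error.
#' @export
interval_error <- function(rate_hz, lo_hz, hi_hz) {
  if (lo_hz > hi_hz) stop("target interval requires lo <= hi", call. = FALSE)
  if (hi_hz > lo_hz) {
    center <- (lo_hz + hi_hz) / 2
    abs(rate_hz - center) / ((hi_hz - lo_hz) / 2)
  } else {
    abs(rate_hz - lo_hz) / max(lo_hz, 1e-6)
  }
}

target_key <- function(population, regime_label)
  paste0(population, "|", regime_label)

#' Name a calibration target for one population and regime
#'
#' Builds the key used in the target map passed to [total_objective()]
#' and [grid_search()].
#' @param population Population name.
#' @param regime_label Stimulation condition label.
#' @export
calibration_target_key <- target_key

#' Multi-objective calibration error
#'
#' Combines [interval_error()] over all observations.  Every observation
#' must have a matching target, keyed by
#' `calibration_target_key(population, regime_label)` and holding a
#' [firing_target()] or any list with `lo_hz` / `hi_hz`.
#'
#' @param observations List of [rate_observation()] objects.
#' @param targets Named list mapping target keys to rate intervals.
#' @param combine How to combine per-pair errors: `"sum"` (default),
#'   `"mean"` or `"max"`.
#' @return Non-negative total error.
#' @export
total_objective <- function(observations, targets, combine = "sum") {
  combine <- match.arg(combine, c("sum", "mean", "max"))
  if (length(observations) == 0L) return(0)
  errs <- vapply(observations, function(ob) {
    key <- target_key(ob$population, ob$regime_label)
    tg <- targets[[key]]
    if (is.null(tg))
      stop("no calibration target for ", key, call. = FALSE)
    interval_error(ob$rate_hz, tg$lo_hz, tg$hi_hz)
  }, numeric(1))
  switch(combine, sum = sum(errs), mean = mean(errs), max = max(errs))
}

#' Exhaustive grid search over parameter values
#'
#' Evaluates the full Cartesian product of the grid (frozen parameters
#' held constant at their assigned values), scores each point with
#' [total_objective()], and returns the argmin -- ties resolved in favour
#' of the first point in lexicographic grid order (the first grid
#' parameter varies slowest) -- together with the full evaluation trace.
#' An evaluator failure at a point is recorded as infinite error and the
#' search continues.
#'
#' @param evaluator Function taking a named list of parameter values and
#'   returning a list of [rate_observation()] objects.
#' @param grid Named list of candidate value vectors, in significance
#'   order.
#' @param targets Target map as in [total_objective()].
#' @param frozen Named list of parameter assignments held fixed; a frozen
#'   name also present in the grid wins over the grid entry (with a
#'   warning).
#' @param combine Error combination rule, see [total_objective()].
#' @return `list(best_params, best_error, trace)` where `trace` is a data
#'   frame with one row per evaluated point.
#' @examples
#' ev <- function(p) list(rate_observation("pop", "base", p$w))
#' tg <- setNames(list(firing_target("resting", 2, 4)),
#'                calibration_target_key("pop", "base"))
#' grid_search(ev, list(w = 1:5), tg)$best_params$w  # 3
#' @export
grid_search <- function(evaluator, grid, targets, frozen = list(),
                        combine = "sum") {
  if (length(grid) == 0L || is.null(names(grid)))
    stop("grid must be a non-empty named list of value vectors",
         call. = FALSE)
  overlap <- intersect(names(grid), names(frozen))
  if (length(overlap) > 0L) {
    warning("frozen parameter(s) ", paste(overlap, collapse = ", "),
            " also present in the grid; the frozen values win",
            call. = FALSE)
    grid <- grid[setdiff(names(grid), overlap)]
    if (length(grid) == 0L)
      stop("all grid parameters are frozen; nothing to search",
         call. = FALSE)
  }
  # expand.grid varies the FIRST factor fastest; reverse so the first
  # grid parameter is the most significant (lexicographic order)
  pts <- expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  pts <- pts[, rev(seq_along(pts)), drop = FALSE]
  errors <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    params <- c(as.list(pts[i, , drop = FALSE]), frozen)
    errors[i] <- tryCatch(
      total_objective(evaluator(params), targets, combine = combine),
      error = function(e) Inf)
  }
  trace <- cbind(pts, error = errors)
  best <- which.min(errors)   # first minimum = lexicographic tie-break
  best_params <- c(as.list(pts[best, , drop = FALSE]), frozen)
  list(best_params = best_params, best_error = errors[best], trace = trace)
}
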