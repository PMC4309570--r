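#' 20--80% rise time of an activation trace
#'
#' The time between the first crossings of 20% and 80% of the plateau
#' amplitude (relative to the initial value), with linear interpolation
#' between samples -- the standard summary of how fast a receptor
#' population, or a synaptic current, activates. The plateau is estimated
#' from the final 10% of samples, which must lie within a 5% band of their
#' mean (otherwise the trace has no defined plateau and an error is raised).
#'
#' @param x a `trace_result` (its summed-conductance trace is used) or a
#'   numeric vector of signal values.
#' @param times time grid matching `x` when `x` is a numeric vector.
#' @param ... unused.
#' @return rise time in the units of `times`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.001)
#' rise_time_20_80(1 - exp(-t), t)  # log(4) = 1.386...
rise_time_20_80 <- function(x, ...) UseMethod("rise_time_20_80")

#' @rdname rise_time_20_80
#' @export
rise_time_20_80.trace_result <- function(x, ...) {
  rise_time_20_80(x$conductance, x$times)
}

#' @rdname rise_time_20_80
#' @export
rise_time_20_80.default <- function(x, times, ...) {
  stopifnot(is.numeric(x), length(x) == length(times), length(x) >= 2L)
  tail_n <- max(2L, ceiling(length(x) * 0.1))
  tail_v <- x[seq(length(x) - tail_n + 1L, length(x))]
  plateau <- mean(tail_v)
  amp <- plateau - x[1L]
  if (amp == 0) stop("flat trace: no rise to measure")
  if (any(abs(tail_v - plateau) > 0.05 * abs(amp)))
    stop("trace has not reached a plateau (final 10% of samples vary by ",
         "more than 5% of the amplitude)")
  t20 <- first_crossing(times, x, x[1L] + 0.2 * amp)
  t80 <- first_crossing(times, x, x[1L] + 0.8 * amp)
  if (is.na(t20) || is.na(t80))
    stop("trace never crosses the 20% or 80% level")
  t80 - t20
}

# first time y crosses `level` (towards it), linear interpolation
first_crossing <- function(times, y, level) {
  up <- y[1L] <= level
  hit <- if (up) which(y >= level) else which(y <= level)
  if (!length(hit)) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(times[1L])
  dy <- y[i] - y[i - 1L]
  if (dy == 0) return(times[i])
  times[i - 1L] + (level - y[i - 1L]) / dy * (times[i] - times[i - 1L])
}

#' Time for a state subset to reach a fraction of its steady-state occupancy
#'
#' First time at which the summed occupancy of the given states reaches
#' `fraction` of its steady-state value (linear interpolation between output
#' samples). Used to quantify how fast a conductance state is stabilized at
#' a given agonist concentration.
#'
#' @param trace a `trace_result`.
#' @param states character vector of state labels, or a conformation name
#'   (all its occupancy states are summed).
#' @param fraction target fraction of the steady-state value (default 0.95).
#' @param steady optional precomputed steady-state occupancy vector; by
#'   default [steady_state()] of the trace's scheme.
#' @return time in seconds, or `NA` (with a message attribute) if the level
#'   is not reached within the trace.
#' @export
time_to_fraction_of_steady_state <- function(trace, states, fraction = 0.95,
                                             steady = NULL) {
  stopifnot(inherits(trace, "trace_result"), fraction > 0, fraction <= 1)
  sch <- trace$scheme
  labels <- sch$states$label
  if (all(states %in% sch$model$conformations$name))
    states <- labels[sch$states$conf %in% states]
  if (!all(states %in% labels)) stop("unknown state label(s)")
  if (is.null(steady)) steady <- steady_state(sch)
  occ <- colSums(trace$occupancy[states, , drop = FALSE])
  if (trace$kind == "ssa") occ <- occ / trace$n_receptors
  target <- fraction * sum(steady[states])
  tt <- if (occ[1L] >= target) trace$times[1L]
        else first_crossing(trace$times, occ, target)
  if (is.na(tt)) {
    attr(tt, "message") <- "target level not reached within the trace"
  }
  tt
}
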