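#' Specification for synthetic data generation
#'
#' Describes how to generate synthetic single-channel frequency tables
#' and patch-like conductance traces from a known (ground-truth) allosteric
#' model, so that fitting and simulation can be exercised end-to-end without
#' external recordings. What real deconvolved single-channel data provide is
#' a relative-frequency table of conductance classes per concentration; the
#' generator emulates exactly that by multinomial sampling of `n_events`
#' classified events per concentration from the model's state functions.
#'
#' @param model generating [allosteric_model()].
#' @param concentrations molar grid at which frequencies are sampled.
#' @param n_events events classified per concentration (multinomial sample
#'   size); `Inf` gives the analytic (noise-free) fractions.
#' @param normalization `"all"` or `"conductive"` (which states an
#'   experiment observes: include the basal row or openings only).
#' @param seed mandatory RNG seed.
#' @param trace optional list of patch-trace settings: `n_receptors`, `G`
#'   (molar), `times` (output grid, s), `mode` (scheme construction),
#'   `anchors`, `conductance` (per-conformation weights), `noise_sd`
#'   (additive Gaussian observation noise on the summed conductance).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(model, concentrations, n_events = 500,
                       normalization = c("all", "conductive"), seed,
                       trace = NULL) {
  stopifnot(inherits(model, "allosteric_model"))
  if (missing(seed)) stop("a seed is required")
  normalization <- match.arg(normalization)
  if (!identical(n_events, Inf)) {
    n_events <- as.integer(n_events)
    if (n_events < 1L) stop("n_events must be >= 1")
  }
  structure(list(model = model, concentrations = check_G(concentrations),
                 n_events = n_events, normalization = normalization,
                 seed = as.integer(seed), trace = trace),
            class = "synth_spec")
}

#' Sample a synthetic conductance-state frequency table
#'
#' For each concentration in the spec, draws `n_events` events from the
#' multinomial distribution over states given by the model's state
#' functions, and returns the relative frequencies. With `n_events = Inf`
#' the analytic fractions are returned unchanged. The generating model and
#' spec are attached as attributes for downstream recovery reports.
#'
#' @param spec a [synth_spec()].
#' @return a [frequency_dataset()] with attributes `generating_model`,
#'   `synth_spec`.
#' @export
sample_frequency_table <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sf <- state_fractions(spec$model, spec$concentrations, spec$normalization)
  probs <- sf$fractions
  if (identical(spec$n_events, Inf)) {
    y <- probs
  } else {
    set.seed(spec$seed)
    y <- apply(probs, 2L, function(p)
      as.vector(rmultinom(1L, spec$n_events, p)) / spec$n_events)
    dimnames(y) <- dimnames(probs)
  }
  ds <- frequency_dataset(spec$concentrations, y)
  attr(ds, "generating_model") <- spec$model
  attr(ds, "synth_spec") <- spec
  ds
}

#' Simulate a patch-clamp-like summed conductance trace
#'
#' Wraps [ssa_timecourse()]: builds a kinetic scheme at the requested
#' agonist concentration, simulates a population of receptors, weights the
#' occupancy counts by per-conformation conductances, and optionally adds
#' Gaussian observation noise (emulating amplifier noise on the summed
#' current). The noise-free trace is always returned alongside the noisy
#' one so tests can compare against exact simulation output.
#'
#' @param spec a [synth_spec()] whose `trace` settings are present.
#' @return list with elements `trace` (noisy conductance vector), `clean`
#'   (the underlying `trace_result`), and `seed`.
#' @export
simulate_patch_trace <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  ts <- spec$trace
  if (is.null(ts)) stop("spec has no trace settings")
  ts <- modifyList(list(mode = "thermo_consistent",
                        anchors = ampar_kinetic_anchors(),
                        conductance = c(B = 0, S = 1, M = 2, L = 3),
                        noise_sd = 0), ts)
  if (is.null(ts$n_receptors) || is.null(ts$G) || is.null(ts$times))
    stop("trace settings must include n_receptors, G and times")
  sch <- kinetic_scheme(spec$model, G = ts$G, anchors = ts$anchors,
                        mode = ts$mode, conductance = ts$conductance)
  clean <- ssa_timecourse(sch, ts$n_receptors, ts$times, seed = spec$seed)
  noisy <- clean$conductance
  if (ts$noise_sd > 0)
    noisy <- noisy + rnorm(length(noisy), sd = ts$noise_sd)
  list(trace = noisy, clean = clean, seed = spec$seed)
}

#' Generate-fit-compare recovery experiment
#'
#' Closes the loop on the fitting machinery: generates a frequency table
#' from a known model, fits the thermodynamic model to it, and reports how
#' well the fitted state-function curves reproduce the generating curves.
#' Curve-space error is the maximum absolute deviation between generating
#' and fitted state fractions over the spec's concentration grid extended by
#' one decade on each side -- the quantity that matters for prediction, and
#' the one that remains identifiable when individual (L, K) pairs trade off.
#'
#' @param spec a [synth_spec()].
#' @param fitspec a [fit_spec()].
#' @param template template model for the fit; defaults to the generating
#'   model's structure with its parameter values as the fixed baseline
#'   (free parameters are still re-estimated from random starts).
#' @return list with the `fit` result, `curve_error` (max abs deviation),
#'   `param_log10_dev` (named log10 deviations of fitted vs generating free
#'   parameters), `dataset`, and `seed`.
#' @export
recovery_experiment <- function(spec, fitspec = fit_spec(), template = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  ds <- sample_frequency_table(spec)
  if (is.null(template)) template <- spec$model
  fit <- fit_thermodynamic(ds, template, fitspec, seed = spec$seed,
                           normalization = spec$normalization)
  gr <- range(spec$concentrations)
  grid <- 10^seq(log10(gr[1L]) - 1, log10(gr[2L]) + 1, length.out = 50L)
  gen <- state_fractions(spec$model, grid, spec$normalization)$fractions
  fitted <- state_fractions(fit$model, grid, spec$normalization)$fractions
  dev <- numeric(0)
  for (nm in fit$free) {
    st <- sub("^[LK]_", "", nm)
    i <- match(st, spec$model$conformations$name)
    truth <- if (startsWith(nm, "L_")) spec$model$conformations$L[i]
             else spec$model$conformations$K[i]
    est <- if (startsWith(nm, "L_")) fit$model$conformations$L[i]
           else fit$model$conformations$K[i]
    dev[nm] <- log10(est) - log10(truth)
  }
  list(fit = fit, curve_error = max(abs(fitted - gen)),
       param_log10_dev = dev, dataset = ds, seed = spec$seed)
}
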