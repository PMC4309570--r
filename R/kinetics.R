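#' Off-rate implied by a dissociation constant
#'
#' Per-conformation dissociation constants satisfy K = koff/kon, so with the
#' on-rate fixed the off-rate is K * kon. On-rates for AMPA receptors are
#' taken as identical across conformations; affinity differences are then
#' carried entirely by the off-rates.
#'
#' @param K dissociation constant, molar, > 0.
#' @param kon association rate constant, M^-1 s^-1, > 0.
#' @return off-rate in s^-1.
#' @export
#' @examples
#' koff_from_K(5.407e-5, 5e6)  # 270.35 s^-1
koff_from_K <- function(K, kon) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be positive")
  if (any(!is.finite(kon)) || any(kon <= 0)) stop("kon must be positive")
  K * kon
}

#' Ligand-count scaling of conformational interconversion rates
#'
#' Interconversion rates are anchored at the fully-liganded receptor. Each
#' ligand bound changes the conformational free-energy difference by a
#' factor c (the affinity ratio of the pair); a transition parameter
#' `a` in \[0, 1\] splits that change between speeding the forward rate and
#' slowing the reverse one:
#' forward \eqn{k(i) = k(4)\,c^{a(4-i)}},
#' reverse \eqn{k(i) = k(4)\,c^{-a(4-i)}},
#' where i is the number of bound ligands. `a = 0.5` distributes the free
#' energy evenly; the equilibrium-constant shift per ligand is \eqn{c^{2a}}
#' regardless of the split.
#'
#' @param k4 anchor rate at full occupancy, s^-1.
#' @param c affinity ratio of the conformational pair, > 0.
#' @param n_bound number of bound ligands, 0..n_sites.
#' @param direction `"forward"` (towards the more-active state) or
#'   `"reverse"`.
#' @param a transition parameter in \[0, 1\].
#' @param n_sites number of binding sites (anchor occupancy).
#' @return rate in s^-1.
#' @export
scale_conformational_rate <- function(k4, c, n_bound,
                                      direction = c("forward", "reverse"),
                                      a = 0.5, n_sites = 4L) {
  direction <- match.arg(direction)
  if (any(n_bound < 0 | n_bound > n_sites)) stop("n_bound out of range")
  if (c <= 0) stop("c must be positive")
  s <- if (direction == "forward") 1 else -1
  k4 * c^(s * a * (n_sites - n_bound))
}

#' Build the conformation x occupancy kinetic scheme
#'
#' Expands an allosteric model into a continuous-time Markov chain over all
#' (conformation, bound-ligand count) states -- 20 states for 4 binding
#' conformations of a tetramer -- at a fixed, buffered ligand concentration
#' G. Transitions:
#' \itemize{
#'   \item binding (X, i) -> (X, i+1) at rate (n - i) kon G; unbinding
#'     (X, i) -> (X, i-1) at rate i koff, with koff = K * kon per
#'     conformation (statistical factors give the binomial occupancy of the
#'     equilibrium model);
#'   \item conformational (X, i) <-> (X', i) between adjacent conformations
#'     only, scaled from the fully-liganded anchors by
#'     [scale_conformational_rate()].
#' }
#'
#' Two construction modes are provided. `"as_published"` uses the
#' fully-liganded reverse anchors exactly as supplied. `"thermo_consistent"`
#' keeps the forward anchors but recomputes each reverse anchor so that the
#' zero-ligand conformational equilibrium matches the allosteric constants
#' (\eqn{k_{rev}(0)/k_{fwd}(0) = L_{X'}/L_X}), which together with
#' `a = 0.5` makes the chain satisfy detailed balance with respect to the
#' closed-form MWC distribution.
#'
#' @param model an [allosteric_model()] in which every conformation binds
#'   ligand (has a K).
#' @param G ligand concentration, molar, held constant.
#' @param anchors list as returned by [ampar_kinetic_anchors()].
#' @param mode `"as_published"` or `"thermo_consistent"`.
#' @param a transition parameter.
#' @param conductance named vector of per-conformation conductance weights
#'   (arbitrary units) used for summed-conductance traces.
#' @return object of class `kinetic_scheme`: list with `states`
#'   (`data.frame` of `conf`, `n_bound`, `label`), generator matrix `Q`
#'   (rows = from, columns = to), `G`, `mode`, `a`, rate tables, and the
#'   originating model.
#' @export
kinetic_scheme <- function(model, G, anchors = ampar_kinetic_anchors(),
                           mode = c("as_published", "thermo_consistent"),
                           a = 0.5,
                           conductance = c(B = 0, S = 1, M = 2, L = 3)) {
  stopifnot(inherits(model, "allosteric_model"), length(G) == 1L)
  G <- check_G(G)
  mode <- match.arg(mode)
  cf <- model$conformations
  if (anyNA(cf$K))
    stop("kinetic_scheme requires a dissociation constant for every conformation")
  n <- model$n_sites
  nc <- nrow(cf)
  states <- data.frame(
    conf = rep(cf$name, each = n + 1L),
    n_bound = rep(0:n, nc))
  states$label <- paste0(states$conf, states$n_bound)
  S <- nrow(states)
  kon <- anchors$kon[cf$name]
  if (anyNA(kon)) stop("anchors$kon must name every conformation")
  koff <- koff_from_K(cf$K, kon)
  names(koff) <- cf$name

  k4 <- anchors$k4
  need <- paste0(cf$name[-nc], cf$name[-1L])
  have <- paste0(k4$from, k4$to)
  if (!all(need %in% have))
    stop("missing interconversion anchor for pair(s): ",
         paste(setdiff(need, have), collapse = ", "))
  k4 <- k4[match(need, have), , drop = FALSE]
  cr <- c_ratios(model)$c
  if (mode == "thermo_consistent") {
    # reverse anchor from detailed balance: k_rev(0)/k_fwd(0) = L_to/L_from
    Lr <- cf$L[-1L] / cf$L[-nc]
    k4$rev <- k4$fwd * Lr * cr^(8 * a)
  }

  Q <- matrix(0, S, S, dimnames = list(states$label, states$label))
  idx <- function(conf, i) (match(conf, cf$name) - 1L) * (n + 1L) + i + 1L
  for (j in seq_len(nc)) {
    for (i in 0:n) {
      s <- idx(cf$name[j], i)
      if (i < n) Q[s, idx(cf$name[j], i + 1L)] <- (n - i) * kon[j] * G
      if (i > 0) Q[s, idx(cf$name[j], i - 1L)] <- i * koff[j]
    }
  }
  for (p in seq_len(nc - 1L)) {
    for (i in 0:n) {
      f <- scale_conformational_rate(k4$fwd[p], cr[p], i, "forward", a, n)
      r <- scale_conformational_rate(k4$rev[p], cr[p], i, "reverse", a, n)
      Q[idx(cf$name[p], i), idx(cf$name[p + 1L], i)] <- f
      Q[idx(cf$name[p + 1L], i), idx(cf$name[p], i)] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  cond <- conductance[states$conf]
  if (anyNA(cond)) stop("conductance weights must name every conformation")
  structure(list(states = states, Q = Q, G = G, mode = mode, a = a,
                 kon = kon, koff = koff, k4 = k4, c = cr,
                 conductance = unname(cond), model = model),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme (", x$mode, "): ", nrow(x$states), " states at G = ",
      format(x$G, digits = 4), " M\n", sep = "")
  cat("  conformational anchors (fully liganded, s^-1):\n")
  print(x$k4, row.names = FALSE)
  invisible(x)
}

new_trace <- function(times, occupancy, kind, scheme, n_receptors = NA,
                      seed = NA) {
  conductance <- drop(scheme$conductance %*% occupancy)
  structure(list(times = times, occupancy = occupancy,
                 conductance = conductance, kind = kind,
                 n_receptors = n_receptors, seed = seed, scheme = scheme),
            class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat("Trace (", x$kind, "): ", length(x$times), " time points, ",
      nrow(x$occupancy), " states", sep = "")
  if (!is.na(x$n_receptors)) cat(", ", x$n_receptors, " receptors", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.trace_result <- function(x, which = NULL, ...) {
  occ <- if (is.null(which)) x$occupancy else x$occupancy[which, , drop = FALSE]
  matplot(x$times, t(occ), type = "l", lty = 1, xlab = "time (s)",
          ylab = if (x$kind == "ode") "occupancy fraction" else "receptors", ...)
  legend("right", legend = rownames(occ), lty = 1,
         col = seq_len(nrow(occ)), bty = "n")
  invisible(x)
}

default_p0 <- function(scheme) {
  p0 <- numeric(nrow(scheme$states))
  names(p0) <- scheme$states$label
  p0[scheme$states$conf == scheme$model$conformations$name[1L] &
       scheme$states$n_bound == 0L] <- 1
  p0
}

#' Deterministic time course of the master equation
#'
#' Integrates dp/dt = Q' p for the scheme's generator Q with a stiff-capable
#' solver (the rates span ~1 to 3e5 s^-1). Occupancies are renormalized
#' checks only -- probability conservation is asserted at 1e-8.
#'
#' @param scheme a [kinetic_scheme()].
#' @param times increasing output time grid in seconds (first element is the
#'   initial time).
#' @param p0 initial occupancy vector over the scheme's states (sums to 1);
#'   default: all receptors in the unliganded reference state.
#' @param rtol,atol solver tolerances.
#' @return a `trace_result` with fractional occupancies (states x times) and
#'   the summed-conductance trace.
#' @export
ode_timecourse <- function(scheme, times, p0 = NULL,
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (is.null(p0)) p0 <- default_p0(scheme)
  if (abs(sum(p0) - 1) > 1e-8) stop("initial occupancy must sum to 1")
  S <- nrow(scheme$states)
  if (length(times) == 1L) {
    occ <- matrix(p0, S, 1, dimnames = list(scheme$states$label, NULL))
    return(new_trace(times, occ, "ode", scheme))
  }
  QT <- t(scheme$Q)
  sol <- deSolve::ode(
    y = p0, times = times,
    func = function(t, y, parms) list(as.vector(QT %*% y)),
    jacfunc = function(t, y, parms) QT, jactype = "fullusr",
    method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("master-equation integration failed; solver diagnostics: ",
         paste(attr(sol, "istate"), collapse = " "))
  occ <- t(unclass(sol)[, -1L, drop = FALSE])
  rownames(occ) <- scheme$states$label
  bad <- abs(colSums(occ) - 1) > 1e-8
  if (any(bad))
    stop("probability not conserved at ", sum(bad), " output times")
  new_trace(times, occ, "ode", scheme)
}

#' Exact stochastic simulation of a receptor population
#'
#' Gillespie (direct-method) simulation of N independent receptors governed
#' by the scheme's generator. Receptors are simulated one at a time (their
#' independence makes this statistically identical to a population-level
#' SSA) in compiled code; state occupancy counts are recorded on a fixed
#' output grid.
#'
#' @param scheme a [kinetic_scheme()].
#' @param n_receptors population size N >= 1.
#' @param times increasing output grid (seconds) starting at the initial
#'   time.
#' @param seed integer RNG seed (mandatory: the result is stochastic).
#' @param init integer vector of initial state indices (length N or 1);
#'   default: all receptors in the unliganded reference state.
#' @param record_paths if `TRUE`, also return each receptor's jump
#'   trajectory (use only for small N).
#' @return a `trace_result` with integer occupancy counts (states x times,
#'   columns summing to N), the summed-conductance trace, and -- when
#'   `record_paths` -- a `paths` element (list of per-receptor `time`/`state`
#'   vectors).
#' @export
ssa_timecourse <- function(scheme, n_receptors, times, seed, init = NULL,
                           record_paths = FALSE) {
  stopifnot(inherits(scheme, "kinetic_scheme"), n_receptors >= 1)
  if (missing(seed)) stop("a seed is required for stochastic simulation")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (is.null(init)) {
    ref <- which(scheme$states$conf == scheme$model$conformations$name[1L] &
                   scheme$states$n_bound == 0L)
    init <- rep(ref, n_receptors)
  } else {
    init <- rep_len(as.integer(init), n_receptors)
    if (any(init < 1L | init > nrow(scheme$states)))
      stop("init contains invalid state indices")
  }
  set.seed(seed)
  res <- ssa_population(scheme$Q, init, times, record_paths, 100000L)
  occ <- res$counts
  dimnames(occ) <- list(scheme$states$label, NULL)
  tr <- new_trace(times, occ, "ssa", scheme, n_receptors, seed)
  if (record_paths) tr$paths <- res$paths
  tr
}

#' Stationary distribution of a kinetic scheme
#'
#' Solves Q'p = 0 with the normalization constraint sum(p) = 1. For
#' `thermo_consistent` schemes this equals the closed-form MWC equilibrium
#' distribution over (conformation, occupancy) states.
#'
#' @param scheme a [kinetic_scheme()].
#' @return named occupancy vector summing to 1.
#' @export
steady_state <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  S <- nrow(scheme$states)
  A <- rbind(t(scheme$Q), rep(1, S))
  p <- qr.solve(A, c(rep(0, S), 1))
  if (min(p) < -1e-8)
    stop("no valid stationary distribution (chain may be reducible); ",
         "most negative component: ", format(min(p)))
  p <- pmax(p, 0)
  setNames(p / sum(p), scheme$states$label)
}

#' Marginal occupancy per conformation
#'
#' Collapses a state-level occupancy vector or trace over ligand counts,
#' giving the total occupancy of each conformation.
#'
#' @param scheme a [kinetic_scheme()].
#' @param occupancy vector over states (e.g. from [steady_state()]) or a
#'   states x times matrix.
#' @return named vector (or conformations x times matrix).
#' @export
conformation_marginals <- function(scheme, occupancy) {
  confs <- scheme$model$conformations$name
  grp <- factor(scheme$states$conf, levels = confs)
  if (is.matrix(occupancy)) {
    out <- apply(occupancy, 2L, function(p) tapply(p, grp, sum))
    rownames(out) <- confs
    out
  } else {
    setNames(as.numeric(tapply(occupancy, grp, sum)[confs]), confs)
  }
}
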