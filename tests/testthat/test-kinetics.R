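glu_scheme <- function(G, mode = "thermo_consistent") {
  kinetic_scheme(ampar_model("GluA3_GluK2"), G = G, mode = mode)
}

test_that("off-rates derive from dissociation constants as K * kon", {
  expect_equal(koff_from_K(3.330e-6, 5e6), 16.65)
  expect_equal(koff_from_K(5.407e-5, 5e6), 270.35)
  expect_identical(koff_from_K(1, 1), 1)
  expect_error(koff_from_K(-1, 5e6), "positive")
  expect_error(koff_from_K(1e-4, 0), "positive")
})

test_that("conformational rates scale with ligand count via c^a", {
  # fully-liganded anchor is returned unchanged
  expect_equal(scale_conformational_rate(3e5, 0.0601, 4, "forward"), 3e5)
  # each missing ligand multiplies forward rates by c^a, divides reverse
  expect_equal(scale_conformational_rate(3e5, 0.0601, 0, "forward"),
               3e5 * 0.0601^2)
  expect_equal(scale_conformational_rate(860, 0.0601, 0, "reverse"),
               860 / 0.0601^2)
  # a = 0 disables the scaling entirely
  expect_equal(scale_conformational_rate(3e5, 0.0601, 1, "forward", a = 0),
               3e5)
  # each ligand removed shifts the equilibrium constant by c^(2a),
  # however a splits the free energy between the two directions
  for (a in c(0.25, 0.5, 0.75)) {
    k_eq <- function(i) {
      scale_conformational_rate(2e4, 0.0616, i, "forward", a) /
        scale_conformational_rate(145, 0.0616, i, "reverse", a)
    }
    expect_equal(k_eq(2) / k_eq(3), 0.0616^(2 * a), tolerance = 1e-12)
  }
  expect_error(scale_conformational_rate(1, 0.5, 5), "out of range")
})

test_that("scheme construction gives the 20-state chain topology", {
  sch <- glu_scheme(1e-3, "as_published")
  expect_equal(nrow(sch$states), 20L)
  expect_equal(dim(sch$Q), c(20L, 20L))
  expect_equal(rowSums(sch$Q), rep(0, 20), tolerance = 1e-8,
               ignore_attr = TRUE)
  # binding propensities carry the statistical factor (n - i) kon G
  expect_equal(sch$Q["B0", "B1"], 4 * 5e6 * 1e-3)
  expect_equal(sch$Q["B3", "B4"], 1 * 5e6 * 1e-3)
  expect_equal(sch$Q["L2", "L1"], 2 * koff_from_K(2.298e-7, 5e6))
  # only adjacent conformations are connected (no B <-> M shortcuts)
  expect_identical(unname(sch$Q["B0", "M0"]), 0)
  expect_identical(unname(sch$Q["S1", "L1"]), 0)
  # as_published keeps the printed fully-liganded reverse anchors
  expect_equal(sch$Q["S4", "B4"], 860)
  expect_equal(sch$Q["L4", "M4"], 691)
  bad <- ampar_kinetic_anchors()
  bad$k4 <- bad$k4[-2, ]
  expect_error(kinetic_scheme(ampar_model("GluA3_GluK2"), 1e-3,
                              anchors = bad), "missing interconversion")
  expect_error(kinetic_scheme(ampar_model("native"), 1e-3),
               "every conformation")
})

test_that("thermo-consistent schemes hit the zero-ligand equilibria", {
  sch <- glu_scheme(1e-6)
  cf <- sch$model$conformations
  # k_rev(0) / k_fwd(0) between adjacent pairs equals the L ratio
  pairs <- list(c("B0", "S0"), c("S0", "M0"), c("M0", "L0"))
  for (p in seq_along(pairs)) {
    ratio <- sch$Q[pairs[[p]][2], pairs[[p]][1]] /
      sch$Q[pairs[[p]][1], pairs[[p]][2]]
    expect_equal(ratio, cf$L[p + 1] / cf$L[p], tolerance = 1e-12)
  }
})

test_that("binding/conformation cycles shift equilibria by 1/c per ligand", {
  for (mode in c("as_published", "thermo_consistent")) {
    sch <- glu_scheme(1e-4, mode)
    cf <- sch$model$conformations
    cr <- c_ratios(sch$model)$c
    for (p in 1:3) {
      from <- cf$name[p]; to <- cf$name[p + 1]
      for (i in 0:3) {
        keq <- function(ii) {
          sch$Q[paste0(from, ii), paste0(to, ii)] /
            sch$Q[paste0(to, ii), paste0(from, ii)]
        }
        expect_equal(keq(i + 1) / keq(i), 1 / cr[p], tolerance = 1e-10)
      }
    }
  }
})

test_that("thermo-consistent mode satisfies detailed balance", {
  sch <- glu_scheme(2e-5)
  p <- mwc_state_occupancy(sch)
  for (i in 1:20) {
    for (j in 1:20) {
      if (i < j && sch$Q[i, j] > 0) {
        expect_equal(p[i] * sch$Q[i, j], p[j] * sch$Q[j, i],
                     tolerance = 1e-10, ignore_attr = TRUE)
      }
    }
  }
})

test_that("the master equation conserves probability and finds equilibria", {
  # zero ligand: relaxation to the Boltzmann distribution over i = 0 states
  sch0 <- glu_scheme(0)
  tr0 <- ode_timecourse(sch0, c(0, 10^seq(-6, 0, length.out = 50)))
  expect_equal(colSums(tr0$occupancy), rep(1, 51), tolerance = 1e-8,
               ignore_attr = TRUE)
  cf <- sch0$model$conformations
  want <- (1 / cf$L) / sum(1 / cf$L)
  got <- conformation_marginals(sch0, tr0$occupancy[, 51])
  expect_equal(unname(got), want, tolerance = 1e-6)
  # a single output time returns the initial occupancy untouched
  tr1 <- ode_timecourse(sch0, 0)
  expect_equal(unname(tr1$occupancy[, 1]), ampaMWC:::default_p0(sch0),
               ignore_attr = TRUE)
})

test_that("stationary distribution equals the closed-form MWC equilibrium", {
  for (G in c(1e-6, 1e-4, 1e-3)) {
    sch <- glu_scheme(G)
    ss <- steady_state(sch)
    expect_equal(ss, mwc_state_occupancy(sch), tolerance = 1e-8)
    marg <- conformation_marginals(sch, ss)
    sf <- state_fractions(sch$model, G)$fractions[, 1]
    expect_equal(unname(marg), unname(sf), tolerance = 1e-8)
  }
})

test_that("large-state stabilization at 1 mM is sub-millisecond", {
  sch <- glu_scheme(1e-3, "as_published")
  tr <- ode_timecourse(sch, c(0, 10^seq(-7, -2, length.out = 300)))
  t95 <- time_to_fraction_of_steady_state(tr, "L", 0.95)
  expect_lt(t95, 1e-3)
  expect_gt(t95, 0)
})

test_that("stabilization accelerates with agonist concentration", {
  # three log-even concentrations spanning 1 uM - 1 mM, thermo-consistent
  # scheme (the mode whose kinetics follow the thermodynamic model)
  t95 <- vapply(10^c(-6, -4.5, -3), function(G) {
    sch <- glu_scheme(G)
    tr <- ode_timecourse(sch, c(0, 10^seq(-7, 1, length.out = 400)))
    time_to_fraction_of_steady_state(tr, "L", 0.95)
  }, numeric(1))
  expect_true(all(diff(t95) < 0))
})

test_that("SSA conserves counts, is seed-reproducible, reaches L4", {
  sch <- glu_scheme(1e-3)
  times <- seq(0, 5e-3, by = 1e-4)
  tr1 <- ssa_timecourse(sch, 50, times, seed = 21)
  tr2 <- ssa_timecourse(sch, 50, times, seed = 21)
  expect_identical(tr1$occupancy, tr2$occupancy)
  expect_equal(colSums(tr1$occupancy), rep(50, length(times)),
               ignore_attr = TRUE)
  # a single receptor started at (B,0) reaches the fully liganded large
  # state (one stochastic path among many; reachability is the contract)
  tr3 <- ssa_timecourse(sch, 1, c(0, 5e-3), seed = 2, record_paths = TRUE)
  path <- tr3$paths[[1]]
  expect_equal(path$state[1], which(sch$states$label == "B0"))
  expect_true(which(sch$states$label == "L4") %in% path$state)
})

test_that("mean SSA occupancy tracks the master-equation solution", {
  sch <- glu_scheme(1e-3)
  times <- c(0, 2e-4, 5e-4, 1e-3, 2e-3)
  ode <- ode_timecourse(sch, times)
  ode_L <- conformation_marginals(sch, ode$occupancy)["L", ]
  fracs <- vapply(1:20, function(s) {
    tr <- ssa_timecourse(sch, 500, times, seed = 100 + s)
    conformation_marginals(sch, tr$occupancy)["L", ] / 500
  }, numeric(length(times)))
  m <- rowMeans(fracs)
  se <- apply(fracs, 1, sd) / sqrt(20)
  expect_true(all(abs(m - ode_L) <= 3 * se + 1e-12))
})

test_that("rise-time and time-to-steady statistics match closed forms", {
  t <- seq(0, 20, by = 0.002)
  tau <- 1.3
  y <- 1 - exp(-t / tau)
  expect_equal(rise_time_20_80(y, t), tau * log(0.8 / 0.2), tolerance = 1e-3)
  # a sampled step cannot resolve a rise time beyond one sample interval
  ys <- rep(c(0, 1), each = 500)
  ts <- seq_along(ys) * 1e-3
  expect_lt(rise_time_20_80(ys, ts), 1e-3)
  # a ramp has no plateau
  expect_error(rise_time_20_80(t, t), "plateau")
  # single-exponential approach to steady state crosses f at -tau log(1-f)
  sch <- glu_scheme(1e-3)
  ss <- steady_state(sch)
  trace <- structure(list(
    times = t, occupancy = matrix(ss %o% (1 - exp(-t / tau)), 20,
                                  dimnames = list(names(ss), NULL)),
    conductance = numeric(length(t)), kind = "ode", n_receptors = NA,
    seed = NA, scheme = sch), class = "trace_result")
  expect_equal(time_to_fraction_of_steady_state(trace, "L", 0.95, ss),
               -tau * log(0.05), tolerance = 1e-3)
  # already at steady state: crossing at time zero
  trace0 <- trace
  trace0$occupancy <- matrix(rep(ss, length(t)), 20,
                             dimnames = list(names(ss), NULL))
  expect_equal(time_to_fraction_of_steady_state(trace0, "L", 0.95, ss), 0)
  # never reached: NA, not an error
  short <- trace
  short$times <- t[1:5]; short$occupancy <- trace$occupancy[, 1:5]
  out <- time_to_fraction_of_steady_state(short, "L", 0.95, ss)
  expect_true(is.na(out))
})
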