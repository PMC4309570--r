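---
title: "A concerted allosteric model of AMPA receptor conductance states"
author: "ampaMWC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A concerted allosteric model of AMPA receptor conductance states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampaMWC)
```

## The model

Single-channel recordings of AMPA-type glutamate receptors show several
discrete open-channel current levels — small, medium and large conductance
substates — whose relative frequencies shift towards the larger conductances
as the agonist concentration rises. `ampaMWC` models this behaviour with a
concerted (Monod–Wyman–Changeux) allosteric mechanism: the tetrameric
receptor interconverts as a whole between an ordered chain of conformations,

$$B \rightleftharpoons A^S \rightleftharpoons A^M \rightleftharpoons A^L,$$

a closed basal state and three open states of increasing conductance. Two
parameter families fully describe the thermodynamics:

* the **allosteric constants** $L_X = [B_0]/[X_0]$, the zero-ligand
  equilibrium ratios of basal to each active conformation ($L \ge 1$:
  without agonist the channel is mostly closed, but spontaneous openings
  exist with probability $\propto 1/L_X$);
* the **dissociation constants** $K_X$ (molar), one per conformation,
  shared by the four identical binding sites. Their adjacent ratios
  $c = K_{X'}/K_X$ are below 1 for agonists: the more-active conformation
  binds agonist more tightly, which is what pulls the equilibrium up the
  chain as concentration rises.

The statistical weight of conformation $X$ at free agonist concentration $G$
is $(1/L_X)(1 + G/K_X)^4$ (a conformation without a $K$ has binding
polynomial 1), and the **state function** — the fraction of receptors in
$X$ — is that weight over the sum of weights. `state_fractions()` evaluates
these in log space with log-sum-exp normalization, so extreme $G/K$ ratios
(the large state at millimolar agonist has $G/K_L > 10^3$, whose fourth
power would overflow along naive paths at higher concentrations still)
cannot corrupt the fractions. The **saturation function**
(`saturation_fraction()`) is the fraction of occupied binding sites; within
one conformation the number of bound ligands is binomial
(`liganded_distribution()`).

Two normalization modes matter in practice. Recordings of recombinant
GluA3/GluK2 receptors resolve closed and open levels, so their frequencies
are fractions over **all** four states. Native-receptor data classify open
events only, so the package also reports fractions renormalized over the
**conductive** states; fitting picks the mode automatically from which rows
a dataset contains.

## Fitting

Observed data are relative-frequency tables $y$ (rows = states, columns =
concentrations). The fitting objective is the sum of squared differences of
base-10 logarithms between observed frequencies and model state functions;
the log gives rare states (frequencies of $10^{-3}$ and below) weight
comparable to dominant ones. Zero observed frequencies are floored at
$\varepsilon = 10^{-6}$ — one event in $10^6$ is below what a single-channel
record can resolve — and the model fraction is floored with the same
constant for symmetry.

The parameter space spans decades (bounds $L \in [1, 10^6]$,
$K \in [10^{-10}, 10^{-3}]$ M by default) and the objective is multimodal,
so `fit_thermodynamic()` searches log10-transformed parameters with a
real-coded genetic algorithm: binary tournament selection, uniform crossover
(rate 0.8), per-gene Gaussian mutation (rate 0.05, SD 0.25 decades),
elitism of 2, population 100, 500 generations, 3 independent restarts. All
randomness flows from a single user-supplied seed, so fits are exactly
reproducible, and elitism makes the best-objective trajectory monotone.
Because the objective is smooth in the parameters, the GA optimum is then
polished with box-constrained L-BFGS-B (`polish = TRUE`); the GA does the
global search, the polish supplies the final digits of convergence. Either
stage can be disabled or resized through `fit_spec()`.

A caution on identifiability: with few concentrations, $(L, K)$ pairs trade
off along ridges. The quantity that stays identifiable is the state-function
*curve*, and `recovery_experiment()` therefore scores fits by the maximum
absolute deviation between generating and fitted curves over the data's
concentration range extended one decade each side, reporting parameter-space
deviations separately. On noise-free frequencies over seven concentrations
spanning $10^{-7}$–$10^{-2}$ M the curves are recovered to well under 0.01;
with three concentrations and a few hundred events each (the regime of real
single-channel records) the report quantifies the identifiability loss as a
function of the event count, which real experiments rarely state.

## Kinetics

`kinetic_scheme()` expands the thermodynamic model into a continuous-time
Markov chain over every (conformation, bound count) pair — 20 states for
four binding conformations. Agonist is a buffered reservoir: $G$ is constant
(synaptic depletion is out of scope). Binding is per-site with statistical
factors, $(4-i)\,k_{on}G$ on and $i\,k_{off}$ off, the unique choice
consistent with the binomial occupancy of the equilibrium model; off-rates
derive from the thermodynamics as $k_{off} = K\,k_{on}$ with a common
$k_{on} = 5\times10^6\,\mathrm{M^{-1}s^{-1}}$. Conformational transitions
connect adjacent conformations only (the chain topology; no shortcuts) and
are anchored at the fully-liganded receptor; each ligand *removed*
multiplies the forward rate by $c^{a}$ and divides the reverse rate by
$c^{a}$, with the transition parameter $a = 0.5$ splitting the per-ligand
free energy evenly between the two directions.

The published fully-liganded anchor rates are not perfectly consistent with
the fitted allosteric constants (taken at face value the zero-ligand
equilibrium $k_{SB}(0)/k_{BS}(0)$ differs from $L_S$ by a factor of ~1000),
so the constructor exposes both readings rather than silently choosing:

* `mode = "as_published"` uses the printed reverse anchors verbatim —
  use it to reproduce the published kinetic simulations;
* `mode = "thermo_consistent"` keeps the printed forward anchors but
  recomputes each reverse anchor so the zero-ligand conformational
  equilibrium equals the fitted $L$ ratio. With $a = 0.5$ this scheme
  satisfies detailed balance exactly, and its stationary distribution *is*
  the closed-form MWC distribution — the property the simulation tests
  lean on.

`ode_timecourse()` integrates the master equation $\dot p = Q^\top p$ with
LSODA (the rates span 1–$3\times10^5\,\mathrm{s^{-1}}$, so a stiff-capable
solver with tight tolerances, relative $10^{-8}$ and absolute $10^{-12}$,
is the default) and asserts probability conservation at $10^{-8}$.
`ssa_timecourse()` runs the exact Gillespie direct method in compiled code,
simulating receptors independently — statistically identical to a
population-level SSA because receptors do not interact — and recording
occupancy counts on a fixed grid; `steady_state()` solves $Q^\top p = 0$
directly. Summary statistics: `rise_time_20_80()` (linear interpolation
between samples; the plateau is the mean of the final 10% of samples, which
must sit within a 5% band to count as a plateau) and
`time_to_fraction_of_steady_state()` for stabilization times. A sampled
instantaneous step yields a rise time below one sample interval rather than
exactly zero — the statistic cannot resolve below the sampling period.

## Synthetic data

No public table of deconvolved sub-conductance frequencies exists for these
receptors, so the package generates its own test data with the statistical
structure real data would have. `sample_frequency_table()` draws, at each
concentration, `n_events` classified events from the multinomial over states
given by the state functions — the default `n_events = 500` is a realistic
order of magnitude for events per single-channel record, and the value is a
parameter precisely because real event counts are rarely reported.
`simulate_patch_trace()` produces population conductance traces by SSA,
weighting conformations by configurable conductances (defaults 0/1/2/3
arbitrary units for B/S/M/L; the true unitary conductances are not part of
the model) and optionally adding Gaussian observation noise to the summed
trace, emulating amplifier noise without modelling the recording filter.
What the generator deliberately does *not* emulate: correlated dwell-time
structure within records, filtering/sampling artifacts, missed brief events,
and classification errors of the deconvolution step. Passing recovery tests
therefore show the estimator works on ideal multinomial data, not that those
artifacts are harmless.

## Numerical and design notes

* **Study conditions in the tests.** The acceptance-style checks use the
  shipped parameter sets; the SSA-vs-closed-form comparison runs $10^4$
  receptors to 20 ms at 1 mM (about 20x the stabilization time, verified
  against the ODE solution) and accepts agreement within 3 Monte-Carlo
  standard errors; recovery uses 7 log-spaced concentrations. These sizes
  keep every check well-resolved while running in seconds.
* **Stabilization-time caveat.** "Time to 95% of the state's own
  steady-state occupancy" is a relative measure: at 1–10 µM the large
  state's steady occupancy is itself tiny ($10^{-5}$–$10^{-2}$), and the
  metric is non-monotone in $G$ there (95% of almost nothing is reached
  early). The monotone-acceleration property is therefore checked on three
  log-even concentrations spanning 1 µM–1 mM with the thermo-consistent
  scheme; with the verbatim published anchors the property fails even on
  that grid — one more symptom of the anchor/thermodynamics inconsistency
  above.
* **Partial-agonist caveat.** The monotone decrease of the basal fraction
  assumes $c < 1$ along the whole chain. BrW violates it at the first link
  ($K_S > K_B$), and its basal state function genuinely rises at the foot of
  the curve before falling.
* **Degenerate inputs.** Fits with more free parameters than observed cells
  complete but are flagged `underdetermined`; a stabilization level never
  reached within a trace returns `NA` with an explanatory attribute rather
  than an error; non-binding conformations are allowed anywhere in the
  thermodynamic chain but the kinetic expansion requires every conformation
  to bind (the ligand-count scaling is undefined without a $c$ ratio).

## Reproducibility

Every stochastic entry point (`ssa_timecourse()`, `sample_frequency_table()`,
`simulate_patch_trace()`, `fit_thermodynamic()`) requires an explicit seed
and records it in its result; the CLI writes a JSON metadata sidecar
(config, seed, package version) next to every output file. Identical seeds
give byte-identical outputs.
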