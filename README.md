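# ampaMWC

Concerted allosteric modelling of AMPA receptor conductance states.

AMPA-type glutamate receptors open to several discrete single-channel
conductance levels — small, medium and large substates — and the relative
frequency of those levels shifts towards higher conductances as the agonist
concentration rises. `ampaMWC` treats this as a concerted
(Monod–Wyman–Changeux) allosteric transition of the tetramer along an
ordered chain of conformations,

    B  ⇌  A_S  ⇌  A_M  ⇌  A_L ,

each conformation X carrying an allosteric constant `L_X = [B_0]/[X_0]`
(spontaneous-opening penalty) and a dissociation constant `K_X` shared by
its four binding sites. The fraction of receptors in conformation X at
agonist concentration G is

    f_X(G) = (1/L_X)(1 + G/K_X)^4  /  Σ_Y (1/L_Y)(1 + G/K_Y)^4 ,

and increasing affinity along the chain (`c = K_X'/K_X < 1` for agonists)
is what drives receptors up the conductance ladder with concentration.

The package is aimed at ion-channel biophysicists and modellers who want to

* evaluate the closed-form state, saturation and occupancy functions for
  receptor parameter sets (four ship with the package: native cerebellar
  receptors, recombinant GluA3/GluK2, and the partial willardiine agonists
  IW and BrW);
* fit the allosteric and dissociation constants to conductance-state
  frequency tables with a seeded genetic algorithm minimizing a log10
  least-squares objective;
* expand the thermodynamic model into the 20-state (conformation × ligand
  count) kinetic scheme and simulate receptor populations deterministically
  (stiff master-equation integration) or stochastically (compiled Gillespie
  SSA), with summary statistics such as the 20–80% rise time and
  stabilization times;
* generate synthetic frequency tables and patch-like conductance traces
  from known parameters, so the whole pipeline is testable without any
  external recording.

## Worked example

```r
library(ampaMWC)

m <- ampar_model("GluA3_GluK2")
state_fractions(m, c(1e-6, 1e-3))
#> State fractions (all normalization), model: GluA3_GluK2
#>    1e-06  0.001
#> B 0.7204 0.0000
#> S 0.2692 0.0001
#> M 0.0099 0.0996
#> L 0.0006 0.9003
```

At 1 µM quisqualate ~72% of receptors are closed (basal) and ~27% sit in the
small conductance state; at 1 mM the large state holds 90% of the population
and the medium state 10% — the concentration-dependent conductance shift the
model exists to explain.

Generate a synthetic dataset from the model, fit it back, and simulate the
activation kinetics:

```r
ds <- sample_frequency_table(
  synth_spec(m, c(1e-6, 2e-6, 6e-6), n_events = 500, seed = 42))
fit <- fit_thermodynamic(ds, m,
  fit_spec(pop_size = 60, generations = 120, n_starts = 2), seed = 42)
fit
#> Thermodynamic fit (seed 42)
#>   objective: 5.62467  Pearson r: 0.9579
#> Concerted allosteric model: GluA3_GluK2 (fitted)
#>   binding sites: 4
#>  name            L         K
#>     B 1.000000e+00 1.000e-03
#>     S 2.332236e+00 1.000e-03
#>     M 2.632701e+02 3.412e-06
#>     L 1.000000e+06 3.946e-07

sch <- kinetic_scheme(m, G = 1e-3, mode = "as_published")
tr  <- ode_timecourse(sch, c(0, 10^seq(-7, -2, length.out = 400)))
1e3 * time_to_fraction_of_steady_state(tr, "L")   # ms
#> [1] 0.987
```

The fitted curves correlate with the noisy observations at r = 0.96 even
though three concentrations cannot pin every parameter individually (see the
identifiability discussion in the vignette), and the large conductance state
reaches 95% of its steady-state occupancy in under 1 ms at 1 mM agonist —
within the rise phase of a synaptic current.

A command-line wrapper with subcommands `statefunc | fit | simulate | synth |
recover` lives at `inst/cli/ampamwc` (see `?ampar_cli`); every output file
gets a JSON metadata sidecar recording config, seed and package version.

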