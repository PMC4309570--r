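#' Built-in AMPA receptor parameter sets
#'
#' Thermodynamic parameter sets for the four receptor/agonist systems the
#' package models:
#' \describe{
#'   \item{`"GluA3_GluK2"`}{recombinant GluA3flip/GluK2 chimeric receptors
#'     stimulated with quisqualate (full agonist); all four conformations
#'     bind ligand.}
#'   \item{`"native"`}{native cerebellar granule-cell receptors stimulated
#'     with glutamate; the basal conformation carries no dissociation
#'     constant (fits of these data constrain only the conductive states).}
#'   \item{`"IW"`, `"BrW"`}{GluR2 homomeric receptors stimulated with the
#'     partial agonists iodo- and bromo-willardiine; allosteric constants are
#'     shared with the GluA3/GluK2 set and only the dissociation constants
#'     differ.}
#' }
#'
#' @param which one of `"GluA3_GluK2"`, `"native"`, `"IW"`, `"BrW"`.
#' @return an [allosteric_model()].
#' @export
#' @examples
#' m <- ampar_model("GluA3_GluK2")
#' c_ratios(m)
ampar_model <- function(which = c("GluA3_GluK2", "native", "IW", "BrW")) {
  which <- match.arg(which)
  tab <- switch(which,
    GluA3_GluK2 = data.frame(
      name = c("B", "S", "M", "L"),
      L = c(1, 2.867, 207.5, 1e6),
      K = c(9e-4, 5.407e-5, 3.330e-6, 2.298e-7)),
    native = data.frame(
      name = c("B", "S", "M", "L"),
      L = c(1, 20.387, 28.898, 1066.73),
      K = c(NA, 1e-3, 3.7e-4, 1e-4)),
    IW = data.frame(
      name = c("B", "S", "M", "L"),
      L = c(1, 2.867, 207.5, 1e6),
      K = c(9e-4, 1e-3, 8.580e-5, 1.198e-5)),
    BrW = data.frame(
      name = c("B", "S", "M", "L"),
      L = c(1, 2.867, 207.5, 1e6),
      K = c(9e-4, 4e-3, 4.97e-5, 5.02e-6)))
  allosteric_model(tab, n_sites = 4L, name = which)
}

#' Kinetic anchors for the AMPA receptor scheme
#'
#' Ligand binding on-rates (identical for all conformations; affinity
#' differences therefore live entirely in the off-rates, which
#' [kinetic_scheme()] derives as K * kon) and the fully-liganded
#' conformational interconversion rates between adjacent states.
#'
#' @return list with elements `kon` (named vector, M^-1 s^-1) and `k4`
#'   (`data.frame` with columns `from`, `to`, `fwd`, `rev`, s^-1; rates are
#'   anchored at the fully-liganded receptor).
#' @export
ampar_kinetic_anchors <- function() {
  list(
    kon = c(B = 5e6, S = 5e6, M = 5e6, L = 5e6),
    k4 = data.frame(
      from = c("B", "S", "M"),
      to   = c("S", "M", "L"),
      fwd  = c(3e5, 2e4, 5e4),
      rev  = c(860, 145, 691)))
}
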