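#' Construct a concerted allosteric receptor model
#'
#' Defines a Monod-Wyman-Changeux (MWC) model of a multimeric receptor that
#' interconverts, in concert, between an ordered chain of conformations
#' (for AMPA receptors: basal B and the small, medium and large conductance
#' states S, M, L). Each conformation carries an allosteric constant
#' \eqn{L = [B_0]/[X_0]} (the zero-ligand equilibrium ratio of the reference
#' conformation to conformation X; L = 1 for the reference itself) and,
#' optionally, a microscopic dissociation constant K (molar) shared by all
#' binding sites in that conformation. A conformation without a K does not
#' bind ligand: its binding polynomial is identically 1.
#'
#' @param conformations a `data.frame` with columns `name` (character),
#'   `L` (numeric, >= 1, exactly 1 for the first row) and `K` (numeric,
#'   molar, `NA` for a non-binding conformation). Row order defines the
#'   conformational chain used by the kinetic scheme.
#' @param n_sites integer number of ligand binding sites (4 for the
#'   tetrameric AMPA receptor).
#' @param name free-text label for the model.
#' @return an object of class `allosteric_model`.
#' @seealso [ampar_model()] for the built-in receptor parameter sets,
#'   [state_fractions()], [saturation_fraction()].
#' @export
#' @examples
#' m <- allosteric_model(data.frame(
#'   name = c("B", "S", "M", "L"),
#'   L = c(1, 2.867, 207.5, 1e6),
#'   K = c(9e-4, 5.407e-5, 3.330e-6, 2.298e-7)))
#' state_fractions(m, c(1e-6, 1e-3))
allosteric_model <- function(conformations, n_sites = 4L, name = "receptor") {
  stopifnot(is.data.frame(conformations),
            all(c("name", "L", "K") %in% names(conformations)))
  conformations <- conformations[, c("name", "L", "K")]
  conformations$name <- as.character(conformations$name)
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) stop("n_sites must be a positive integer")
  if (nrow(conformations) < 1L) stop("at least one conformation is required")
  if (anyDuplicated(conformations$name))
    stop("conformation names must be unique")
  if (!is.numeric(conformations$L) || any(!is.finite(conformations$L)) ||
      any(conformations$L <= 0))
    stop("all allosteric constants L must be finite and positive")
  if (conformations$L[1L] != 1)
    stop("the first conformation is the reference and must have L = 1")
  if (sum(conformations$L == 1) != 1L)
    stop("exactly one conformation (the reference) may have L = 1")
  K <- conformations$K
  if (any(!is.na(K) & K <= 0)) stop("dissociation constants K must be > 0")
  structure(
    list(name = name, n_sites = n_sites, conformations = conformations),
    class = "allosteric_model")
}

#' @export
print.allosteric_model <- function(x, ...) {
  cat("Concerted allosteric model:", x$name, "\n")
  cat("  binding sites:", x$n_sites, "\n")
  tab <- x$conformations
  tab$K <- ifelse(is.na(tab$K), "(non-binding)", format(tab$K, digits = 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

# log of the partition-function weight of one conformation:
# log[(1/L) (1 + G/K)^n]; non-binding conformations contribute log(1/L).
conf_log_weight <- function(L, K, n, G) {
  if (is.na(K)) rep(-log(L), length(G)) else -log(L) + n * log1p(G / K)
}

check_G <- function(G) {
  if (length(G) == 0L) stop("concentration grid must be non-empty")
  if (!is.numeric(G) || any(!is.finite(G)) || any(G < 0))
    stop("ligand concentrations must be finite, non-negative molar values")
  as.numeric(G)
}

#' Partition-function weight of one conformation
#'
#' The unnormalized statistical weight \eqn{(1/L)\,(1+G/K)^n} of a
#' conformation at ligand concentration G: the binding polynomial of its n
#' identical sites divided by its allosteric constant. State fractions are
#' ratios of these weights.
#'
#' @param model an [allosteric_model()].
#' @param conf name of one conformation in `model`.
#' @param G ligand concentration(s), molar, >= 0.
#' @return numeric vector of weights, one per concentration. May overflow to
#'   `Inf` for extreme `G/K`; [state_fractions()] works in log space and does
#'   not suffer from this.
#' @export
conformation_weight <- function(model, conf, G) {
  stopifnot(inherits(model, "allosteric_model"))
  G <- check_G(G)
  i <- match(conf, model$conformations$name)
  if (is.na(i)) stop("unknown conformation: ", conf)
  L <- model$conformations$L[i]
  K <- model$conformations$K[i]
  if (is.na(K)) rep(1 / L, length(G)) else (1 / L) * (1 + G / K)^model$n_sites
}

#' State functions: fraction of receptors in each conformation
#'
#' Evaluates the MWC state functions over a concentration grid. The fraction
#' of conformation X at concentration G is its weight
#' \eqn{(1/L_X)(1+G/K_X)^n} divided by the sum of weights over all
#' conformations. With `normalization = "conductive"` the reference (basal)
#' row is dropped and each column renormalized over the conductive
#' conformations only -- the scale on which single-channel conductance
#' frequencies (openings classified as S/M/L) are reported.
#'
#' Weights are computed in log space and combined by log-sum-exp, so the
#' fractions remain accurate when \eqn{(1+G/K)^n} overflows double precision.
#'
#' @param model an [allosteric_model()].
#' @param G concentration grid, molar, >= 0.
#' @param normalization `"all"` or `"conductive"`.
#' @return an object of class `state_fraction_table`: list with elements
#'   `concentrations`, `fractions` (matrix, conformations x concentrations,
#'   every column summing to 1) and `normalization`.
#' @export
state_fractions <- function(model, G, normalization = c("all", "conductive")) {
  stopifnot(inherits(model, "allosteric_model"))
  normalization <- match.arg(normalization)
  G <- check_G(G)
  cf <- model$conformations
  lw <- vapply(seq_len(nrow(cf)),
               function(i) conf_log_weight(cf$L[i], cf$K[i], model$n_sites, G),
               numeric(length(G)))
  lw <- matrix(lw, nrow = length(G))       # G x conf
  keep <- seq_len(nrow(cf))
  if (normalization == "conductive") {
    if (nrow(cf) < 2L)
      stop("conductive normalization needs at least one non-reference conformation")
    keep <- keep[-1L]
  }
  lw <- lw[, keep, drop = FALSE]
  m <- apply(lw, 1L, max)
  w <- exp(sweep(lw, 1L, m, "-"))
  frac <- w / rowSums(w)
  frac <- t(frac)                          # conf x G
  dimnames(frac) <- list(cf$name[keep], signif(G, 8))
  structure(list(concentrations = G, fractions = frac,
                 normalization = normalization, model_name = model$name),
            class = "state_fraction_table")
}

#' @export
print.state_fraction_table <- function(x, digits = 4, ...) {
  cat("State fractions (", x$normalization, " normalization), model: ",
      x$model_name, "\n", sep = "")
  print(round(x$fractions, digits))
  invisible(x)
}

#' @export
as.data.frame.state_fraction_table <- function(x, ...) {
  data.frame(state = rep(rownames(x$fractions), ncol(x$fractions)),
             concentration = rep(x$concentrations, each = nrow(x$fractions)),
             fraction = as.vector(x$fractions))
}

#' Plot state-function curves on a semi-log concentration axis
#'
#' @param x a `state_fraction_table`.
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.state_fraction_table <- function(x, ...) {
  matplot(x$concentrations, t(x$fractions), type = "l", log = "x", lty = 1,
          xlab = "ligand (M)", ylab = "fraction of receptors", ...)
  legend("right", legend = rownames(x$fractions), lty = 1,
         col = seq_len(nrow(x$fractions)), bty = "n")
  invisible(x)
}

#' Saturation function: fraction of binding sites occupied
#'
#' \deqn{\bar Y(G) = \frac{\sum_X (1/L_X)(G/K_X)(1+G/K_X)^{n-1}}
#'                        {\sum_X (1/L_X)(1+G/K_X)^{n}}}
#' Non-binding conformations contribute 0 to the numerator and \eqn{1/L} to
#' the denominator. Computed in log space.
#'
#' @inheritParams state_fractions
#' @return numeric vector in \[0, 1\], one value per concentration.
#' @export
saturation_fraction <- function(model, G) {
  stopifnot(inherits(model, "allosteric_model"))
  G <- check_G(G)
  cf <- model$conformations
  n <- model$n_sites
  num <- den <- matrix(-Inf, length(G), nrow(cf))
  for (i in seq_len(nrow(cf))) {
    den[, i] <- conf_log_weight(cf$L[i], cf$K[i], n, G)
    if (!is.na(cf$K[i]))
      num[, i] <- ifelse(G > 0,
                         -log(cf$L[i]) + log(G / cf$K[i]) +
                           (n - 1) * log1p(G / cf$K[i]),
                         -Inf)
  }
  lse <- function(lw) {
    m <- apply(lw, 1L, max)
    out <- m + log(rowSums(exp(sweep(lw, 1L, m, "-"))))
    out[!is.finite(m)] <- -Inf
    out
  }
  y <- exp(lse(num) - lse(den))
  pmin(pmax(y, 0), 1)
}

#' Distribution of the number of bound ligands within one conformation
#'
#' Within conformation X (identical independent sites at equilibrium), the
#' number of bound ligands is binomial with n trials and per-site occupancy
#' \eqn{(G/K_X)/(1+G/K_X)}. A non-binding conformation returns a point mass
#' at zero ligands.
#'
#' @inheritParams conformation_weight
#' @return numeric probability vector over 0..n_sites bound ligands (one
#'   concentration at a time).
#' @export
liganded_distribution <- function(model, conf, G) {
  stopifnot(inherits(model, "allosteric_model"), length(G) == 1L)
  G <- check_G(G)
  i <- match(conf, model$conformations$name)
  if (is.na(i)) stop("unknown conformation: ", conf)
  n <- model$n_sites
  K <- model$conformations$K[i]
  p <- if (is.na(K)) 0 else (G / K) / (1 + G / K)
  setNames(dbinom(0:n, n, p), 0:n)
}

#' Affinity ratios c between adjacent conformations
#'
#' For each adjacent pair along the conformational chain, the c parameter is
#' the ratio of dissociation constants of the more-active to the less-active
#' conformation, \eqn{c = K_{X'}/K_X}. Agonists bind active states more
#' tightly, so c < 1. Pairs where either conformation does not bind ligand
#' get `NA`.
#'
#' @param model an [allosteric_model()].
#' @return `data.frame` with columns `pair` (e.g. `"BS"`) and `c`.
#' @export
c_ratios <- function(model) {
  stopifnot(inherits(model, "allosteric_model"))
  cf <- model$conformations
  if (nrow(cf) < 2L) return(data.frame(pair = character(), c = numeric()))
  i <- seq_len(nrow(cf) - 1L)
  data.frame(pair = paste0(cf$name[i], cf$name[i + 1L]),
             c = cf$K[i + 1L] / cf$K[i])
}
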