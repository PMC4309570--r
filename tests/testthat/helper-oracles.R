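# Independent brute-force oracle: enumerate every (conformation, binding
# pattern) microstate -- 2^n site patterns per conformation -- and sum
# Boltzmann weights (1/L) * prod_occupied (G/K). No shared code with
# state_fractions(), which works per-conformation in log space.
oracle_state_fractions <- function(model, G, normalization = "all") {
  cf <- model$conformations
  n <- model$n_sites
  patterns <- as.matrix(expand.grid(rep(list(0:1), n)))
  vapply(G, function(g) {
    w <- vapply(seq_len(nrow(cf)), function(i) {
      if (is.na(cf$K[i])) {
        # non-binding: only the empty pattern exists
        1 / cf$L[i]
      } else {
        x <- g / cf$K[i]
        sum((1 / cf$L[i]) * x^rowSums(patterns))
      }
    }, numeric(1))
    if (normalization == "conductive") w <- w[-1L]
    w / sum(w)
  }, numeric(nrow(cf) - (normalization == "conductive")))
}

# same enumeration, mean fraction of occupied sites
oracle_saturation <- function(model, G) {
  cf <- model$conformations
  n <- model$n_sites
  patterns <- as.matrix(expand.grid(rep(list(0:1), n)))
  occ <- rowSums(patterns)
  vapply(G, function(g) {
    num <- den <- 0
    for (i in seq_len(nrow(cf))) {
      if (is.na(cf$K[i])) {
        den <- den + 1 / cf$L[i]
      } else {
        x <- g / cf$K[i]
        w <- (1 / cf$L[i]) * x^occ
        num <- num + sum(w * occ / n)
        den <- den + sum(w)
      }
    }
    num / den
  }, numeric(1))
}

# closed-form equilibrium over (conformation, ligand count) states of a
# scheme: weight (1/L) * choose(n, i) * (G/K)^i, normalized
mwc_state_occupancy <- function(scheme) {
  cf <- scheme$model$conformations
  n <- scheme$model$n_sites
  w <- numeric(nrow(scheme$states))
  for (s in seq_len(nrow(scheme$states))) {
    j <- match(scheme$states$conf[s], cf$name)
    i <- scheme$states$n_bound[s]
    w[s] <- (1 / cf$L[j]) * choose(n, i) * (scheme$G / cf$K[j])^i
  }
  setNames(w / sum(w), scheme$states$label)
}

all_preset_models <- function() {
  lapply(c("GluA3_GluK2", "native", "IW", "BrW"), ampar_model)
}

# a receptor with strongly closed-biased gating (rare spontaneous openings)
high_L_model <- function() {
  allosteric_model(data.frame(
    name = c("B", "S", "M", "L"),
    L = c(1, 1e3, 1e4, 1e5),
    K = c(9e-4, 5e-5, 3e-6, 2e-7)), name = "high-L")
}
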