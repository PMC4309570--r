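#' Conductance-state frequency dataset
#'
#' Container for observed (or synthetic) relative frequencies of conductance
#' states across a set of ligand concentrations: a matrix with one row per
#' state and one column per concentration. Datasets may cover a subset of
#' the model's conformations -- single-channel records of native receptors
#' classify only open events, so they have S/M/L rows and no basal row.
#'
#' @param concentrations molar concentration grid (length = `ncol(y)`).
#' @param y numeric matrix of relative frequencies in \[0, 1\]; rownames are
#'   state labels. Columns must sum to at most 1 (equal to 1 when every
#'   state is observed). `NA` cells mark missing observations.
#' @return object of class `frequency_dataset`.
#' @export
frequency_dataset <- function(concentrations, y) {
  y <- as.matrix(y)
  concentrations <- check_G(concentrations)
  if (ncol(y) != length(concentrations))
    stop("y must have one column per concentration")
  if (is.null(rownames(y))) stop("y must have state labels as rownames")
  vals <- y[!is.na(y)]
  if (any(vals < 0 | vals > 1)) stop("frequencies must lie in [0, 1]")
  cs <- colSums(y, na.rm = TRUE)
  if (any(cs > 1 + 1e-8)) stop("column sums exceed 1")
  structure(list(concentrations = concentrations, y = y,
                 states = rownames(y)),
            class = "frequency_dataset")
}

#' @export
print.frequency_dataset <- function(x, digits = 4, ...) {
  cat("Conductance-state frequencies:", length(x$concentrations),
      "concentrations,", nrow(x$y), "states\n")
  m <- round(x$y, digits)
  colnames(m) <- signif(x$concentrations, 4)
  print(m)
  invisible(x)
}

# which normalization matches the dataset: "all" if the model's reference
# conformation is observed, "conductive" otherwise
dataset_mode <- function(model, data) {
  ref <- model$conformations$name[1L]
  if (ref %in% data$states) "all" else "conductive"
}

predicted_fractions <- function(model, data, normalization) {
  sf <- state_fractions(model, data$concentrations, normalization)
  miss <- setdiff(data$states, rownames(sf$fractions))
  if (length(miss))
    stop("dataset states not in model: ", paste(miss, collapse = ", "))
  sf$fractions[data$states, , drop = FALSE]
}

#' Log least-squares objective for frequency data
#'
#' Sum over every observed (state, concentration) cell of the squared
#' difference between the base-10 logarithms of the model state function and
#' the observed relative frequency. The logarithm gives comparable weight to
#' rare and common states (state functions are read on a semi-log scale).
#' Observed zeros are floored at `log_floor` before taking logs; model
#' fractions are floored with the same constant for symmetry.
#'
#' @param model an [allosteric_model()].
#' @param data a [frequency_dataset()].
#' @param log_floor small positive floor applied inside the logarithm.
#' @param normalization `"auto"` (default: `"all"` when the dataset observes
#'   the reference conformation, `"conductive"` otherwise), `"all"` or
#'   `"conductive"`.
#' @return non-negative scalar.
#' @export
objective_value <- function(model, data, log_floor = 1e-6,
                            normalization = "auto") {
  stopifnot(inherits(model, "allosteric_model"),
            inherits(data, "frequency_dataset"), log_floor > 0)
  if (normalization == "auto") normalization <- dataset_mode(model, data)
  pred <- predicted_fractions(model, data, normalization)
  obs <- data$y
  ok <- !is.na(obs)
  d <- log10(pmax(pred[ok], log_floor)) - log10(pmax(obs[ok], log_floor))
  sum(d^2)
}

#' Pearson correlation between observed and fitted frequencies
#'
#' Correlates the observed relative frequencies with the model-predicted
#' state-function values over all observed (state, concentration) pairs,
#' reporting r and the two-sided p-value of the standard t transform.
#'
#' @inheritParams objective_value
#' @return list with elements `r` and `p_value`.
#' @export
pearson_fit_report <- function(model, data, normalization = "auto") {
  stopifnot(inherits(data, "frequency_dataset"))
  if (normalization == "auto") normalization <- dataset_mode(model, data)
  pred <- predicted_fractions(model, data, normalization)
  ok <- !is.na(data$y)
  if (sum(ok) < 3L) stop("need at least 3 paired points")
  ct <- cor.test(data$y[ok], pred[ok])
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Fitting specification for the thermodynamic model
#'
#' Collects which parameters are free, the box constraints, and the genetic
#' algorithm (GA) hyperparameters. Parameters are named `"L_<state>"` and
#' `"K_<state>"`; all are searched on the log10 scale, matching bounds that
#' span many decades (L in \[1, 1e6\], K in \[1e-10, 1e-3\] M by default).
#'
#' @param free character vector of free parameter names, or `NULL` to free
#'   every L of a non-reference conformation and every K the dataset can
#'   constrain.
#' @param fixed named numeric vector of parameter values to hold fixed
#'   (overriding the template model).
#' @param L_bounds,K_bounds length-2 numeric bounds.
#' @param pop_size,generations GA population size and number of generations.
#' @param crossover_rate probability that a selected pair is recombined
#'   (uniform crossover).
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sd mutation step SD in log10 units.
#' @param elitism number of best individuals copied unchanged.
#' @param n_starts independent GA restarts (best of all is returned).
#' @param polish if `TRUE`, refine the GA optimum with box-constrained
#'   quasi-Newton iterations (the objective is smooth; the GA handles the
#'   global search, the polish the final convergence).
#' @param log_floor floor used inside the objective.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(free = NULL, fixed = numeric(),
                     L_bounds = c(1, 1e6), K_bounds = c(1e-10, 1e-3),
                     pop_size = 100L, generations = 500L,
                     crossover_rate = 0.8, mutation_rate = 0.05,
                     mutation_sd = 0.25, elitism = 2L, n_starts = 3L,
                     polish = TRUE, log_floor = 1e-6) {
  stopifnot(all(L_bounds > 0), all(K_bounds > 0),
            L_bounds[1] < L_bounds[2], K_bounds[1] < K_bounds[2],
            pop_size >= 4L, generations >= 1L, n_starts >= 1L)
  structure(list(free = free, fixed = fixed,
                 L_bounds = L_bounds, K_bounds = K_bounds,
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 elitism = as.integer(elitism),
                 n_starts = as.integer(n_starts),
                 polish = isTRUE(polish), log_floor = log_floor),
            class = "fit_spec")
}

# replace free parameters (natural scale) in a template model
apply_params <- function(template, values) {
  cf <- template$conformations
  for (nm in names(values)) {
    kind <- substr(nm, 1, 1)
    st <- sub("^[LK]_", "", nm)
    i <- match(st, cf$name)
    if (is.na(i)) stop("parameter refers to unknown conformation: ", nm)
    if (kind == "L") cf$L[i] <- values[[nm]] else cf$K[i] <- values[[nm]]
  }
  template$conformations <- cf
  template
}

default_free <- function(template, data) {
  cf <- template$conformations
  nm <- character()
  for (i in seq_len(nrow(cf))[-1L]) nm <- c(nm, paste0("L_", cf$name[i]))
  for (i in seq_len(nrow(cf)))
    if (!is.na(cf$K[i])) nm <- c(nm, paste0("K_", cf$name[i]))
  nm
}

#' Fit the thermodynamic model to frequency data with a genetic algorithm
#'
#' Minimizes [objective_value()] over the free allosteric (L) and
#' dissociation (K) constants. The objective is highly non-linear with many
#' local minima, so the global search uses a real-coded genetic algorithm on
#' log10-transformed parameters (tournament selection, uniform crossover,
#' Gaussian mutation, elitism), optionally followed by a local box-constrained
#' polish. Deterministic given `seed`.
#'
#' @param data a [frequency_dataset()].
#' @param template an [allosteric_model()] supplying the conformational chain
#'   and any fixed parameter values.
#' @param spec a [fit_spec()].
#' @param seed integer RNG seed (recorded in the result).
#' @param normalization passed to [objective_value()].
#' @return object of class `fit_result`: list with the fitted `model`,
#'   `objective`, `residuals` (log10 differences), `pearson` (`r`,
#'   `p_value`), `trajectory` (best objective per generation, per start),
#'   `seed`, and `underdetermined` flag (more free parameters than observed
#'   cells).
#' @export
fit_thermodynamic <- function(data, template, spec = fit_spec(), seed,
                              normalization = "auto") {
  stopifnot(inherits(data, "frequency_dataset"),
            inherits(template, "allosteric_model"),
            inherits(spec, "fit_spec"))
  if (missing(seed)) stop("a seed is required for reproducible fits")
  if (length(data$concentrations) < 2L)
    warning("fewer than 2 concentrations: fit is weakly constrained")
  if (normalization == "auto") normalization <- dataset_mode(template, data)
  if (length(spec$fixed)) template <- apply_params(template, spec$fixed)
  free <- if (is.null(spec$free)) default_free(template, data) else spec$free
  free <- setdiff(free, names(spec$fixed))
  if (!length(free)) stop("no free parameters")
  is_L <- startsWith(free, "L_")
  lo <- ifelse(is_L, log10(spec$L_bounds[1]), log10(spec$K_bounds[1]))
  hi <- ifelse(is_L, log10(spec$L_bounds[2]), log10(spec$K_bounds[2]))

  # fast objective on the log10 parameter vector: rebuild the (conf x G)
  # log-weight matrix directly instead of constructing model objects
  cf <- template$conformations
  n <- template$n_sites
  G <- data$concentrations
  conf_keep <- if (normalization == "conductive") seq_len(nrow(cf))[-1L]
               else seq_len(nrow(cf))
  row_idx <- match(data$states, cf$name[conf_keep])
  if (anyNA(row_idx))
    stop("dataset states not covered by the chosen normalization")
  obs <- data$y
  ok <- !is.na(obs)
  lobs <- log10(pmax(obs[ok], spec$log_floor))
  Lvec <- cf$L; Kvec <- cf$K
  Lpos <- match(free[is_L], paste0("L_", cf$name))
  Kpos <- match(free[!is_L], paste0("K_", cf$name))
  obj_z <- function(z) {
    p <- 10^z
    L <- Lvec; K <- Kvec
    if (length(Lpos)) L[Lpos] <- p[is_L]
    if (length(Kpos)) K[Kpos] <- p[!is_L]
    lw <- matrix(0, nrow(cf), length(G))
    for (i in seq_len(nrow(cf)))
      lw[i, ] <- conf_log_weight(L[i], K[i], n, G)
    lw <- lw[conf_keep, , drop = FALSE]
    m <- apply(lw, 2L, max)
    lse <- m + log(colSums(exp(sweep(lw, 2L, m, "-"))))
    lfrac <- sweep(lw[row_idx, , drop = FALSE], 2L, lse, "-") / log(10)
    d <- pmax(lfrac[ok], log10(spec$log_floor)) - lobs
    sum(d^2)
  }

  set.seed(seed)
  d <- length(free)
  best_z <- NULL; best_f <- Inf
  trajectory <- matrix(NA_real_, spec$generations, spec$n_starts)
  for (s in seq_len(spec$n_starts)) {
    pop <- matrix(runif(spec$pop_size * d, lo, hi),
                  nrow = spec$pop_size, byrow = TRUE)
    fit <- apply(pop, 1L, obj_z)
    for (g in seq_len(spec$generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(spec$elitism)], , drop = FALSE]
      # binary tournament selection
      n_off <- spec$pop_size - spec$elitism
      i1 <- sample.int(spec$pop_size, n_off, replace = TRUE)
      i2 <- sample.int(spec$pop_size, n_off, replace = TRUE)
      parents <- ifelse(fit[i1] <= fit[i2], i1, i2)
      off <- pop[parents, , drop = FALSE]
      # uniform crossover of consecutive pairs
      for (k in seq_len(n_off %/% 2L)) {
        if (runif(1) < spec$crossover_rate) {
          a <- 2L * k - 1L; b <- 2L * k
          swap <- runif(d) < 0.5
          tmp <- off[a, swap]
          off[a, swap] <- off[b, swap]
          off[b, swap] <- tmp
        }
      }
      mut <- matrix(runif(n_off * d) < spec$mutation_rate, n_off, d)
      step <- matrix(rnorm(n_off * d, sd = spec$mutation_sd), n_off, d)
      off <- off + mut * step
      off <- pmin(pmax(off, matrix(lo, n_off, d, byrow = TRUE)),
                  matrix(hi, n_off, d, byrow = TRUE))
      pop <- rbind(elite, off)
      fit <- c(fit[ord[seq_len(spec$elitism)]], apply(off, 1L, obj_z))
      trajectory[g, s] <- min(fit)
    }
    i <- which.min(fit)
    if (fit[i] < best_f) { best_f <- fit[i]; best_z <- pop[i, ] }
  }
  if (spec$polish) {
    op <- optim(best_z, obj_z, method = "L-BFGS-B", lower = lo, upper = hi,
                control = list(maxit = 500, factr = 1e4))
    if (op$value < best_f) { best_f <- op$value; best_z <- op$par }
  }

  values <- setNames(10^best_z, free)
  model <- apply_params(template, values)
  model$name <- paste0(template$name, " (fitted)")
  pred <- predicted_fractions(model, data, normalization)
  ok2 <- !is.na(data$y)
  res <- log10(pmax(pred[ok2], spec$log_floor)) -
    log10(pmax(data$y[ok2], spec$log_floor))
  structure(list(
    model = model, objective = best_f, residuals = res,
    pearson = pearson_fit_report(model, data, normalization),
    trajectory = trajectory, seed = seed, free = free,
    normalization = normalization,
    underdetermined = length(free) > sum(ok2)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Thermodynamic fit (seed ", x$seed, ")\n", sep = "")
  cat("  objective:", format(x$objective, digits = 6),
      " Pearson r:", format(x$pearson$r, digits = 4), "\n")
  if (x$underdetermined)
    cat("  NOTE: more free parameters than observed cells (under-determined)\n")
  print(x$model)
  invisible(x)
}
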