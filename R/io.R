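#' Read and write allosteric models as JSON
#'
#' The on-disk schema is `{name, n_sites, conformations: [{name, L, K}]}`
#' with `K: null` for non-binding conformations. Parameter files for the
#' built-in receptor systems ship under `inst/extdata/` and round-trip
#' losslessly.
#'
#' @param path file path.
#' @return [read_model_json()] returns an [allosteric_model()];
#'   [write_model_json()] returns `path` invisibly.
#' @export
#' @examples
#' p <- system.file("extdata", "gluA3_gluK2.json", package = "ampaMWC")
#' m <- read_model_json(p)
read_model_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::read_json(path)
  for (f in c("name", "n_sites", "conformations"))
    if (is.null(j[[f]])) stop("model file missing field '", f, "': ", path)
  cf <- do.call(rbind, lapply(seq_along(j$conformations), function(i) {
    ci <- j$conformations[[i]]
    for (f in c("name", "L"))
      if (is.null(ci[[f]]))
        stop("conformations[", i, "] missing field '", f, "': ", path)
    data.frame(name = ci$name, L = as.numeric(ci$L),
               K = if (is.null(ci$K)) NA_real_ else as.numeric(ci$K))
  }))
  allosteric_model(cf, n_sites = j$n_sites, name = j$name)
}

#' @rdname read_model_json
#' @param model an [allosteric_model()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "allosteric_model"))
  cf <- model$conformations
  confs <- lapply(seq_len(nrow(cf)), function(i)
    list(name = cf$name[i], L = cf$L[i],
         K = if (is.na(cf$K[i])) NULL else cf$K[i]))
  jsonlite::write_json(
    list(name = model$name, n_sites = model$n_sites, conformations = confs),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and write conductance-frequency tables as CSV
#'
#' Format: first column `state`, remaining column names are molar
#' concentrations (scientific notation accepted); one row per state; empty
#' cells mark missing observations.
#'
#' @param path file path.
#' @return a [frequency_dataset()] / `path` invisibly.
#' @export
read_frequency_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "state") stop("first column must be 'state'")
  y <- as.matrix(df[, -1L, drop = FALSE])
  rownames(y) <- df$state
  conc <- as.numeric(colnames(y))
  if (anyNA(conc)) stop("column headers must be molar concentrations")
  frequency_dataset(conc, y)
}

#' @rdname read_frequency_csv
#' @param data a [frequency_dataset()].
#' @export
write_frequency_csv <- function(data, path) {
  stopifnot(inherits(data, "frequency_dataset"))
  df <- data.frame(state = data$states, data$y, check.names = FALSE)
  colnames(df) <- c("state", format(data$concentrations, scientific = TRUE,
                                    trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export state-function tables and simulation traces as CSV
#'
#' State-fraction tables are written with a header row of molar
#' concentrations and one row per state; traces with a `time` column plus
#' one column per state.
#'
#' @param x a `state_fraction_table` or `trace_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_state_fractions_csv <- function(x, path) {
  stopifnot(inherits(x, "state_fraction_table"))
  df <- data.frame(state = rownames(x$fractions), x$fractions,
                   check.names = FALSE)
  colnames(df) <- c("state", format(x$concentrations, scientific = TRUE,
                                    trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_fractions_csv
#' @export
write_trace_csv <- function(x, path) {
  stopifnot(inherits(x, "trace_result"))
  df <- data.frame(time = x$times, t(x$occupancy),
                   conductance = x$conductance, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# metadata sidecar so any stochastic output can be reproduced exactly
write_run_metadata <- function(path, config, seed = NULL) {
  meta <- list(
    package = "ampaMWC",
    version = as.character(utils::packageVersion("ampaMWC")),
    seed = seed, config = config)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
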