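#' Read a reaction-based model from a directory of plain-text files
#'
#' A model lives in a directory of whitespace-separated text files:
#' \describe{
#'   \item{`left_side`}{reactant stoichiometry matrix `A`, one row per
#'     reaction (M rows), one column per species (N columns).}
#'   \item{`right_side`}{product stoichiometry matrix `B`, same shape.}
#'   \item{`c_vector`}{kinetic constants, one per line (M values).}
#'   \item{`M_0`}{initial concentrations, N values.}
#'   \item{`t_vector`}{sampling time instants, one per line, strictly
#'     increasing; the last value is the simulation horizon.}
#'   \item{`cs_vector`}{optional; 0-based indices of the species whose
#'     concentration is recorded.}
#'   \item{`species_names`}{optional; one label per species.}
#' }
#' Lines starting with `#` and blank lines are ignored. Species order is the
#' column order of `left_side`; all indices in files are 0-based.
#'
#' @param model_dir path to the model directory.
#' @param allow_zero_order if `TRUE`, accept reactions with an empty
#'   reactant side (constant-rate sources). By default only first- and
#'   second-order reactions (one or two reactant molecules) are admitted.
#' @return an object of class `reaction_model` with fields `n_species`,
#'   `n_reactions`, `reactant_matrix`, `product_matrix`, `kinetic_constants`,
#'   `initial_state`, `sampling_times`, `recorded_species` (0-based, or NULL
#'   for all) and `species_names`.
#' @seealso [validate_model()], [write_model()], [generate_random_model()]
#' @examples
#' dir <- system.file("extdata", "two_reaction_example", package = "massaction")
#' m <- parse_model(dir)
#' m$n_reactions
#' @export
parse_model <- function(model_dir, allow_zero_order = FALSE) {
  if (!dir.exists(model_dir)) {
    stop("model directory not found: ", model_dir, call. = FALSE)
  }
  need <- c("left_side", "right_side", "c_vector", "M_0", "t_vector")
  paths <- file.path(model_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing model file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }

  A <- read_matrix_file(file.path(model_dir, "left_side"), "left_side")
  if (nrow(A) == 0L || ncol(A) == 0L) {
    stop("left_side contains no reactions", call. = FALSE)
  }
  B <- read_matrix_file(file.path(model_dir, "right_side"), "right_side")
  if (!identical(dim(A), dim(B))) {
    stop(sprintf(
      "dimension mismatch: left_side is %dx%d but right_side is %dx%d",
      nrow(A), ncol(A), nrow(B), ncol(B)
    ), call. = FALSE)
  }
  M <- nrow(A)
  N <- ncol(A)
  K <- read_vector_file(file.path(model_dir, "c_vector"), "c_vector")
  if (length(K) != M) {
    stop(sprintf("dimension mismatch: c_vector has %d entries, expected %d",
                 length(K), M), call. = FALSE)
  }
  X0 <- read_vector_file(file.path(model_dir, "M_0"), "M_0")
  if (length(X0) != N) {
    stop(sprintf("dimension mismatch: M_0 has %d entries, expected %d",
                 length(X0), N), call. = FALSE)
  }
  times <- read_vector_file(file.path(model_dir, "t_vector"), "t_vector")

  recorded <- NULL
  cs_path <- file.path(model_dir, "cs_vector")
  if (file.exists(cs_path)) {
    recorded <- as.integer(read_vector_file(cs_path, "cs_vector"))
    if (any(recorded < 0L) || any(recorded >= N)) {
      stop("cs_vector indices must be 0-based and smaller than the species count",
           call. = FALSE)
    }
  }
  names_path <- file.path(model_dir, "species_names")
  species_names <- if (file.exists(names_path)) {
    nm <- read_token_file(names_path)
    if (length(nm) != N) {
      stop(sprintf("species_names has %d entries, expected %d", length(nm), N),
           call. = FALSE)
    }
    nm
  } else {
    paste0("X", seq_len(N))
  }

  model <- new_reaction_model(A, B, K, X0, times, species_names, recorded)
  viol <- validate_model(model, allow_zero_order = allow_zero_order)
  if (nrow(viol) > 0) {
    stop("invalid model:\n", paste0("  - ", viol$message, collapse = "\n"),
         call. = FALSE)
  }
  model
}

#' Construct a reaction-based model from its components
#'
#' Low-level constructor used by [parse_model()] and
#' [generate_random_model()]; performs shape coercion but no kinetic
#' validation (see [validate_model()]).
#'
#' @param reactant_matrix M x N non-negative integer matrix `A`.
#' @param product_matrix M x N non-negative integer matrix `B`.
#' @param kinetic_constants length-M positive numeric vector.
#' @param initial_state length-N non-negative numeric vector.
#' @param sampling_times strictly increasing numeric vector of recording
#'   instants; the last entry is the simulation horizon.
#' @param species_names optional character vector of length N.
#' @param recorded_species optional 0-based integer indices of species to
#'   record (`NULL` records all).
#' @return a `reaction_model` object.
#' @export
new_reaction_model <- function(reactant_matrix, product_matrix, kinetic_constants,
                               initial_state, sampling_times,
                               species_names = NULL, recorded_species = NULL) {
  A <- as.matrix(reactant_matrix)
  B <- as.matrix(product_matrix)
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  if (is.null(species_names)) species_names <- paste0("X", seq_len(ncol(A)))
  structure(
    list(
      n_species = ncol(A),
      n_reactions = nrow(A),
      reactant_matrix = A,
      product_matrix = B,
      kinetic_constants = as.numeric(kinetic_constants),
      initial_state = as.numeric(initial_state),
      sampling_times = as.numeric(sampling_times),
      species_names = as.character(species_names),
      recorded_species = if (is.null(recorded_species)) NULL else as.integer(recorded_species)
    ),
    class = "reaction_model"
  )
}

#' @export
print.reaction_model <- function(x, ...) {
  cat(sprintf("Reaction-based model: %d reactions x %d species\n",
              x$n_reactions, x$n_species))
  cat(sprintf("  kinetic constants in [%.3g, %.3g]\n",
              min(x$kinetic_constants), max(x$kinetic_constants)))
  cat(sprintf("  %d sampling instants over [%g, %g]\n",
              length(x$sampling_times), x$sampling_times[1],
              x$sampling_times[length(x$sampling_times)]))
  invisible(x)
}

#' Check a reaction-based model against the mass-action contract
#'
#' Violations are returned as data, not raised as errors, so that a caller
#' can report all problems at once. The rules: `A` and `B` share an M x N
#' shape with non-negative integer entries; every reaction involves one or
#' two reactant molecules (first/second order only; zero-order sources are
#' rejected unless `allow_zero_order`); every kinetic constant is strictly
#' positive; initial concentrations are non-negative; sampling times are
#' strictly increasing.
#'
#' @param model a `reaction_model`.
#' @param allow_zero_order accept reactions with empty reactant side.
#' @return a data.frame with columns `rule`, `index` (offending 1-based
#'   reaction/species index, NA for global rules) and `message`; zero rows
#'   when the model is valid.
#' @export
validate_model <- function(model, allow_zero_order = FALSE) {
  rule <- character()
  index <- integer()
  msg <- character()
  add <- function(r, i, m) {
    rule <<- c(rule, r)
    index <<- c(index, i)
    msg <<- c(msg, m)
  }

  A <- model$reactant_matrix
  B <- model$product_matrix
  if (!identical(dim(A), dim(B))) {
    add("shape", NA_integer_, "reactant and product matrices differ in shape")
    return(data.frame(rule = rule, index = index, message = msg,
                      stringsAsFactors = FALSE))
  }
  M <- nrow(A)
  N <- ncol(A)
  if (length(model$kinetic_constants) != M) {
    add("shape", NA_integer_, sprintf(
      "kinetic constants: %d entries for %d reactions",
      length(model$kinetic_constants), M))
  }
  if (length(model$initial_state) != N) {
    add("shape", NA_integer_, sprintf(
      "initial state: %d entries for %d species",
      length(model$initial_state), N))
  }
  bad_int <- function(x) any(!is.finite(x)) || any(x < 0) || any(x != round(x))
  if (bad_int(A)) {
    add("stoichiometry", NA_integer_,
        "reactant matrix entries must be non-negative integers")
  }
  if (bad_int(B)) {
    add("stoichiometry", NA_integer_,
        "product matrix entries must be non-negative integers")
  }

  orders <- rowSums(A)
  lo <- if (allow_zero_order) 0 else 1
  for (i in which(orders > 2 | orders < lo)) {
    add(
      if (orders[i] > 2) "reaction order > 2" else "reaction order < 1", i,
      sprintf("reaction %d has %g reactant molecules (allowed: %d-2)",
              i, orders[i], lo))
  }
  ks <- model$kinetic_constants
  for (i in which(!is.finite(ks) | ks <= 0)) {
    add("non-positive kinetic constant", i,
        sprintf("reaction %d has kinetic constant %g (must be > 0)", i, ks[i]))
  }
  x0 <- model$initial_state
  for (j in which(!is.finite(x0) | x0 < 0)) {
    add("negative initial concentration", j,
        sprintf("species %d has initial concentration %g (must be >= 0)", j, x0[j]))
  }
  ts <- model$sampling_times
  if (length(ts) < 1 || any(!is.finite(ts)) || any(ts < 0)) {
    add("sampling times", NA_integer_,
        "sampling times must be non-negative and non-empty")
  } else if (length(ts) > 1 && any(diff(ts) <= 0)) {
    add("sampling times", NA_integer_, "sampling times must be strictly increasing")
  }
  data.frame(rule = rule, index = index, message = msg, stringsAsFactors = FALSE)
}

#' Write a reaction-based model in the plain-text dialect
#'
#' Produces the same file layout that [parse_model()] reads, so that
#' `parse_model(write_model(m, d))` round-trips exactly.
#'
#' @param model a `reaction_model`.
#' @param model_dir output directory (created if necessary).
#' @return `model_dir`, invisibly.
#' @export
write_model <- function(model, model_dir) {
  if (!dir.exists(model_dir)) dir.create(model_dir, recursive = TRUE)
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  write_mat <- function(m, path) {
    writeLines(apply(m, 1L, function(r) paste(format(r, trim = TRUE), collapse = "\t")),
               path)
  }
  write_mat(model$reactant_matrix, file.path(model_dir, "left_side"))
  write_mat(model$product_matrix, file.path(model_dir, "right_side"))
  writeLines(fmt(model$kinetic_constants), file.path(model_dir, "c_vector"))
  writeLines(paste(fmt(model$initial_state), collapse = "\t"),
             file.path(model_dir, "M_0"))
  writeLines(fmt(model$sampling_times), file.path(model_dir, "t_vector"))
  if (!is.null(model$recorded_species)) {
    writeLines(format(model$recorded_species, trim = TRUE),
               file.path(model_dir, "cs_vector"))
  }
  if (!is.null(model$species_names)) {
    writeLines(model$species_names, file.path(model_dir, "species_names"))
  }
  invisible(model_dir)
}

#' Write a simulated time series as a tab-separated file
#'
#' The first column is `time`; the remaining columns carry one recorded
#' species each, labelled by name. Values are written with 17 significant
#' digits so that a read-back reproduces the doubles bit-for-bit.
#'
#' @param result a `simulation_result` from [simulate_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_timeseries()]
#' @export
write_timeseries <- function(result, path) {
  if (is.null(result$times) || length(result$times) == 0) {
    stop("empty simulation result", call. = FALSE)
  }
  tab <- cbind(time = result$times, result$states)
  lines <- c(
    paste(colnames(tab), collapse = "\t"),
    apply(tab, 1L, function(r) {
      paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
    })
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read back a tab-separated time series
#'
#' @param path file written by [write_timeseries()].
#' @return a list with `times` and `states` (matrix with species columns).
#' @export
read_timeseries <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  states <- as.matrix(tab[, -1, drop = FALSE])
  list(times = tab[[1]], states = states)
}

## -- internal parsing helpers -------------------------------------------

read_token_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines
}

read_matrix_file <- function(path, label) {
  lines <- read_token_file(path)
  if (length(lines) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  rows <- lapply(lines, function(l) {
    toks <- strsplit(l, "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric token in %s: '%s'", label,
                   toks[which(is.na(vals))[1]]), call. = FALSE)
    }
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    stop(sprintf("ragged rows in %s (found row lengths %s)", label,
                 paste(sort(unique(ncols)), collapse = ", ")), call. = FALSE)
  }
  do.call(rbind, rows)
}

read_vector_file <- function(path, label) {
  lines <- read_token_file(path)
  toks <- unlist(strsplit(lines, "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals))) {
    stop(sprintf("non-numeric token in %s: '%s'", label,
                 toks[which(is.na(vals))[1]]), call. = FALSE)
  }
  vals
}
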