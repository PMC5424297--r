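#' Default simulation configuration
#'
#' The defaults: per-species explicit tolerance `eps_rkf = 1e-12`,
#' first-order BDF (`q = 1`, backward Euler) with implicit step
#' `dt_bdf = 0.1`, Newton tolerance `eps_nr = 1e-6` with at most `1e4`
#' iterations, initial explicit step `dt0 = 1e-3`, and stiffness-switch
#' threshold `eps_s = 1e-6`.
#'
#' @param n_species number of species (length of the tolerance vector).
#' @param eps_rkf per-species explicit error tolerance (scalar or vector).
#' @param bdf_order BDF order `q`, 1 to 6.
#' @param dt_bdf implicit macro-step length.
#' @param eps_nr Newton-Raphson tolerance.
#' @param max_it Newton-Raphson iteration cap.
#' @param dt0 initial explicit step size.
#' @param eps_s step-size threshold below which the system is declared
#'   stiff and integration switches to BDF.
#' @param delta_max cap on the step-size multiplier.
#' @param dt_max optional hard cap on the explicit step; by default the
#'   step is only limited by the distance to the next sampling instant.
#' @param bdf_run_steps number of consecutive BDF macro-steps taken per
#'   switch before the explicit method is retried.
#' @param recorded_species optional 0-based indices of species to record;
#'   `NULL` records every species.
#' @return a list of class `simulation_config`.
#' @export
default_config <- function(n_species, eps_rkf = 1e-12, bdf_order = 1,
                           dt_bdf = 0.1, eps_nr = 1e-6, max_it = 1e4,
                           dt0 = 1e-3, eps_s = 1e-6, delta_max = 4,
                           dt_max = NULL, bdf_run_steps = 1,
                           recorded_species = NULL) {
  stopifnot(n_species >= 1)
  cfg <- structure(
    list(
      eps_rkf = rep_len(as.numeric(eps_rkf), n_species),
      bdf_order = as.integer(bdf_order),
      dt_bdf = dt_bdf, eps_nr = eps_nr, max_it = as.integer(max_it),
      dt0 = dt0, eps_s = eps_s, delta_max = delta_max,
      dt_max = dt_max, bdf_run_steps = as.integer(bdf_run_steps),
      recorded_species = recorded_species
    ),
    class = "simulation_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    all(cfg$eps_rkf > 0), cfg$bdf_order >= 1, cfg$bdf_order <= 6,
    cfg$dt_bdf > 0, cfg$eps_nr > 0, cfg$max_it >= 1, cfg$dt0 > 0,
    cfg$eps_s > 0, cfg$delta_max > 1, cfg$bdf_run_steps >= 1
  )
  invisible(cfg)
}

#' Simulate a reaction-based model
#'
#' Runs the full workflow: the ODE system is generated from stoichiometry
#' and compressed ([build_encoding()]), the state is recorded at every
#' requested sampling instant, and between instants the system is advanced
#' by adaptive explicit Runge-Kutta-Fehlberg steps. A rejected step whose
#' shrunken retry size falls below `eps_s` marks the system as stiff: the
#' simulator then takes implicit BDF macro-steps of length `dt_bdf`
#' (modified Newton-Raphson with reused LU factors) before handing control
#' back to the explicit method at step `dt0`. The explicit step is clamped
#' so integration lands exactly on each sampling instant; no interpolation
#' is performed.
#'
#' Concentrations are not clipped at zero: the ODE flow defines the
#' dynamics, and a warning is emitted if any recorded value falls below
#' `-1e-9`.
#'
#' @param model a valid `reaction_model`.
#' @param config a `simulation_config`; defaults to
#'   `default_config(model$n_species)`.
#' @param encoding optionally, a prebuilt `ode_encoding` for `model`.
#' @return an object of class `simulation_result` with `times` (the
#'   sampling instants), `states` (instants x recorded species matrix with
#'   named columns) and `diagnostics` (counts of accepted and rejected
#'   explicit steps, BDF steps, and explicit-to-implicit switches).
#' @examples
#' m <- generate_random_model(16, 16, seed = 1)
#' r <- simulate_model(m)
#' r$diagnostics
#' @export
simulate_model <- function(model, config = NULL, encoding = NULL) {
  viol <- validate_model(model)
  if (nrow(viol) > 0) {
    stop("invalid model:\n", paste0("  - ", viol$message, collapse = "\n"),
         call. = FALSE)
  }
  if (is.null(config)) config <- default_config(model$n_species)
  validate_config(config)
  if (is.null(encoding)) encoding <- build_encoding(model)

  times <- model$sampling_times
  res <- cpp_simulate(
    encoding, model$initial_state, times, config$eps_rkf,
    config$dt0, config$eps_s, config$delta_max,
    if (is.null(config$dt_max)) -1 else config$dt_max,
    config$bdf_order, config$dt_bdf, config$eps_nr, config$max_it,
    config$bdf_run_steps
  )
  if (nzchar(res$error)) {
    stop("simulation aborted: ", res$error, call. = FALSE)
  }
  states <- res$states
  colnames(states) <- model$species_names

  recorded <- config$recorded_species
  if (is.null(recorded)) recorded <- model$recorded_species
  if (!is.null(recorded)) {
    states <- states[, recorded + 1L, drop = FALSE]
  }
  if (any(states < -1e-9)) {
    warning("recorded concentrations below -1e-9; the model may be leaving ",
            "the physical regime", call. = FALSE)
  }
  structure(
    list(
      times = times,
      states = states,
      diagnostics = list(
        accepted = res$accepted, rejected = res$rejected,
        bdf_steps = res$bdf_steps, switches = res$switches
      )
    ),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "Simulation result: %d instants x %d species (RKF steps: %d accepted, %d rejected; BDF steps: %d; switches: %d)\n",
    length(x$times), ncol(x$states), d$accepted, d$rejected, d$bdf_steps,
    d$switches))
  invisible(x)
}

#' Compare two simulated trajectories
#'
#' Computes the maximum absolute and maximum relative deviation between two
#' results on the same time grid and species set, and reports where each
#' maximum occurs. The relative deviation at a cell is
#' `|a - b| / max(|a|, |b|, atol)`, so that values below the absolute floor
#' `atol` do not inflate the relative measure.
#'
#' @param a,b `simulation_result` objects (or lists with `times` and
#'   `states`).
#' @param rtol relative tolerance used for the `within_tolerance` verdict.
#' @param atol absolute floor for the relative deviation.
#' @return a list with `max_abs`, `max_abs_where`, `max_rel`,
#'   `max_rel_where` (each `where` a `(time, species)` pair) and
#'   `within_tolerance`.
#' @export
compare_trajectories <- function(a, b, rtol = 1e-4, atol = 1e-8) {
  if (length(a$times) != length(b$times) ||
      any(abs(a$times - b$times) > 1e-12 * pmax(1, abs(a$times)))) {
    stop("time grids differ", call. = FALSE)
  }
  if (!identical(dim(a$states), dim(b$states))) {
    stop("species sets differ", call. = FALSE)
  }
  d <- abs(a$states - b$states)
  scale <- pmax(abs(a$states), abs(b$states), atol)
  rel <- d / scale
  ia <- which(d == max(d), arr.ind = TRUE)[1, ]
  ir <- which(rel == max(rel), arr.ind = TRUE)[1, ]
  sp_names <- colnames(a$states)
  if (is.null(sp_names)) sp_names <- paste0("X", seq_len(ncol(a$states)))
  list(
    max_abs = max(d),
    max_abs_where = list(time = a$times[ia[1]], species = sp_names[ia[2]]),
    max_rel = max(rel),
    max_rel_where = list(time = a$times[ir[1]], species = sp_names[ir[2]]),
    within_tolerance = max(rel) <= rtol
  )
}
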