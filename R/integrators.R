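#' One explicit Runge-Kutta-Fehlberg 4(5) step
#'
#' Advances the state by a single embedded-pair step: six derivative stages
#' `l1..l6` are evaluated through the compressed encoding and combined into
#' two approximations of `X(t + dt)` — the fifth-order `u` (the candidate
#' new state, i.e. local extrapolation) and the fourth-order companion `w`.
#' The per-species error measure is `ER = |w - u| / dt`, computed directly
#' from the stage combination to avoid cancellation.
#'
#' @param system an `ode_encoding`.
#' @param X current state vector.
#' @param t current time (the right-hand side is autonomous; kept for the
#'   standard step signature).
#' @param dt step size, > 0.
#' @param eps optional tolerance vector; when supplied, the step multipliers
#'   `delta` are attached (see [error_and_delta()]).
#' @param delta_max cap applied to each `delta_j` (used when `ER_j = 0`).
#' @return a list of class `rkf_step_result` with `stages` (N x 6 matrix),
#'   `u`, `w`, `ER` and (if `eps` given) `delta`.
#' @export
rkf_step <- function(system, X, t = 0, dt, eps = NULL, delta_max = 4) {
  stopifnot(dt > 0)
  X <- as.numeric(X)
  if (length(X) != system$n_species) {
    stop("state length does not match the system", call. = FALSE)
  }
  res <- cpp_rkf_step(system, X, dt)
  res$u <- as.numeric(res$u)
  res$w <- as.numeric(res$w)
  res$ER <- as.numeric(res$ER)
  if (any(!is.finite(res$stages))) {
    res$failed <- TRUE
  } else {
    res$failed <- FALSE
  }
  if (!is.null(eps)) {
    res$delta <- delta_from_er(res$ER, eps, delta_max)
  }
  class(res) <- "rkf_step_result"
  res
}

#' Per-species error measure and step-size multiplier
#'
#' The embedded pair's two states give the error measure
#' `ER = |w - u| / dt` and the safety-factored multiplier
#' `delta = 0.84 (eps / ER)^(1/4)`, applied componentwise. Where `ER_j = 0`
#' the multiplier is capped at `delta_max` instead of dividing by zero.
#'
#' @param u candidate (fifth-order) state.
#' @param w companion (fourth-order) state.
#' @param dt step size, > 0.
#' @param eps positive tolerance vector (recycled to the state length).
#' @param delta_max upper cap on each multiplier.
#' @return a list with `ER` and `delta` vectors.
#' @export
error_and_delta <- function(u, w, dt, eps, delta_max = 4) {
  stopifnot(dt > 0, all(eps > 0))
  ER <- abs(w - u) / dt
  list(ER = ER, delta = delta_from_er(ER, rep_len(eps, length(ER)), delta_max))
}

delta_from_er <- function(ER, eps, delta_max) {
  delta <- rep(delta_max, length(ER))
  nz <- is.finite(ER) & ER > 0
  delta[nz] <- pmin(0.84 * (eps[nz] / ER[nz])^0.25, delta_max)
  delta
}

#' Accept, retry or switch: the explicit step controller
#'
#' The step is accepted iff `ER_j <= eps_j` for every species, in which case
#' the candidate `u` becomes the new state. Otherwise the step is rejected
#' and retried at `dt' = dt * min_j delta_j`; if that shrunken step falls
#' below the stiffness threshold `eps_s`, the controller instead signals a
#' switch to implicit (BDF) integration.
#'
#' @param result an `rkf_step_result`.
#' @param eps positive tolerance vector.
#' @param dt the step size that produced `result`.
#' @param eps_s stiffness threshold on the retry step size.
#' @param delta_max cap on the step multipliers.
#' @return a list with `action` (`"accept"`, `"retry"` or
#'   `"switch_to_bdf"`), `state` (new state on acceptance, else `NULL`) and
#'   `dt` (the updated step size; on acceptance `dt * min delta`, on
#'   rejection the shrunken retry step).
#' @export
step_control <- function(result, eps, dt, eps_s, delta_max = 4) {
  eps <- rep_len(eps, length(result$ER))
  delta <- delta_from_er(result$ER, eps, delta_max)
  ok <- !isTRUE(result$failed) && all(is.finite(result$ER)) &&
    all(result$ER <= eps)
  if (ok) {
    return(list(action = "accept", state = result$u, dt = dt * min(delta)))
  }
  dt_new <- if (isTRUE(result$failed) || any(!is.finite(result$ER))) {
    dt * 0.1
  } else {
    dt * min(delta)
  }
  if (dt_new >= eps_s) {
    list(action = "retry", state = NULL, dt = dt_new)
  } else {
    list(action = "switch_to_bdf", state = NULL, dt = dt_new)
  }
}

#' Coefficients of the backward differentiation formulae, orders 1 to 6
#'
#' In the convention `sum_{i=0}^{q} alpha_i X(t - i dt) = dt beta_0 f(t, X(t))`
#' with `alpha_0 = 1`, where `X(t)` is the state being solved for and the
#' remaining terms are history at uniform spacing `dt`. Order 1 is the
#' backward Euler method. Orders above 6 have a vanishing absolute-stability
#' region and are refused.
#'
#' The returned coefficients satisfy the polynomial exactness identities
#' `sum_i alpha_i = 0` and `beta_0 = -sum_i i alpha_i`.
#'
#' @param q integer order, 1 to 6.
#' @return a list of class `bdf_coefficients` with `order`, `alphas`
#'   (length `q + 1`) and `beta0`.
#' @export
bdf_coefficients <- function(q) {
  if (length(q) != 1 || !is.finite(q) || q != round(q) || q < 1 || q > 6) {
    stop("unsupported BDF order: q must be an integer in 1..6", call. = FALSE)
  }
  tab <- list(
    list(alphas = c(1, -1), beta0 = 1),
    list(alphas = c(1, -4 / 3, 1 / 3), beta0 = 2 / 3),
    list(alphas = c(1, -18 / 11, 9 / 11, -2 / 11), beta0 = 6 / 11),
    list(alphas = c(1, -48 / 25, 36 / 25, -16 / 25, 3 / 25), beta0 = 12 / 25),
    list(alphas = c(1, -300 / 137, 300 / 137, -200 / 137, 75 / 137, -12 / 137),
         beta0 = 60 / 137),
    list(alphas = c(1, -360 / 147, 450 / 147, -400 / 147, 225 / 147, -72 / 147,
                    10 / 147), beta0 = 60 / 147)
  )[[q]]
  structure(list(order = as.integer(q), alphas = tab$alphas, beta0 = tab$beta0),
            class = "bdf_coefficients")
}

#' One implicit BDF step
#'
#' Solves the order-`q` BDF relation for the new state `z = X(t + dt)`:
#' the residual is `G(z) = z + sum_{i=1..q} alpha_i X_hist_i - dt beta_0 f(z)`
#' and the nonlinear system is handled by the modified Newton-Raphson
#' iteration with the iteration matrix `I - dt beta_0 J` factorized once
#' (LU with partial pivoting) and reused across iterations.
#'
#' @param system an `ode_encoding`.
#' @param history matrix of recent states, one row per state, most recent
#'   first, at uniform spacing `dt`; at least `q` rows.
#' @param dt implicit step size.
#' @param q BDF order, 1 to 6.
#' @param eps_nr Newton tolerance on the max-norm of the update.
#' @param max_it Newton iteration cap.
#' @return the new state vector, with attributes `iterations` and
#'   `converged`.
#' @export
bdf_step <- function(system, history, dt, q = 1, eps_nr = 1e-6, max_it = 1e4) {
  history <- rbind(history)
  if (nrow(history) < q) {
    stop("history must hold at least q states", call. = FALSE)
  }
  coef <- bdf_coefficients(q)
  res <- cpp_bdf_step(system, history, dt, as.integer(q), eps_nr,
                      as.integer(max_it))
  if (!res$converged) {
    stop(sprintf(
      "Newton-Raphson failed to converge within %d iterations in the BDF step",
      as.integer(max_it)), call. = FALSE)
  }
  structure(as.numeric(res$state), iterations = res$iterations,
            converged = TRUE)
}

#' Modified Newton-Raphson iteration with reused LU factors
#'
#' Root-finds `G(z) = 0` by `z <- z - solve(J0, G(z))`, where the iteration
#' matrix is the Jacobian evaluated at the initial guess, factorized once
#' and reused ("modified" scheme). If the update norm stagnates (successive
#' ratio above 0.9 for three iterations) the Jacobian is re-evaluated and
#' re-factorized once before failure is declared. Convergence is reached
#' when the max-norm of the update drops below `eps_nr`.
#'
#' @param residual_fn function of `z` returning the residual vector.
#' @param jacobian_fn function of `z` returning the Jacobian matrix.
#' @param z0 initial guess.
#' @param eps_nr tolerance on the max-norm of the Newton update.
#' @param max_it iteration cap.
#' @return the solution vector with attribute `iterations`.
#' @export
newton_raphson <- function(residual_fn, jacobian_fn, z0, eps_nr = 1e-6,
                           max_it = 1e4) {
  z <- as.numeric(z0)
  fac <- lu_factor(rbind(jacobian_fn(z)))
  prev_norm <- -1
  stagnant <- 0L
  refactorized <- FALSE
  for (it in seq_len(max_it)) {
    G <- as.numeric(residual_fn(z))
    if (any(!is.finite(G))) {
      stop("non-finite residual in Newton-Raphson iteration", call. = FALSE)
    }
    step <- lu_solve(fac, G)
    z <- z - step
    nrm <- max(abs(step))
    if (nrm < eps_nr) {
      return(structure(z, iterations = it))
    }
    if (prev_norm > 0 && nrm > 0.9 * prev_norm) {
      stagnant <- stagnant + 1L
      if (stagnant >= 3L) {
        if (refactorized) break
        fac <- lu_factor(rbind(jacobian_fn(z)))
        refactorized <- TRUE
        stagnant <- 0L
        prev_norm <- -1
        next
      }
    } else {
      stagnant <- 0L
    }
    prev_norm <- nrm
  }
  stop(sprintf("Newton-Raphson did not converge within %d iterations",
               as.integer(max_it)), call. = FALSE)
}

#' LU factorization with partial pivoting
#'
#' Thin wrapper around the dense LU factorization of the Matrix package;
#' the returned object can be passed to [lu_solve()] repeatedly, so one
#' factorization serves many right-hand sides (as the modified Newton
#' scheme requires).
#'
#' @param A square numeric matrix.
#' @return an object of class `lu_factorization`.
#' @export
lu_factor <- function(A) {
  A <- rbind(A)
  if (nrow(A) != ncol(A)) stop("matrix must be square", call. = FALSE)
  if (any(!is.finite(A))) stop("matrix must be finite", call. = FALSE)
  # build a general dense Matrix explicitly: Matrix() would specialize
  # diagonal/triangular inputs to classes whose lu() methods differ
  Ag <- methods::new("dgeMatrix", x = as.double(A), Dim = dim(A))
  f <- tryCatch(Matrix::lu(Ag),
                error = function(e) stop("singular matrix", call. = FALSE),
                warning = function(w) stop("singular matrix", call. = FALSE))
  ex <- Matrix::expand(f)
  d <- Matrix::diag(ex$U)
  if (any(abs(d) < .Machine$double.eps * max(abs(d), 1) * nrow(A))) {
    stop("singular matrix", call. = FALSE)
  }
  structure(list(factor = f, n = nrow(A)), class = "lu_factorization")
}

#' Solve a linear system via LU with partial pivoting
#'
#' @param A a square matrix, or a factorization from [lu_factor()].
#' @param b right-hand-side vector (or matrix of columns).
#' @return the solution of `A x = b`.
#' @export
lu_solve <- function(A, b) {
  fac <- if (inherits(A, "lu_factorization")) A else lu_factor(A)
  if (length(b) %% fac$n != 0 && NROW(b) != fac$n) {
    stop("right-hand side length does not match the matrix", call. = FALSE)
  }
  as.numeric(Matrix::solve(fac$factor, b))
}
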