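# Shared fixtures (built in code) and independent oracles.

# R1: X1 + X2 -(k1)-> X3,  R2: X3 -(k2)-> X1 + X2; the worked example whose
# species-1 ODE is -k1*X1*X2 + k2*X3.
two_reaction_model <- function(k = c(2, 3), x0 = c(1, 0.5, 2)) {
  new_reaction_model(
    reactant_matrix = rbind(c(1, 1, 0), c(0, 0, 1)),
    product_matrix = rbind(c(0, 0, 1), c(1, 1, 0)),
    kinetic_constants = k, initial_state = x0, sampling_times = c(0, 50)
  )
}

# unimolecular decay X1 -(k)-> X2
decay_model <- function(k = 1, x0 = 1, t_max = 50) {
  new_reaction_model(rbind(c(1, 0)), rbind(c(0, 1)), k, c(x0, 0), c(0, t_max))
}

# reversible isomerization A <=> B
ab_model <- function(k1 = 1, k2 = 1, x0 = c(1, 0), times = c(0, 25, 50)) {
  new_reaction_model(rbind(c(1, 0), c(0, 1)), rbind(c(0, 1), c(1, 0)),
                     c(k1, k2), x0, times)
}

# isomerization chain A -> B -> C -> D (closed conversion network)
chain_model <- function(k = c(1, 0.5, 0.25), times = seq(0, 50, length.out = 11)) {
  A <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  B <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  new_reaction_model(A, B, k, c(1, 0, 0, 0), times)
}

# two-timescale model: fast pair A <=> B (k = 1e4), slow pair C <=> D (k = 1e-2)
two_timescale_model <- function(times = seq(0, 50, length.out = 11)) {
  A <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  B <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 0))
  new_reaction_model(A, B, c(1e4, 1e4, 1e-2, 1e-2), c(1, 0, 1, 0), times)
}

# dense brute-force right-hand side dX/dt = (B - A)^T (K o X^A), evaluated
# entry by entry with explicit matrices; independent of the compressed path
dense_derivatives <- function(model, X) {
  A <- model$reactant_matrix
  rates <- model$kinetic_constants * apply(A, 1, function(a) prod(X^a))
  as.numeric(t(model$product_matrix - A) %*% rates)
}

# central finite-difference Jacobian of the dense right-hand side
fd_jacobian <- function(model, X, h = 1e-6) {
  N <- length(X)
  J <- matrix(0, N, N)
  for (r in seq_len(N)) {
    e <- numeric(N)
    e[r] <- h
    J[, r] <- (dense_derivatives(model, X + e) - dense_derivatives(model, X - e)) / (2 * h)
  }
  J
}

# reference trajectory from an independent stiff/non-stiff solver (LSODA)
# driven by the dense right-hand side
lsoda_reference <- function(model, rtol = 1e-10, atol = 1e-14) {
  rhs <- function(t, X, p) list(dense_derivatives(p, X))
  out <- deSolve::lsoda(model$initial_state, model$sampling_times, rhs, model,
                        rtol = rtol, atol = atol, maxsteps = 100000)
  states <- as.matrix(out[, -1, drop = FALSE])
  colnames(states) <- model$species_names
  list(times = model$sampling_times, states = states)
}

# BDF coefficients derived independently from the polynomial exactness
# conditions: with nodes 0, -1, ..., -q (in units of dt) and alpha_0 = 1,
# sum_i alpha_i p(-i) = beta_0 p'(0) for every polynomial p of degree <= q.
bdf_coefficients_oracle <- function(q) {
  # unknowns: alpha_1..alpha_q, beta_0; equations from p = x^m, m = 0..q
  Amat <- matrix(0, q + 1, q + 1)
  rhs <- numeric(q + 1)
  for (m in 0:q) {
    for (i in 1:q) Amat[m + 1, i] <- (-i)^m
    Amat[m + 1, q + 1] <- -(if (m == 1) 1 else 0)
    rhs[m + 1] <- -(if (m == 0) 1 else 0)  # alpha_0 * 0^m term moved across
  }
  sol <- solve(Amat, rhs)
  list(alphas = c(1, sol[1:q]), beta0 = sol[q + 1])
}

max_rel_dev <- function(a, b, atol = 1e-8) {
  max(abs(a - b) / pmax(abs(a), abs(b), atol))
}
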