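test_that("a single explicit step has six stages and fourth/fifth order accuracy", {
  enc <- build_encoding(decay_model())
  res <- rkf_step(enc, c(1, 0), dt = 0.1)
  expect_equal(ncol(res$stages), 6)
  expect_equal(nrow(res$stages), 2)
  # stage 1 is the derivative at the current state: dX1/dt = -X1
  expect_equal(res$stages[, 1], c(-1, 1))
  # the candidate state is the fifth-order member of the pair
  expect_lt(abs(res$u[1] - exp(-0.1)), 1e-7)
  expect_lt(abs(res$u[1] - exp(-0.1)), abs(res$w[1] - exp(-0.1)))
  # ER is |w - u| / dt (evaluated from the stage combination, which agrees
  # with the naive difference up to cancellation round-off)
  expect_lt(max(abs(res$ER - abs(res$w - res$u) / 0.1)), 1e-13)
})

test_that("at an exact equilibrium the step is a fixed point with zero error", {
  # A <=> B with X_A k1 = X_B k2 at X = (0.5, 1), k = (2, 1)
  enc <- build_encoding(ab_model(k1 = 2, k2 = 1))
  X <- c(0.5, 1)
  res <- rkf_step(enc, X, dt = 0.3, eps = 1e-12)
  expect_identical(res$u, X)
  expect_identical(res$w, X)
  expect_identical(res$ER, c(0, 0))
  expect_equal(res$delta, c(4, 4))  # capped at delta_max
})

test_that("the error measure scales as the fourth power of the step size", {
  # smooth nonlinear test model: dimerization + back-reaction
  m <- new_reaction_model(rbind(c(2, 0), c(0, 1)), rbind(c(0, 1), c(2, 0)),
                          c(1, 0.5), c(1, 0.2), c(0, 1))
  enc <- build_encoding(m)
  X <- c(1, 0.2)
  er1 <- max(rkf_step(enc, X, dt = 0.2)$ER)
  er2 <- max(rkf_step(enc, X, dt = 0.1)$ER)
  ratio <- er1 / er2
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("the controller formula gives 0.84 at the tolerance and caps at zero error", {
  # construct |w - u| = dt * eps so that ER = eps exactly in floating point
  dt <- 0.25
  eps <- c(1e-12, 1e-10)
  u <- c(0, 0)
  w <- u + dt * eps
  out <- error_and_delta(u, w, dt, eps)
  expect_identical(out$ER, eps)
  expect_equal(out$delta, c(0.84, 0.84))
  # eps = 16 ER -> delta = 0.84 * 2
  out2 <- error_and_delta(u, u + dt * eps / 16, dt, eps)
  expect_equal(out2$delta, c(1.68, 1.68))
  # w = u -> ER = 0, delta capped
  out3 <- error_and_delta(u, u, dt, eps, delta_max = 4)
  expect_equal(out3$ER, c(0, 0))
  expect_equal(out3$delta, c(4, 4))
})

test_that("step control accepts, retries, or declares stiffness", {
  enc <- build_encoding(decay_model())
  res <- rkf_step(enc, c(1, 0), dt = 0.01)
  # loose tolerance: accept with the candidate state
  dec <- step_control(res, eps = 1e-6, dt = 0.01, eps_s = 1e-6)
  expect_equal(dec$action, "accept")
  expect_identical(dec$state, res$u)
  expect_gt(dec$dt, 0.01)  # the step is allowed to grow after acceptance
  # impossible tolerance, shrunken retry still above the threshold: retry
  dec2 <- step_control(res, eps = 1e-30, dt = 0.01, eps_s = 1e-12)
  expect_equal(dec2$action, "retry")
  expect_null(dec2$state)
  expect_equal(dec2$dt, 0.01 * min(0.84 * (1e-30 / res$ER)^0.25))
  # the same rejection with a high threshold: switch to implicit integration
  dec3 <- step_control(res, eps = 1e-30, dt = 0.01, eps_s = 1)
  expect_equal(dec3$action, "switch_to_bdf")
})

test_that("BDF coefficients match the polynomial-exactness oracle for q = 1..6", {
  for (q in 1:6) {
    got <- bdf_coefficients(q)
    ora <- bdf_coefficients_oracle(q)
    expect_equal(got$alphas, ora$alphas, tolerance = 1e-12)
    expect_equal(got$beta0, ora$beta0, tolerance = 1e-12)
    # exact identities: sum alpha_i = 0 and beta_0 = -sum i alpha_i
    expect_equal(sum(got$alphas), 0, tolerance = 1e-15)
    expect_equal(got$beta0, -sum(seq_along(got$alphas[-1]) * got$alphas[-1]),
                 tolerance = 1e-14)
    expect_equal(got$alphas[1], 1)
  }
  expect_equal(bdf_coefficients(1)$alphas, c(1, -1))  # backward Euler
  expect_equal(bdf_coefficients(2)$alphas, c(1, -4 / 3, 1 / 3))
  expect_equal(bdf_coefficients(2)$beta0, 2 / 3)
  expect_error(bdf_coefficients(7), "1..6")
  expect_error(bdf_coefficients(0), "1..6")
})

test_that("an implicit Euler step on linear decay matches the closed form", {
  enc <- build_encoding(decay_model(k = 1))
  z <- bdf_step(enc, history = rbind(c(1, 0)), dt = 0.1, q = 1)
  # (I - dt J)^{-1} X: X1 = 1 / 1.1
  expect_equal(z[1], 1 / 1.1, tolerance = 1e-14)
  expect_equal(z[1] + z[2], 1 / 1.1 + (1 - 1 / 1.1) / 1 * 1, tolerance = 1e-10)
  # linear problem: Newton converges essentially immediately
  expect_lte(attr(z, "iterations"), 2)
})

test_that("a second-order BDF step on linear decay matches the scalar recurrence", {
  k <- 1
  dt <- 0.1
  enc <- build_encoding(decay_model(k = k))
  x_n <- exp(-dt)      # exact states as uniform history
  x_nm1 <- 1
  hist <- rbind(c(x_n, 1 - x_n), c(x_nm1, 1 - x_nm1))
  z <- bdf_step(enc, hist, dt = dt, q = 2)
  closed <- (4 / 3 * x_n - 1 / 3 * x_nm1) / (1 + (2 / 3) * k * dt)
  expect_equal(z[1], closed, tolerance = 1e-12)
})

test_that("a BDF step from an exact equilibrium returns the equilibrium", {
  enc <- build_encoding(ab_model(k1 = 2, k2 = 1))
  X <- c(0.5, 1)
  for (q in c(1, 3)) {
    z <- bdf_step(enc, history = matrix(rep(X, q), nrow = q, byrow = TRUE),
                  dt = 0.5, q = q)
    expect_equal(as.numeric(z), X, tolerance = 1e-12)
  }
})

test_that("repeated implicit Euler steps converge at first order in the step size", {
  enc <- build_encoding(decay_model(k = 1))
  run <- function(dt) {
    X <- c(1, 0)
    for (i in seq_len(round(1 / dt))) {
      X <- as.numeric(bdf_step(enc, rbind(X), dt = dt, q = 1, eps_nr = 1e-12))
    }
    abs(X[1] - exp(-1))
  }
  ratio <- run(0.02) / run(0.01)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("Newton-Raphson with a frozen Jacobian finds roots and honours its cap", {
  # 1-D: G(z) = z^2 - 4 from z0 = 3
  root <- newton_raphson(function(z) z^2 - 4, function(z) 2 * z, 3,
                         eps_nr = 1e-6)
  expect_equal(as.numeric(root), 2, tolerance = 1e-5)
  # already at a root: returns after one zero-update iteration
  at_root <- newton_raphson(function(z) z^2 - 4, function(z) 2 * z, 2)
  expect_identical(as.numeric(at_root), 2)
  expect_equal(attr(at_root, "iterations"), 1)
  # 2-D nonlinear system
  G <- function(z) c(z[1]^2 + z[2]^2 - 5, z[1] * z[2] - 2)
  Jf <- function(z) rbind(c(2 * z[1], 2 * z[2]), c(z[2], z[1]))
  sol <- newton_raphson(G, Jf, c(2.2, 0.8), eps_nr = 1e-10)
  expect_equal(as.numeric(sol), c(2, 1), tolerance = 1e-8)
  # iteration cap from a poor guess
  expect_error(newton_raphson(function(z) z^2 - 4, function(z) 2 * z, 50,
                              eps_nr = 1e-12, max_it = 1),
               "did not converge")
})

test_that("LU solves with partial pivoting and reports singular systems", {
  expect_equal(lu_solve(diag(3), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(lu_solve(rbind(c(2, 0), c(0, 4)), c(2, 8)), c(1, 2))
  # a factorization is reusable across right-hand sides
  A <- rbind(c(0, 2, 1), c(1, 1, 0), c(3, 0, 1))  # needs pivoting (zero pivot)
  fac <- lu_factor(A)
  for (b in list(c(1, 0, 0), c(0, 1, 0), c(4, -2, 1))) {
    expect_equal(as.numeric(A %*% lu_solve(fac, b)), b, tolerance = 1e-12)
  }
  expect_error(lu_factor(rbind(c(1, 2), c(2, 4))), "singular")
  expect_error(lu_factor(rbind(c(1, 2, 3), c(4, 5, 6))), "square")
})
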