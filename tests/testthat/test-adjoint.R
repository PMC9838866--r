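# Standard adjoint: measurement jumps, backward integration, quadratures.

test_that("measurement jumps accumulate observable-wise residual terms", {
  m <- pd_model()
  th <- c(2, 1); u <- c(w = 1)
  # zero residual: unchanged
  expect_equal(measurement_jump(c(0.3), m, 2, th, u,
                                data.frame(obs_idx = 1L, residual = 0, sigma = 1)),
               0.3)
  # unit case
  expect_equal(measurement_jump(0, m, 2, th, u,
                                data.frame(obs_idx = 1L, residual = 1, sigma = 1)),
               1)
  # two observables h = (x1, x1 + x2), residuals (1, 2): jump = (3, 2)
  m2 <- compile_model(parse_model(list(
    species = list("x1", "x2"), parameters = list("k"),
    odes = list(x1 = "-k*x1", x2 = "-k*x2"),
    observables = list(y1 = "x1", y2 = "x1 + x2"))))
  jump <- measurement_jump(c(0, 0), m2, c(1, 1), 1, NULL,
                           data.frame(obs_idx = c(1L, 2L), residual = c(1, 2),
                                      sigma = 1))
  expect_equal(jump, c(3, 2))
  expect_error(measurement_jump(0, m, 2, th, u,
                                data.frame(obs_idx = 1L, residual = 1, sigma = 0)),
               class = "steadygrad_degenerate_noise")
})

test_that("backward pass with zero adjoint and no data stays exactly zero", {
  m <- pd_model()
  th <- c(2, 1); u <- c(w = 1)
  traj <- steadygrad:::make_trajectory(m, th, u,
                                       seq(0, 5, length.out = 21),
                                       matrix(2, 21, 1))
  bw <- backward_pass(m, traj, th, u,
                      data.frame(time = numeric(0), obs_idx = integer(0),
                                 residual = numeric(0), sigma = numeric(0)),
                      5, 0, 0)
  expect_identical(bw$p, 0)
  expect_identical(bw$q, c(0, 0))
})

test_that("scalar adjoint follows the linear closed form with its quadrature", {
  # xdot = -k x with the exact solution x(t) = x0 exp(-k t) as trajectory:
  # J = -k, so p(t) = p0 exp(-k (T - t)) backward from p(T) = p0, and
  # q(0) = -int_0^T p (df/dk) dt = int_0^T p(t) x(t) dt = p0 x0 T exp(-k T)
  # (the integrand is constant).
  m <- compile_model(parse_model(list(
    species = list("x"), parameters = list("k"),
    reactions = list("x -> 0 at k*x"), initials = list(x = "1"))))
  k <- 1; x0 <- 0.7; T <- 3; p0 <- 1.3
  times <- seq(0, T, length.out = 61)
  traj <- steadygrad:::make_trajectory(m, k, NULL, times,
                                       matrix(x0 * exp(-k * times), ncol = 1))
  bw <- backward_pass(m, traj, k, NULL,
                      data.frame(time = numeric(0), obs_idx = integer(0),
                                 residual = numeric(0), sigma = numeric(0)),
                      T, 0, p0)
  expect_lt(abs(bw$p - p0 * exp(-k * T)), 1e-8)
  expect_lt(abs(bw$q - p0 * x0 * T * exp(-k * T)), 1e-8)
})

test_that("zero residuals give a zero gradient through the long-simulation adjoint", {
  prob <- pd_ss_problem()
  prob$measurements$measurement <- 2  # equals xms* exactly
  g <- asa_gradient_longsim(prob)
  expect_lt(max(abs(g$gradient)), 1e-7)
})

test_that("long-simulation adjoint reproduces the closed-form steady-state gradient", {
  g <- asa_gradient_longsim(pd_ss_problem())
  expect_lt(rel_err(g$gradient_linear, c(-1, 2)), 1e-6)
  expect_gt(g$counters$backward_rhs_equil, 0)
})

test_that("long-simulation adjoint matches finite differences on a seeded linear network", {
  fx <- make_fixture(fixture_spec("linear_network", seed = 42, n_x = 5,
                                  sigma = 0.05, n_timepoints = 4,
                                  equilibration = "post"))
  ga <- asa_gradient_longsim(fx$problem, fx$theta_true_est)
  gf <- objective_gradient(fx$problem, fx$theta_true_est, method = "fd")
  expect_lt(rel_err(ga$gradient, gf$gradient), 1e-4)
})
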