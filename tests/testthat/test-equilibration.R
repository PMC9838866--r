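# Weighted-residual convergence test and steady-state equilibration.

test_that("weighted residual evaluates the printed criterion", {
  expect_equal(wrms_residual(c(0, 0), c(1, 2), 1e-8, 1e-16), 0)
  expect_equal(wrms_residual(0.5, 1, rtol = 1, atol = 0), 0.25)
  expect_equal(wrms_residual(c(2, 0), c(1, 1), rtol = 1, atol = 0), 2)
  expect_error(wrms_residual(1, 0, rtol = 1, atol = 0),
               class = "steadygrad_degenerate_weight")
})

test_that("production-degradation equilibrates to k_in/k_out", {
  m <- pd_model()
  eq <- equilibrate(m, c(k_in = 2, k_out = 1), c(w = 1), x_init = 0)
  expect_lt(abs(eq$x_star - 2), 1e-6 * 2)
  expect_lt(eq$wrms, 1)
  expect_gt(eq$n_rhs_evals, 0)
})

test_that("a state already at steady state returns immediately", {
  m <- pd_model()
  eq <- equilibrate(m, c(2, 1), c(w = 1), x_init = 2)
  expect_equal(eq$t_equil, 0)
  expect_equal(eq$x_star, 2)
  expect_equal(eq$n_rhs_evals, 0L)
})

test_that("reduced conversion model equilibrates to k2*T/(k1+k2)", {
  red <- reduce_model(compile_model(conv_network()))
  eq <- equilibrate(red, c(k1 = 2, k2 = 1, a0 = 1))
  expect_lt(abs(eq$x_star - 1 / 3), 1e-6)
  # oracle: long fixed-horizon integration
  sol <- steadygrad:::integrate_states(red, c(2, 1, 1), NULL, red$x0(c(2, 1, 1)),
                                       c(0, 50), gradient_settings())
  expect_lt(abs(eq$x_star - sol$states[2, 1]), 1e-8)
})

test_that("pre-equilibration under scaled input gives the scaled steady state", {
  m <- pd_model()
  cond <- sg_condition("c1", u = c(w = 1), u_pre = c(w = 0.5))
  eq <- steady_state_for_condition(m, c(k_in = 2, k_out = 1), cond, phase = "pre")
  expect_lt(abs(eq$x_star - 1), 1e-6)
})

test_that("conditions without equilibration flags are rejected", {
  m <- pd_model()
  cond <- sg_condition("c1", u = c(w = 1))
  expect_error(steady_state_for_condition(m, c(2, 1), cond, phase = "pre"),
               class = "steadygrad_noop_error")
})

test_that("stable linear systems equilibrate to the direct solve -A^-1 b", {
  for (seed in c(42, 43, 44, 45, 46)) {
    fx <- make_model(fixture_spec("linear_network", seed = seed, n_x = 4))
    m <- fx$model
    th <- fx$theta_true
    u <- c(w = 1)
    A <- m$jac(numeric(4), th, u)       # linear: Jacobian is A everywhere
    b <- m$f(numeric(4), th, u)         # f(0) = b*w
    x_direct <- solve(A, -b)
    eq <- equilibrate(m, th, u, x_init = numeric(4))
    expect_lt(rel_err(eq$x_star, x_direct), 1e-6)
    # generation-time stability assumption holds
    expect_true(all(Re(eigen(A, only.values = TRUE)$values) < 0))
  }
})

test_that("Newton polish never increases the weighted residual", {
  m <- make_model(fixture_spec("mm_chain"))$model
  th <- c(k_in = 0.8, V1 = 1, K1 = 0.5, V2 = 0.9, K2 = 0.4, k3 = 0.3)
  no_polish <- gradient_settings(newton_polish = FALSE)
  eq_sim <- equilibrate(m, th, c(w = 1), settings = no_polish)
  eq_pol <- equilibrate(m, th, c(w = 1))
  expect_lte(eq_pol$wrms, eq_sim$wrms)
  expect_equal(eq_pol$method, "simulation+newton")
  expect_equal(eq_sim$method, "simulation")
})

test_that("a system without a steady state fails with diagnostics", {
  m <- compile_model(parse_model(list(
    species = list("x"), parameters = list("k"),
    reactions = list("0 -> x at k"), initials = list(x = "0"))))
  expect_error(
    equilibrate(m, c(k = 1), settings = gradient_settings(max_doublings = 3)),
    "wrms", class = "steadygrad_equilibration_failure")
})

test_that("equilibration honours a minimum horizon", {
  m <- pd_model()
  eq <- equilibrate(m, c(2, 1), c(w = 1), x_init = 2,
                    settings = gradient_settings(t_min_equil = 25))
  expect_gte(eq$t_equil, 25)
})
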