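# Steady-state adjoint: linear-solve contributions and full gradients.

test_that("post-equilibration contribution solves the 1x1 system by hand", {
  m <- pd_model()
  th <- c(k_in = 2, k_out = 1); u <- c(w = 1)
  ss_rows <- data.frame(obs_idx = 1L, residual = 1, sigma = 1)  # ybar*=3, y*=2
  post <- posteq_adjoint_contribution(m, 2, th, u, ss_rows)
  expect_equal(post$p_boundary, 1)
  expect_equal(post$p_integral, 1)      # (-1) p_int = -1
  expect_equal(post$gradient, c(-1, 2)) # -p_int^T (1, -x*)
  expect_equal(post$p_carry, 0)
  expect_lt(post$residual, 1e-12)
})

test_that("zero steady-state residuals give zero boundary, integral and contribution", {
  m <- pd_model()
  post <- posteq_adjoint_contribution(m, 2, c(2, 1), c(w = 1),
                                      data.frame(obs_idx = 1L, residual = 0,
                                                 sigma = 1))
  expect_equal(post$p_boundary, 0)
  expect_equal(post$p_integral, 0)
  expect_equal(post$gradient, c(0, 0))
})

test_that("identity-Jacobian case maps the boundary value straight through", {
  # xdot_i = b_i - x_i: Jacobian = -I for any state
  m <- compile_model(parse_model(list(
    species = list("x1", "x2", "x3"), parameters = list("b1", "b2", "b3"),
    odes = list(x1 = "b1 - x1", x2 = "b2 - x2", x3 = "b3 - x3"),
    observables = list(y1 = "x1", y2 = "x2", y3 = "x3"))))
  v <- c(0.3, -1.2, 2)
  post <- posteq_adjoint_contribution(m, c(1, 1, 1), c(1, 1, 1), NULL,
                                      data.frame(obs_idx = 1:3, residual = v,
                                                 sigma = 1))
  expect_equal(post$p_boundary, v)
  expect_equal(post$p_integral, v)
})

test_that("pre-equilibration contribution solves in the pre-equilibration Jacobian", {
  m <- pd_model()
  th <- c(k_in = 2, k_out = 1)
  u_pre <- c(w = 0.5)
  x_star_pre <- 1  # k_in*0.5/k_out
  p_t0 <- 0.8
  pre <- preeq_adjoint_contribution(m, x_star_pre, th, u_pre, p_t0)
  expect_equal(pre$p_integral, p_t0 / th["k_out"], ignore_attr = TRUE)
  # -p_int^T df/dtheta at (x*_pre, u_pre): df/dtheta = (w, -x) = (0.5, -1)
  expect_equal(pre$gradient, c(-0.8 * 0.5, 0.8 * 1))
})

test_that("ssASA equals the standard adjoint when nothing equilibrates", {
  fx <- make_fixture(fixture_spec("linear_network", seed = 9, n_x = 3,
                                  sigma = 0.05, n_timepoints = 5,
                                  equilibration = "none"))
  gs <- ssasa_gradient(fx$problem, fx$theta_true_est)
  ga <- asa_gradient_longsim(fx$problem, fx$theta_true_est)
  expect_lt(rel_err(gs$gradient, ga$gradient), 1e-12)
  expect_equal(gs$counters$backward_rhs_equil, 0L)
  expect_equal(ga$counters$backward_rhs_equil, 0L)
})

test_that("ssASA matches the oracles on the nonlinear chain with pre- and post-equilibration", {
  fx <- make_fixture(fixture_spec("mm_chain", seed = 2, sigma = 0.05,
                                  n_timepoints = 4, equilibration = "both"))
  gs <- ssasa_gradient(fx$problem, fx$theta_true_est)
  gf <- forward_gradient(fx$problem, fx$theta_true_est)
  gd <- objective_gradient(fx$problem, fx$theta_true_est, method = "fd")
  expect_lt(rel_err(gs$gradient, gf$gradient), 1e-6)
  expect_lt(rel_err(gs$gradient, gd$gradient), 1e-4)
})

test_that("every steady-state linear solve meets the residual bound", {
  for (fx in get_suite()[c("pd_post", "lin3_both", "mm_both")]) {
    g <- ssasa_gradient(fx$problem, fx$theta_true_est)
    if (nrow(g$solves) == 0) next
    expect_true(all(g$solves$residual <=
                      1e-10 * (1 + g$solves$norm_p_boundary)))
  }
})

test_that("zero data residuals give an exactly zero ssASA gradient", {
  fx <- make_fixture(fixture_spec("mm_chain", seed = 3, sigma = 0,
                                  n_timepoints = 3, equilibration = "both"))
  g <- ssasa_gradient(fx$problem, fx$theta_true_est)
  expect_lt(max(abs(g$gradient)), 1e-10)
})

test_that("ssASA does no backward work over equilibration spans; the reference does", {
  fx <- get_suite()$mm_both
  gs <- ssasa_gradient(fx$problem, fx$theta_true_est)
  ga <- asa_gradient_longsim(fx$problem, fx$theta_true_est)
  expect_equal(gs$counters$backward_rhs_equil, 0L)
  expect_gt(ga$counters$backward_rhs_equil, 0L)
  expect_lt(gs$counters$backward_rhs_total, ga$counters$backward_rhs_total)
})

test_that("the reference adjoint converges to ssASA as the equilibration tail doubles", {
  fx <- make_fixture(fixture_spec("linear_network", seed = 21, n_x = 4,
                                  sigma = 0.05, n_timepoints = 3,
                                  equilibration = "post"))
  loose <- gradient_settings(ss_rtol = 1e-2, ss_atol = 1e-8)
  gs <- ssasa_gradient(fx$problem, fx$theta_true_est, settings = loose)
  diffs <- vapply(c(5, 10, 20, 40, 80), function(tmin) {
    sett <- gradient_settings(ss_rtol = 1e-2, ss_atol = 1e-8, t_min_equil = tmin)
    ga <- asa_gradient_longsim(fx$problem, fx$theta_true_est, settings = sett)
    max(abs(ga$gradient - gs$gradient))
  }, numeric(1))
  expect_lt(diffs[length(diffs)], 1e-5)
  expect_lt(diffs[length(diffs)], diffs[1])
})

test_that("a singular steady-state Jacobian raises unless the fallback is allowed", {
  fx <- make_fixture(fixture_spec("conversion", sigma = 0.05, n_timepoints = 3,
                                  equilibration = "post"))
  full_prob <- sg_problem(fx$model_full, fx$measurements,
                          conditions = fx$conditions,
                          parameters = fx$parameters)
  suppressWarnings(
    expect_error(ssasa_gradient(full_prob, fx$theta_true_est),
                 class = "steadygrad_singular_jacobian"))
  sett <- gradient_settings(allow_asa_fallback = TRUE)
  g_fb <- suppressWarnings(
    ssasa_gradient(full_prob, fx$theta_true_est, settings = sett))
  expect_match(g_fb$per_condition[["c1"]], "asa-fallback")
  g_ref <- suppressWarnings(
    asa_gradient_longsim(full_prob, fx$theta_true_est))
  expect_lt(rel_err(g_fb$gradient, g_ref$gradient), 1e-4)
})

test_that("steady-state Jacobians of the fixture suite are Hurwitz", {
  for (fx in get_suite()) {
    m <- fx$problem$model
    for (cond in fx$problem$conditions) {
      eq <- equilibrate(m, fx$theta_true, cond$u)
      ev <- eigen(m$jac(eq$x_star, fx$theta_true, cond$u), only.values = TRUE)$values
      expect_true(all(Re(ev) < 0))
    }
  }
})
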