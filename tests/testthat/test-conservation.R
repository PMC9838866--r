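# Conserved-moiety detection, model reduction, nonsingularity checks.

test_that("left null space of simple stoichiometries is found exactly", {
  an <- find_conserved_quantities(matrix(c(-1, 1, 1, -1), 2))
  expect_equal(an$n_c, 1L)
  expect_equal(unname(an$L), matrix(c(1, 1), 1))
  expect_equal(an$eliminated_indices, 2L)  # tie broken to highest index

  an2 <- find_conserved_quantities(matrix(c(1, 0), 2, 1))
  expect_equal(an2$n_c, 1L)
  expect_equal(unname(an2$L), matrix(c(0, 1), 1))
})

test_that("full-row-rank stoichiometry has no conserved law (rank by QR oracle)", {
  set.seed(11)
  repeat {
    S <- matrix(sample(-3:3, 40, replace = TRUE), 5, 8)
    if (qr(S)$rank == 5L) break
  }
  expect_equal(find_conserved_quantities(S)$n_c, 0L)
})

test_that("L S = 0 holds exactly for every detected law", {
  set.seed(3)
  for (rep in 1:20) {
    n_x <- sample(3:6, 1)
    n_r <- sample(1:4, 1)
    S <- matrix(sample(-2:2, n_x * n_r, replace = TRUE), n_x, n_r)
    an <- find_conserved_quantities(S)
    if (an$n_c > 0) expect_equal(max(abs(an$L %*% S)), 0)
    expect_equal(an$n_c, n_x - qr(S)$rank)
  }
})

test_that("conversion reaction reduces to a one-state model with the hand-derived RHS", {
  full <- compile_model(conv_network())
  red <- reduce_model(full)
  th <- c(k1 = 2, k2 = 1, a0 = 1)
  expect_equal(red$n_x, 1L)
  expect_equal(red$species, "A")
  # f_A = -k1 A + k2 (T - A), T = a0
  for (A in c(0.1, 0.5, 0.9))
    expect_equal(red$f(A, th), -2 * A + 1 * (1 - A))
  expect_equal(red$jac(0.5, th), matrix(-(2 + 1), 1, 1))
  # observables survive substitution: obs_B = a0 - A
  expect_equal(red$h(0.4, th), c(0.4, 0.6))
})

test_that("reduction is the identity when there is nothing to reduce", {
  m <- make_model(fixture_spec("mm_chain"))$model_full
  expect_identical(reduce_model(m), m)
})

test_that("totals inherit parameter dependence through x0", {
  red <- reduce_model(compile_model(conv_network()))
  th <- c(k1 = 2, k2 = 1, a0 = 1.7)
  fd <- fd_jacobian(function(tt) red$f(0.4, tt), th)
  expect_lt(rel_err(red$dfdtheta(0.4, th), fd), 1e-6)
  fd0 <- fd_jacobian(function(tt) red$x0(tt), th)
  expect_lt(rel_err(red$dx0dtheta(th), fd0), 1e-6)
})

test_that("full and reduced models simulate identically on kept states", {
  full <- compile_model(conv_network())
  red <- reduce_model(full)
  set.seed(5)
  sett <- gradient_settings()
  for (rep in 1:12) {
    th <- runif(3, 0.3, 3)
    times <- seq(0, 4, length.out = 9)
    solf <- steadygrad:::integrate_states(full, th, NULL, full$x0(th), times, sett)
    solr <- steadygrad:::integrate_states(red, th, NULL, red$x0(th), times, sett)
    expect_lt(max(abs(solf$states[, 1] - solr$states[, 1])), 1e-8)
    # conserved total constant along the full trajectory
    expect_lt(max(abs(rowSums(solf$states) - (th[3]))), 1e-8)
  }
})

test_that("reduced-model gradient matches full-model finite differences", {
  fx <- make_fixture(fixture_spec("conversion", sigma = 0.05, n_timepoints = 4,
                                  equilibration = "post"))
  # full-model problem shares data; the objective is reduction-invariant
  full_prob <- sg_problem(fx$model_full, fx$measurements,
                          conditions = fx$conditions, parameters = fx$parameters)
  g_red <- ssasa_gradient(fx$problem, fx$theta_true_est)
  # the full model has a singular Jacobian, so its equilibration warns that
  # the Newton polish is unavailable; the simulation result is used
  g_fd_full <- suppressWarnings(
    objective_gradient(full_prob, fx$theta_true_est, method = "fd"))
  expect_lt(rel_err(g_red$gradient, g_fd_full$gradient), 1e-4)
})

test_that("nonsingularity assertion accepts and rejects correctly", {
  expect_error(assert_nonsingular(matrix(c(-1, 1, 1, -1), 2)),
               "conserved", class = "steadygrad_singular_jacobian")
  expect_equal(assert_nonsingular(-diag(3)), 1, ignore_attr = TRUE)
  full <- compile_model(conv_network())
  red <- reduce_model(full)
  th <- c(k1 = 2, k2 = 1, a0 = 1)
  xs <- c(1 / 3, 2 / 3)
  expect_error(assert_nonsingular(full$jac(xs, th)),
               class = "steadygrad_singular_jacobian")
  expect_no_error(assert_nonsingular(red$jac(1 / 3, th)))
})

test_that("conservation report tabulates laws and per-condition totals", {
  net <- conv_network()
  an <- find_conserved_quantities(net$S, net)
  df <- conservation_report(an, model = compile_model(net),
                            theta = c(k1 = 2, k2 = 1, a0 = 1.5),
                            conditions = list(c1 = NULL))
  expect_equal(df$law, 1L)
  expect_equal(df$total.c1, 1.5)
})
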