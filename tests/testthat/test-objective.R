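# Negative log-likelihood, gradient assembly, multi-start estimation.

test_that("negative log-likelihood matches direct arithmetic", {
  tab1 <- data.frame(measurement = 1, sd = 1)
  expect_equal(negative_log_likelihood(1, tab1)$nll, 0.5 * log(2 * pi))
  expect_equal(negative_log_likelihood(1, tab1)$nll, 0.9189385, tolerance = 1e-6)
  expect_equal(negative_log_likelihood(0, tab1)$nll, 0.5 * log(2 * pi) + 0.5)
  expect_equal(negative_log_likelihood(0, tab1)$nll, 1.4189385, tolerance = 1e-6)
  expect_equal(negative_log_likelihood(numeric(0),
                                       tab1[0, , drop = FALSE])$nll, 0)
  expect_error(negative_log_likelihood(NA_real_, tab1),
               "row 1", class = "steadygrad_assembly_error")
})

test_that("objective is additive over conditions and measurement rows", {
  fx <- get_suite()$pd_post
  meas <- fx$problem$measurements
  meas2 <- rbind(meas, transform(meas, conditionId = "c2"))
  prob2 <- sg_problem(fx$problem$model, meas2,
                      conditions = list(sg_condition("c1", u = c(w = 1)),
                                        sg_condition("c2", u = c(w = 1))),
                      parameters = fx$parameters)
  g1 <- ssasa_gradient(fx$problem, fx$theta_true_est)
  g2 <- ssasa_gradient(prob2, fx$theta_true_est)
  expect_equal(g2$nll, 2 * g1$nll, tolerance = 1e-12)
  expect_equal(g2$gradient, 2 * g1$gradient, tolerance = 1e-10)
})

test_that("an observation-map parameter has the closed-form direct gradient", {
  # y = s_obs * x with a steady-state datum: dJ/ds_obs = -r/sigma^2 * x*
  m <- compile_model(parse_model(list(
    species = list("x"), parameters = list("k_in", "k_out", "s_obs"),
    inputs = list("w"),
    reactions = list("0 -> x at k_in*w", "x -> 0 at k_out*x"),
    initials = list(x = "0"), observables = list(obs_x = "s_obs*x"))))
  meas <- data.frame(conditionId = "c1", observableId = "obs_x",
                     time = Inf, measurement = 3, sd = 0.5)
  prob <- sg_problem(m, meas,
                     conditions = list(sg_condition("c1", u = c(w = 1))),
                     parameters = data.frame(
                       parameterId = c("k_in", "k_out", "s_obs"),
                       parameterScale = "linear", lowerBound = 1e-3,
                       upperBound = 1e3, nominalValue = c(2, 1, 1.2)))
  g <- ssasa_gradient(prob)
  r <- 3 - 1.2 * 2
  expect_equal(unname(g$gradient["s_obs"]), -r / 0.25 * 2, tolerance = 1e-9)
  gf <- objective_gradient(prob, method = "fd")
  expect_lt(rel_err(g$gradient, gf$gradient), 1e-6)
})

test_that("log10 parameter scales chain the closed-form gradient", {
  g <- ssasa_gradient(pd_ss_problem(scale = "log10"))
  expect_equal(unname(g$gradient),
               c(-1 * 2 * log(10), 2 * 1 * log(10)), tolerance = 1e-8)
  expect_equal(unname(g$gradient_linear), c(-1, 2), tolerance = 1e-8)
})

test_that("an optimum start converges immediately with a near-zero gradient", {
  fx <- make_fixture(fixture_spec("production_degradation", sigma = 0,
                                  n_timepoints = 0, equilibration = "post"))
  rep <- estimate(fx$problem, n_starts = 1, seed = 1, max_iter = 50,
                  starts = matrix(fx$theta_true_est, 1))
  expect_true(rep$results$converged[1])
  expect_lte(rep$results$n_fn[1], 10)
  g <- ssasa_gradient(fx$problem, rep$best$theta)
  expect_lt(max(abs(g$gradient)), 1e-4)
})

test_that("start draws are seeded, reproducible and inside the bounds", {
  fx <- get_suite()$pd_post
  r1 <- estimate(fx$problem, n_starts = 4, seed = 7, max_iter = 4)
  r2 <- estimate(fx$problem, n_starts = 4, seed = 7, max_iter = 4)
  expect_identical(r1$starts, r2$starts)
  p <- fx$problem$parameters
  lb <- to_estimation_scale(p$lowerBound, p$parameterScale)
  ub <- to_estimation_scale(p$upperBound, p$parameterScale)
  for (k in seq_along(p$parameterId)) {
    v <- r1$results[[p$parameterId[k]]]
    expect_true(all(v >= lb[k] - 1e-12 & v <= ub[k] + 1e-12))
  }
})

test_that("the identifiable ratio of the production-degradation model is recovered", {
  # steady-state data only: k_in/k_out identifiable, not the pair
  fx <- make_fixture(fixture_spec("production_degradation", sigma = 0.001,
                                  n_timepoints = 0, equilibration = "post",
                                  n_replicates = 8))
  rep <- estimate(fx$problem, n_starts = 4, seed = 3, max_iter = 100)
  ratio_true <- fx$theta_true["k_in"] / fx$theta_true["k_out"]
  ratio_fit <- rep$best$theta_linear["k_in"] / rep$best$theta_linear["k_out"]
  expect_lt(abs(ratio_fit - ratio_true) / ratio_true, 0.01)
})
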