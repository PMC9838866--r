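# Model parsing, symbolic compilation, and parameter scales.

test_that("reaction shorthand builds the expected stoichiometry and rates", {
  net <- parse_model("A -> B at k1*A; B -> A at k2*B")
  expect_equal(unname(net$S), matrix(c(-1, 1, 1, -1), nrow = 2))
  expect_equal(net$species, c("A", "B"))
  expect_setequal(net$parameters, c("k1", "k2"))
  # rates evaluate as declared
  m <- compile_model(net)
  expect_equal(m$f(c(A = 2, B = 3), c(k1 = 5, k2 = 7)),
               c(-5 * 2 + 7 * 3, 5 * 2 - 7 * 3))
})

test_that("raw-ODE definitions pass through without a reaction structure", {
  net <- parse_model(list(
    species = list("x"), parameters = list("k_in", "k_out"),
    odes = list(x = "k_in - k_out*x"), initials = list(x = "0")))
  expect_null(net$S)
  m <- compile_model(net)
  expect_equal(m$f(1.5, c(2, 1)), 2 - 1.5)
})

test_that("parse errors name the offending symbol or species", {
  expect_error(parse_model(list(
    species = list("A"), parameters = list("k1"),
    reactions = list("A -> 0 at k9*A"))),
    "k9", class = "steadygrad_parse_error")
  expect_error(parse_model(list(
    species = list("A", "A"), parameters = list("k1"),
    reactions = list("A -> 0 at k1*A"))),
    "duplicate", class = "steadygrad_parse_error")
  expect_error(parse_model(list(
    species = list("A"), parameters = list("k1"),
    reactions = list("A -> Z at k1*A"))),
    "Z", class = "steadygrad_parse_error")
})

test_that("symbolic derivatives match hand differentiation", {
  net <- parse_model(list(
    species = list("x"), parameters = list("k_in", "k_out"),
    odes = list(x = "k_in - k_out*x")))
  m <- compile_model(net)
  expect_equal(m$jac(c(x = 3), c(2, 1)), matrix(-1, 1, 1))
  expect_equal(m$dfdtheta(c(x = 3), c(2, 1)), matrix(c(1, -3), 1, 2))

  conv <- compile_model(conv_network())
  th <- c(k1 = 2, k2 = 1, a0 = 1)
  expect_equal(conv$jac(c(A = 0.4, B = 0.6), th),
               matrix(c(-2, 2, 1, -1), 2, 2))
})

test_that("non-differentiable rate expressions fail at compile time", {
  net <- parse_model(list(
    species = list("x"), parameters = list("k"),
    odes = list(x = "-k*abs(x)")))
  expect_error(compile_model(net), "differentiable",
               class = "steadygrad_compile_error")
})

test_that("projection observables differentiate trivially", {
  net <- parse_model(list(
    species = list("x1", "x2"), parameters = list("k"),
    odes = list(x1 = "-k*x1", x2 = "k*x1"),
    observables = list(y = "x2")))
  m <- compile_model(net)
  expect_equal(m$dhdx(c(1, 2), 1), matrix(c(0, 1), 1, 2))
  expect_equal(m$dhdtheta(c(1, 2), 1), matrix(0, 1, 1))
})

test_that("jacobian and parameter derivatives match finite differences on random draws", {
  mm <- make_model(fixture_spec("mm_chain"))$model
  conv <- compile_model(conv_network())
  set.seed(42)
  for (m in list(mm, conv)) {
    u <- if (length(m$inputs)) c(w = 1.2) else NULL
    for (rep in 1:10) {
      x <- runif(m$n_x, 0.2, 3)
      th <- runif(m$n_theta, 0.2, 3)
      J_fd <- fd_jacobian(function(xx) m$f(xx, th, u), x)
      expect_lt(rel_err(m$jac(x, th, u), J_fd), 1e-6)
      D_fd <- fd_jacobian(function(tt) m$f(x, tt, u), th)
      expect_lt(rel_err(m$dfdtheta(x, th, u), D_fd), 1e-6)
    }
  }
})

test_that("assembled right-hand side equals S.v", {
  net <- conv_network()
  m <- compile_model(net)
  set.seed(7)
  for (rep in 1:5) {
    x <- runif(2); th <- runif(3, 0.5, 2)
    vals <- c(as.list(setNames(x, net$species)), as.list(setNames(th, net$parameters)))
    v <- vapply(net$rates, eval, numeric(1), envir = vals)
    expect_equal(m$f(x, th), as.numeric(net$S %*% v))
  }
})

test_that("parameter scales apply, invert and chain correctly", {
  expect_equal(apply_scale(0, "log10"), 1)
  expect_equal(apply_scale(c(0.5, 2), c("log10", "linear")), c(10^0.5, 2))
  th <- c(0.3, 5)
  sc <- c("log10", "linear")
  expect_equal(to_estimation_scale(apply_scale(th, sc), sc), th)
  # d(10^s)/ds at theta_lin = 2 is 2*ln(10); FD oracle
  fd <- (10^(log10(2) + 1e-7) - 10^(log10(2) - 1e-7)) / 2e-7
  expect_equal(chain_rule(1, 2, "log10"), fd, tolerance = 1e-6)
  expect_equal(chain_rule(1, 2, "log10"), 2 * log(10))
  expect_equal(chain_rule(c(3, 4), c(2, 2), c("linear", "linear")), c(3, 4))
  expect_error(to_estimation_scale(-1, "log10"), class = "steadygrad_domain_error")
})
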