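# Shared fixtures for the test suite. Everything is generated in code.

# production-degradation model: xdot = k_in*w - k_out*x, y = x
pd_model <- function() {
  compile_model(parse_model(list(
    format = "steadygrad-model-v1",
    species = list("x"), parameters = list("k_in", "k_out"),
    inputs = list("w"),
    reactions = list("0 -> x at k_in*w", "x -> 0 at k_out*x"),
    initials = list(x = "0"), observables = list(obs_x = "x"))))
}

# single steady-state datum ybar* = 3, sigma = 1 at (k_in, k_out) = (2, 1):
# closed-form gradient (-1, +2) on the linear scale
pd_ss_problem <- function(scale = "linear") {
  meas <- data.frame(conditionId = "c1", observableId = "obs_x",
                     time = Inf, measurement = 3, sd = 1)
  sg_problem(pd_model(), meas,
             conditions = list(sg_condition("c1", u = c(w = 1))),
             parameters = data.frame(parameterId = c("k_in", "k_out"),
                                     parameterScale = scale,
                                     lowerBound = 1e-3, upperBound = 1e3,
                                     nominalValue = c(2, 1)))
}

# conversion reaction A <-> B with conserved total a0
conv_network <- function() {
  parse_model(list(
    format = "steadygrad-model-v1",
    species = list("A", "B"), parameters = list("k1", "k2", "a0"),
    reactions = list("A -> B at k1*A", "B -> A at k2*B"),
    initials = list(A = "a0", B = "0"),
    observables = list(obs_A = "A", obs_B = "B")))
}

rel_err <- function(got, want) {
  max(abs(got - want)) / max(abs(want), .Machine$double.eps)
}

# central finite differences of a vector-valued function (independent oracle)
fd_jacobian <- function(fn, x, step = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (k in seq_along(x)) {
    h <- step * (1 + abs(x[k]))
    up <- x; up[k] <- up[k] + h
    dn <- x; dn[k] <- dn[k] - h
    J[, k] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

# memoized standard fixture suite (shared across test files)
.sg_test_cache <- new.env(parent = emptyenv())
get_suite <- function() {
  if (is.null(.sg_test_cache$suite))
    .sg_test_cache$suite <- fixture_suite(seed = 1L, sigma = 0.05)
  .sg_test_cache$suite
}
get_suite_gradients <- function(methods = c("ssasa", "forward", "fd")) {
  key <- paste(methods, collapse = "+")
  if (is.null(.sg_test_cache[[key]])) {
    .sg_test_cache[[key]] <- lapply(get_suite(), function(fx)
      check_gradients(fx$problem, theta = fx$theta_true_est, methods = methods))
  }
  .sg_test_cache[[key]]
}
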