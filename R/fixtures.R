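# Seeded synthetic fixtures with the statistical structure the gradient
# methods assume: exponentially stable steady states (Hurwitz Jacobian,
# verified at generation time) and independent Gaussian measurement noise.

#' Specify a synthetic fixture
#'
#' @param kind One of `"production_degradation"` (1 state, closed-form
#'   steady state), `"conversion"` (2 states, one conserved total —
#'   exercises moiety reduction), `"linear_network"` (seeded random stable
#'   linear system \eqn{\dot x = A x + b w} with strictly diagonally
#'   dominant, hence Hurwitz, `A`), or `"mm_chain"` (3-state
#'   Michaelis--Menten chain with inflow, saturable conversions, small
#'   linear leaks and first-order export — nonlinear, nonsingular Jacobian).
#' @param seed Seed controlling the random model draw (linear network) and
#'   the measurement noise.
#' @param sigma Measurement noise standard deviation (observable units); 0
#'   gives noiseless data recorded with unit weights.
#' @param n_timepoints Number of log-spaced (decade-style) time-course
#'   sampling times per observable and condition; 0 for steady-state-only
#'   data.
#' @param equilibration `"none"`, `"pre"`, `"post"` or `"both"`: whether the
#'   initial state is a pre-equilibration steady state and/or steady-state
#'   measurements are taken after the time course.
#' @param n_x States of the linear network (ignored otherwise).
#' @param n_conditions 1 or 2 experimental conditions (different input
#'   levels).
#' @param n_replicates Replicate measurements per (time, observable) cell.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("production_degradation", "conversion",
                                  "linear_network", "mm_chain"),
                         seed = 1L, sigma = 0.02, n_timepoints = 8L,
                         equilibration = c("post", "pre", "both", "none"),
                         n_x = 5L, n_conditions = 1L, n_replicates = 1L) {
  kind <- match.arg(kind)
  equilibration <- match.arg(equilibration)
  if (kind == "conversion" && equilibration %in% c("pre", "both"))
    stop_sg("steadygrad_fixture_error",
            "the conversion fixture has no inputs, so pre-equilibration is not meaningful")
  structure(list(kind = kind, seed = as.integer(seed), sigma = sigma,
                 n_timepoints = as.integer(n_timepoints),
                 equilibration = equilibration, n_x = as.integer(n_x),
                 n_conditions = as.integer(n_conditions),
                 n_replicates = as.integer(n_replicates)),
            class = "fixture_spec")
}

# time-course sampling window per kind (model time units)
fixture_t_span <- function(kind) {
  switch(kind,
         production_degradation = c(0.1, 8),
         conversion = c(0.05, 4),
         linear_network = c(0.1, 15),
         # sampling ends well inside the transient so post-equilibration
         # fixtures have a genuine equilibration phase beyond t_nt
         mm_chain = c(0.2, 40))
}

#' Generate a fixture model
#'
#' Builds the network, the true parameters, the parameter table
#' (log10 scales and bounds) and the experimental conditions for a
#' [fixture_spec()]. Steady-state stability (all Jacobian eigenvalues with
#' negative real part) is verified at generation time; random draws that
#' fail are regenerated with the next sub-seed (at most 10 tries).
#'
#' @param spec A [fixture_spec()].
#' @return List with `network`, `theta_true` (named, linear scale), the
#'   `parameters` table, `conditions`, the compiled full `model_full`, the
#'   (moiety-reduced where applicable) `model`, and the conservation
#'   `analysis` (or `NULL`).
#' @export
make_model <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (try_i in 0:9) {
    built <- build_fixture_network(spec, spec$seed + 1000L * try_i)
    model_full <- compile_model(built$network)
    analysis <- if (!is.null(built$network$S))
      find_conserved_quantities(built$network$S, built$network) else NULL
    model <- if (!is.null(analysis) && analysis$n_c > 0L)
      reduce_model(model_full, analysis) else model_full
    if (fixture_is_stable(model, built$theta_true, built$conditions)) {
      return(list(network = built$network, theta_true = built$theta_true,
                  parameters = built$parameters, conditions = built$conditions,
                  model_full = model_full, model = model, analysis = analysis))
    }
  }
  stop_sg("steadygrad_fixture_error",
          "could not generate a stable '%s' fixture in 10 tries", spec$kind)
}

# Hurwitz check of the (reduced) Jacobian at every condition's steady state.
fixture_is_stable <- function(model, theta, conditions) {
  ok <- TRUE
  for (cond in conditions) {
    for (u in c(list(cond$u), if (cond$preeq) list(cond$u_pre))) {
      eq <- tryCatch(equilibrate(model, theta, u,
                                 x_init = model$x0(theta, u)),
                     error = function(e) NULL)
      if (is.null(eq)) return(FALSE)
      ev <- eigen(model$jac(eq$x_star, theta, u), only.values = TRUE)$values
      ok <- ok && all(Re(ev) < 0)
    }
  }
  ok
}

build_fixture_network <- function(spec, seed) {
  switch(spec$kind,
    production_degradation = {
      net <- parse_model(list(
        format = "steadygrad-model-v1",
        species = list("x"), parameters = list("k_in", "k_out"),
        inputs = list("w"),
        reactions = list("0 -> x at k_in*w", "x -> 0 at k_out*x"),
        initials = list(x = "0"), observables = list(obs_x = "x")))
      conds <- fixture_conditions(spec, w_main = c(1, 1.6), w_pre = 0.5)
      list(network = net, theta_true = c(k_in = 2, k_out = 1),
           parameters = fixture_parameters(c(k_in = 2, k_out = 1), 1e-3, 1e3),
           conditions = conds)
    },
    conversion = {
      net <- parse_model(list(
        format = "steadygrad-model-v1",
        species = list("A", "B"), parameters = list("k1", "k2", "a0"),
        reactions = list("A -> B at k1*A", "B -> A at k2*B"),
        initials = list(A = "a0", B = "0"),
        observables = list(obs_A = "A", obs_B = "B")))
      conds <- list(sg_condition("c1"))
      if (spec$n_conditions > 1L) conds <- c(conds, list(sg_condition("c2")))
      list(network = net, theta_true = c(k1 = 2, k2 = 1, a0 = 1),
           parameters = fixture_parameters(c(k1 = 2, k2 = 1, a0 = 1), 1e-3, 1e3),
           conditions = conds[seq_len(spec$n_conditions)])
    },
    linear_network = {
      set.seed(seed)
      n <- spec$n_x
      M <- matrix(stats::runif(n * n), n, n)
      d <- stats::runif(n, 0.5, 1.5)
      A <- M
      diag(A) <- diag(M) - (rowSums(M) + d)  # strict diagonal dominance
      b_true <- stats::runif(n, 0.5, 2)
      sp <- paste0("x", seq_len(n))
      odes <- stats::setNames(lapply(seq_len(n), function(i) {
        terms <- sprintf("%.17g*%s", A[i, ], sp)
        paste(c(terms, sprintf("b%d*w", i)), collapse = " + ")
      }), sp)
      net <- parse_model(list(
        format = "steadygrad-model-v1",
        species = as.list(sp), parameters = as.list(paste0("b", seq_len(n))),
        inputs = list("w"), odes = odes,
        initials = stats::setNames(as.list(rep("0", n)), sp),
        observables = stats::setNames(as.list(sp), paste0("obs_", sp))))
      conds <- fixture_conditions(spec, w_main = c(1, 1.5), w_pre = 0.4)
      theta_true <- stats::setNames(b_true, paste0("b", seq_len(n)))
      list(network = net, theta_true = theta_true,
           parameters = fixture_parameters(theta_true, 1e-2, 1e2),
           conditions = conds)
    },
    mm_chain = {
      net <- parse_model(list(
        format = "steadygrad-model-v1",
        species = list("x1", "x2", "x3"),
        parameters = list("k_in", "V1", "K1", "V2", "K2", "k3"),
        inputs = list("w"),
        reactions = list(
          "0 -> x1 at k_in*w",
          "x1 -> x2 at V1*x1/(K1+x1)",
          "x1 -> 0 at 0.1*x1",
          "x2 -> x3 at V2*x2/(K2+x2)",
          "x2 -> 0 at 0.1*x2",
          "x3 -> 0 at k3*x3"),
        initials = list(x1 = "0", x2 = "0", x3 = "0"),
        observables = list(obs_x1 = "x1", obs_x2 = "x2", obs_x3 = "x3")))
      theta_true <- c(k_in = 0.8, V1 = 1, K1 = 0.5, V2 = 0.9, K2 = 0.4, k3 = 0.3)
      conds <- fixture_conditions(spec, w_main = c(1, 1.6), w_pre = 0.4)
      list(network = net, theta_true = theta_true,
           parameters = fixture_parameters(theta_true, 1e-2, 1e2),
           conditions = conds)
    })
}

fixture_conditions <- function(spec, w_main, w_pre) {
  u_pre <- if (spec$equilibration %in% c("pre", "both")) c(w = w_pre) else NULL
  lapply(seq_len(spec$n_conditions), function(i)
    sg_condition(paste0("c", i), u = c(w = w_main[i]), u_pre = u_pre))
}

fixture_parameters <- function(theta_true, lb, ub) {
  data.frame(parameterId = names(theta_true), parameterScale = "log10",
             lowerBound = lb, upperBound = ub,
             nominalValue = as.numeric(theta_true))
}

#' Generate a synthetic measurement table for a fixture model
#'
#' Simulates the model at the true parameters (including the equilibration
#' phases the spec requests), adds independent Gaussian noise
#' \eqn{\varepsilon \sim N(0, \sigma^2)} with the seeded generator, and
#' emits time-course rows at log-spaced times and/or steady-state rows
#' (`time = Inf`). With `sigma = 0` the values equal the noiseless
#' simulation exactly and rows carry unit weights (`sd = 1`).
#'
#' @param fx A fixture model from [make_model()].
#' @param spec The [fixture_spec()] used to build it.
#' @return A measurement data frame for [sg_problem()].
#' @export
make_data <- function(fx, spec) {
  model <- fx$model
  theta <- fx$theta_true
  span <- fixture_t_span(spec$kind)
  times <- if (spec$n_timepoints > 0L)
    signif(exp(seq(log(span[1L]), log(span[2L]), length.out = spec$n_timepoints)), 6)
  else numeric(0)
  sd_rec <- if (spec$sigma > 0) spec$sigma else 1

  rows <- list()
  for (cond in fx$conditions) {
    skel <- expand.grid(observableId = model$observables, time = times,
                        stringsAsFactors = FALSE)
    if (spec$equilibration %in% c("post", "both"))
      skel <- rbind(skel, expand.grid(observableId = model$observables,
                                      time = Inf, stringsAsFactors = FALSE))
    if (nrow(skel) == 0L)
      stop_sg("steadygrad_fixture_error",
              "fixture spec produces no measurements (n_timepoints = 0 and no steady-state rows)")
    skel <- skel[rep(seq_len(nrow(skel)), each = spec$n_replicates), ,
                 drop = FALSE]
    cond_meas <- data.frame(conditionId = cond$id,
                            observableId = skel$observableId,
                            time = skel$time, measurement = NA_real_,
                            sd = sd_rec)
    cond$posteq <- any(!is.finite(cond_meas$time))
    sim <- tryCatch(
      simulate_condition(model, theta, cond, cond_meas, gradient_settings()),
      error = function(e) stop_sg("steadygrad_fixture_error",
                                  "simulation at theta_true failed: %s",
                                  conditionMessage(e)))
    y <- c(sim$tc$y, sim$ss$y)
    key_sim <- c(paste(sim$tc$observableId, sim$tc$time),
                 paste(sim$ss$observableId, sim$ss$time))
    # simulate_condition reorders rows; map values back by (observable, time)
    cond_meas$measurement <- y[match(paste(cond_meas$observableId, cond_meas$time),
                                     key_sim)]
    rows[[cond$id]] <- cond_meas
  }
  meas <- do.call(rbind, rows)
  set.seed(spec$seed + 7919L)
  if (spec$sigma > 0)
    meas$measurement <- meas$measurement + stats::rnorm(nrow(meas), 0, spec$sigma)
  rownames(meas) <- NULL
  meas
}

#' Build a complete synthetic estimation problem
#'
#' Convenience wrapper: [make_model()] + [make_data()] + [sg_problem()].
#'
#' @param spec A [fixture_spec()], or arguments forwarded to it.
#' @param ... Forwarded to [fixture_spec()] when `spec` is a kind string.
#' @return List with the `problem`, `theta_true` (linear scale),
#'   `theta_true_est` (estimation scale), and the [make_model()] fields.
#' @examples
#' fx <- make_fixture("production_degradation", sigma = 0, n_timepoints = 0)
#' fx$problem
#' @export
make_fixture <- function(spec, ...) {
  if (is.character(spec)) spec <- fixture_spec(spec, ...)
  fx <- make_model(spec)
  meas <- make_data(fx, spec)
  problem <- sg_problem(fx$model, meas, conditions = fx$conditions,
                        parameters = fx$parameters)
  c(list(problem = problem,
         theta_true = fx$theta_true,
         theta_true_est = stats::setNames(
           to_estimation_scale(fx$theta_true,
                               fx$parameters$parameterScale),
           fx$parameters$parameterId),
         spec = spec, measurements = meas),
    fx)
}

#' Standard seeded fixture suite
#'
#' Eleven problems covering no/pre-/post-/both equilibration, linear and
#' Michaelis--Menten dynamics, and models with and without conserved
#' moieties. This is the cross-validation surface on which all gradient
#' methods are compared.
#'
#' @param seed Base seed.
#' @param sigma Measurement noise level.
#' @return Named list of [make_fixture()] results.
#' @export
fixture_suite <- function(seed = 1L, sigma = 0.05) {
  specs <- list(
    pd_post    = fixture_spec("production_degradation", seed = seed, sigma = sigma,
                              n_timepoints = 4, equilibration = "post"),
    pd_pre     = fixture_spec("production_degradation", seed = seed + 1L, sigma = sigma,
                              n_timepoints = 5, equilibration = "pre"),
    conv_post  = fixture_spec("conversion", seed = seed + 2L, sigma = sigma,
                              n_timepoints = 4, equilibration = "post"),
    conv_none  = fixture_spec("conversion", seed = seed + 3L, sigma = sigma,
                              n_timepoints = 6, equilibration = "none"),
    lin4_post  = fixture_spec("linear_network", seed = seed + 4L, sigma = sigma,
                              n_x = 4, n_timepoints = 4, equilibration = "post"),
    lin5_pre   = fixture_spec("linear_network", seed = seed + 5L, sigma = sigma,
                              n_x = 5, n_timepoints = 4, equilibration = "pre"),
    lin3_both  = fixture_spec("linear_network", seed = seed + 6L, sigma = sigma,
                              n_x = 3, n_timepoints = 4, equilibration = "both"),
    lin5_none  = fixture_spec("linear_network", seed = seed + 7L, sigma = sigma,
                              n_x = 5, n_timepoints = 5, equilibration = "none"),
    mm_post    = fixture_spec("mm_chain", seed = seed + 8L, sigma = sigma,
                              n_timepoints = 4, equilibration = "post"),
    mm_pre     = fixture_spec("mm_chain", seed = seed + 9L, sigma = sigma,
                              n_timepoints = 4, equilibration = "pre"),
    mm_both    = fixture_spec("mm_chain", seed = seed + 10L, sigma = sigma,
                              n_timepoints = 4, equilibration = "both"))
  lapply(specs, make_fixture)
}
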