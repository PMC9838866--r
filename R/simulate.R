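# Forward integration, checkpointed trajectories, and work counters.
#
# Gradient comparisons across methods must not be limited by integrator
# noise, so forward/backward passes default to much tighter tolerances
# (rtol 1e-10, atol 1e-12) than the steady-state convergence test
# (rtol 1e-8, atol 1e-16). State values needed during the backward pass come
# from piecewise cubic Hermite interpolation of a densely checkpointed
# forward solution (states and their time derivatives at every checkpoint).

#' Numerical settings shared by simulation and gradient methods
#'
#' @param rtol,atol Relative/absolute tolerances of the stiff forward and
#'   backward integrations (dimensionless / state units).
#' @param ss_rtol,ss_atol Tolerances of the steady-state weighted-residual
#'   convergence test; defaults follow common practice for equilibration
#'   (1e-8 and 1e-16).
#' @param t_start_window First equilibration window length (model time
#'   units); subsequent windows double, bounding total work at about twice
#'   the final window.
#' @param max_doublings Maximum number of equilibration windows.
#' @param t_min_equil Minimum equilibration horizon; the convergence test is
#'   only accepted at `t >= t_min_equil`. Used to stretch the reference
#'   long-simulation tail when studying its convergence to the steady-state
#'   adjoint solves.
#' @param newton_polish Apply Newton iterations on `f(x) = 0` after the
#'   simulation converges; a step is kept only if it decreases the weighted
#'   residual.
#' @param newton_max_iter Maximum Newton iterations.
#' @param n_grid_equil Output checkpoints per equilibration window (the
#'   convergence test is evaluated at each).
#' @param n_dense Checkpoints across a time-course interval (half uniform,
#'   half geometric near the start, so fast transients are resolved).
#' @param allow_asa_fallback If the steady-state Jacobian is singular, fall
#'   back to backward integration for that interval instead of raising an
#'   error (tagged in the result).
#' @param fd_step Relative step of the central finite-difference oracle on
#'   the estimation scale.
#' @param rcond_tol Reciprocal-condition threshold of [assert_nonsingular()].
#' @return A named list of settings.
#' @export
gradient_settings <- function(rtol = 1e-10, atol = 1e-12,
                              ss_rtol = 1e-8, ss_atol = 1e-16,
                              t_start_window = 10, max_doublings = 30,
                              t_min_equil = 0,
                              newton_polish = TRUE, newton_max_iter = 25,
                              n_grid_equil = 81, n_dense = 241,
                              allow_asa_fallback = FALSE,
                              fd_step = 1e-5, rcond_tol = 1e-10) {
  stopifnot(ss_rtol > 0, ss_atol >= 0, max_doublings >= 1, t_start_window > 0)
  list(rtol = rtol, atol = atol, ss_rtol = ss_rtol, ss_atol = ss_atol,
       t_start_window = t_start_window, max_doublings = max_doublings,
       t_min_equil = t_min_equil,
       newton_polish = newton_polish, newton_max_iter = newton_max_iter,
       n_grid_equil = n_grid_equil, n_dense = n_dense,
       allow_asa_fallback = allow_asa_fallback,
       fd_step = fd_step, rcond_tol = rcond_tol)
}

# Right-hand-side evaluation counters (environment so closures can bump them).
new_counters <- function() {
  cnt <- new.env(parent = emptyenv())
  cnt$forward <- 0L
  cnt$backward_timecourse <- 0L
  cnt$backward_equil <- 0L
  cnt
}
counters_as_list <- function(cnt) {
  list(forward_rhs = cnt$forward,
       backward_rhs_timecourse = cnt$backward_timecourse,
       backward_rhs_equil = cnt$backward_equil,
       backward_rhs_total = cnt$backward_timecourse + cnt$backward_equil)
}

# Stiff forward integration over a fixed time grid; counts RHS evaluations.
integrate_states <- function(model, theta, u, x_init, times, settings,
                             counters = NULL, tag = "forward") {
  func <- function(t, y, parms) {
    if (!is.null(counters)) counters[[tag]] <- counters[[tag]] + 1L
    list(model$f(y, theta, u))
  }
  jacf <- function(t, y, parms) model$jac(y, theta, u)
  out <- deSolve::ode(y = as.numeric(x_init), times = times, func = func,
                      parms = NULL, jacfunc = jacf, jactype = "fullusr",
                      method = "lsoda", rtol = settings$rtol, atol = settings$atol)
  if (attr(out, "istate")[1L] < 0)
    stop_sg("steadygrad_integration_failure",
            "forward integration failed near t = %.4g", utils::tail(out[, 1L], 1L))
  list(times = out[, 1L], states = unname(out[, -1L, drop = FALSE]))
}

# Checkpointed trajectory: states and exact derivatives at the checkpoints.
make_trajectory <- function(model, theta, u, times, states) {
  derivs <- t(vapply(seq_along(times),
                     function(i) model$f(states[i, ], theta, u),
                     numeric(ncol(states))))
  if (ncol(states) == 1L) derivs <- matrix(derivs, ncol = 1L)
  list(times = times, states = states, derivs = derivs)
}

# Piecewise cubic Hermite interpolation of a checkpointed trajectory.
traj_interp <- function(traj, t) {
  tt <- traj$times
  n <- length(tt)
  if (t <= tt[1L]) return(traj$states[1L, ])
  if (t >= tt[n]) return(traj$states[n, ])
  k <- findInterval(t, tt)
  h <- tt[k + 1L] - tt[k]
  s <- (t - tt[k]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * traj$states[k, ] + h10 * h * traj$derivs[k, ] +
    h01 * traj$states[k + 1L, ] + h11 * h * traj$derivs[k + 1L, ]
}

# Concatenate two trajectories that share their junction point.
traj_append <- function(a, b) {
  if (is.null(a)) return(b)
  list(times = c(a$times, b$times[-1L]),
       states = rbind(a$states, b$states[-1L, , drop = FALSE]),
       derivs = rbind(a$derivs, b$derivs[-1L, , drop = FALSE]))
}

# Dense output grid over [t0, t1]: half geometric (resolves stiff initial
# transients), half uniform; always includes both endpoints and `extra`.
dense_grid <- function(t0, t1, n, extra = numeric(0)) {
  if (t1 <= t0) return(sort(unique(c(t0, extra))))
  span <- t1 - t0
  n_geo <- floor(n / 2)
  geo <- t0 + span * exp(seq(log(1e-5), log(1), length.out = n_geo))
  uni <- seq(t0, t1, length.out = n - n_geo)
  sort(unique(c(t0, geo, uni, t1, extra)))
}

# Simulate a time course over [t0, t_nt]; returns the checkpointed
# trajectory plus the states at requested measurement times.
simulate_timecourse <- function(model, theta, u, x_init, t0, t_nt, meas_times,
                                settings, counters = NULL) {
  meas_times <- round(meas_times, 12)
  if (t_nt <= t0) {
    times <- t0
    states <- matrix(as.numeric(x_init), nrow = 1L)
  } else {
    times <- dense_grid(t0, t_nt, settings$n_dense, extra = meas_times)
    sol <- integrate_states(model, theta, u, x_init, times, settings, counters)
    times <- sol$times
    states <- sol$states
  }
  traj <- make_trajectory(model, theta, u, times, states)
  idx <- match(meas_times, round(times, 12))
  if (anyNA(idx))
    stop_sg("steadygrad_integration_failure", "internal: measurement time not on output grid")
  list(traj = traj,
       meas_states = states[idx, , drop = FALSE],
       x_end = states[nrow(states), ])
}
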