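# Forward sensitivity analysis with steady-state sensitivities by linear
# solves, used as an independent gradient oracle and exposed as a method.

# State sensitivities at a nonsingular steady state: J s* = -df/dtheta
# column-wise (total derivative of f(x*, theta) = 0).
steady_state_sensitivities <- function(model, x_star, theta, u, settings) {
  J <- model$jac(x_star, theta, u)
  assert_nonsingular(J, settings$rcond_tol)
  s <- solve(J, -model$dfdtheta(x_star, theta, u))
  matrix(s, model$n_x, model$n_theta)
}

# Integrate the augmented system xdot = f, sdot = J s + df/dtheta.
integrate_forward_sens <- function(model, theta, u, x_init, s_init, times,
                                   settings, counters = NULL) {
  n_x <- model$n_x; n_th <- model$n_theta
  func <- function(t, y, parms) {
    if (!is.null(counters)) counters$forward <- counters$forward + 1L
    x <- y[seq_len(n_x)]
    s <- matrix(y[-seq_len(n_x)], n_x, n_th)
    ds <- model$jac(x, theta, u) %*% s + model$dfdtheta(x, theta, u)
    list(c(model$f(x, theta, u), as.numeric(ds)))
  }
  out <- deSolve::ode(y = c(as.numeric(x_init), as.numeric(s_init)),
                      times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = settings$rtol,
                      atol = settings$atol)
  if (attr(out, "istate")[1L] < 0)
    stop_sg("steadygrad_integration_failure", "forward sensitivity integration failed")
  out
}

# Forward-sensitivity gradient of one condition (linear scale).
cond_gradient_forward <- function(model, theta, cond, meas_c, settings,
                                  counters) {
  n_x <- model$n_x; n_th <- model$n_theta
  u <- cond$u
  tc <- meas_c[is.finite(meas_c$time), , drop = FALSE]
  ss <- meas_c[!is.finite(meas_c$time), , drop = FALSE]
  t_nt <- if (nrow(tc)) max(tc$time) else 0

  if (isTRUE(cond$preeq)) {
    eq_pre <- equilibrate(model, theta, cond$u_pre,
                          x_init = model$x0(theta, cond$u_pre),
                          settings = settings, counters = counters)
    x_t0 <- eq_pre$x_star
    s_t0 <- steady_state_sensitivities(model, x_t0, theta, cond$u_pre, settings)
  } else {
    x_t0 <- model$x0(theta, u)
    s_t0 <- model$dx0dtheta(theta, u)
  }

  ut <- sort(unique(round(tc$time, 12)))
  times <- sort(unique(c(0, ut, t_nt)))
  if (length(times) > 1L) {
    out <- integrate_forward_sens(model, theta, u, x_t0, s_t0, times,
                                  settings, counters)
    xs <- unname(out[, 1L + seq_len(n_x), drop = FALSE])
    ses <- unname(out[, -(seq_len(n_x + 1L)), drop = FALSE])
  } else {
    xs <- matrix(as.numeric(x_t0), 1L)
    ses <- matrix(as.numeric(s_t0), 1L)
  }
  x_end <- xs[nrow(xs), ]
  s_end <- matrix(ses[nrow(ses), ], n_x, n_th)

  g <- numeric(n_th)
  nll <- 0
  if (nrow(tc)) {
    tc$obs_idx <- match(tc$observableId, model$observables)
    ti <- match(round(tc$time, 12), round(times, 12))
    for (r in seq_len(nrow(tc))) {
      x <- xs[ti[r], ]
      s <- matrix(ses[ti[r], ], n_x, n_th)
      i <- tc$obs_idx[r]
      y <- model$h(x, theta, u)[i]
      dy <- model$dhdx(x, theta, u)[i, ] %*% s + model$dhdtheta(x, theta, u)[i, ]
      res <- tc$measurement[r] - y
      g <- g - res / tc$sd[r]^2 * as.numeric(dy)
      nll <- nll + 0.5 * (log(2 * pi * tc$sd[r]^2) + (res / tc$sd[r])^2)
    }
  }
  if (nrow(ss)) {
    eq_post <- equilibrate(model, theta, u, x_init = x_end,
                           settings = settings, counters = counters)
    x_star <- eq_post$x_star
    s_star <- steady_state_sensitivities(model, x_star, theta, u, settings)
    ss$obs_idx <- match(ss$observableId, model$observables)
    for (r in seq_len(nrow(ss))) {
      i <- ss$obs_idx[r]
      y <- model$h(x_star, theta, u)[i]
      dy <- model$dhdx(x_star, theta, u)[i, ] %*% s_star +
        model$dhdtheta(x_star, theta, u)[i, ]
      res <- ss$measurement[r] - y
      g <- g - res / ss$sd[r]^2 * as.numeric(dy)
      nll <- nll + 0.5 * (log(2 * pi * ss$sd[r]^2) + (res / ss$sd[r])^2)
    }
  }
  list(nll = nll, gradient = g,
       method = "forward-sensitivities;steady-state:linear-solve")
}

#' Forward-sensitivity gradient
#'
#' Integrates the state sensitivity ODEs along with the model
#' (\eqn{\dot s = J s + \partial f/\partial\theta}); at steady states the
#' sensitivities are obtained per parameter from the linear solves
#' \eqn{J s^*_k = -\partial f/\partial\theta_k}. Pre-equilibration
#' sensitivities propagate into the time-course initial sensitivities. The
#' gradient is assembled from the observable sensitivities
#' \eqn{\partial y/\partial\theta = (\partial h/\partial x) s +
#' \partial h/\partial\theta}.
#'
#' @inheritParams objective_gradient
#' @return A `gradient_result`.
#' @export
forward_gradient <- function(problem, theta = NULL, settings = NULL)
  objective_gradient(problem, theta, method = "forward", settings = settings)

#' Central finite-difference gradient of a scalar function
#'
#' Central differences on the estimation (possibly log10) scale with a step
#' relative to each coordinate, \eqn{h_k = \mathrm{step}\,(1 + |\theta_k|)}.
#' Used as an independent oracle despite its limited accuracy; pair with
#' tight integrator tolerances.
#'
#' @param objective_fn Function of the full parameter vector returning a
#'   scalar.
#' @param theta Evaluation point (estimation scale).
#' @param step Relative step size (default `1e-5`).
#' @return Numeric gradient of the same length as `theta`.
#' @examples
#' fd_gradient(function(th) sum(th^2), c(1, 2))  # ~ (2, 4)
#' @export
fd_gradient <- function(objective_fn, theta, step = 1e-5) {
  g <- numeric(length(theta))
  for (k in seq_along(theta)) {
    h <- step * (1 + abs(theta[k]))
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    vals <- tryCatch(c(objective_fn(up), objective_fn(dn)),
                     error = function(e) stop_sg(
                       "steadygrad_fd_error",
                       "objective failed at a perturbation of coordinate %d (%s): %s",
                       k, names(theta)[k] %||% "", conditionMessage(e)))
    g[k] <- (vals[1L] - vals[2L]) / (2 * h)
  }
  g
}
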