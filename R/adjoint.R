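# Standard adjoint sensitivity analysis: backward integration of
#   p' = -J(x(t))^T p
# with jumps at measurement times and simultaneous quadrature accumulation
# of the gradient integrals against df/dtheta. The reference treatment of
# equilibration intervals ("long-simulation" adjoint) integrates backward
# over the same span the forward equilibration used.

#' Adjoint jump at a measurement time
#'
#' At each measured time point the adjoint state receives a jump
#' \deqn{p \mathrel{+}= \sum_i \left(\frac{\partial h_i}{\partial x}\right)^T
#' \frac{\bar y_i - y_i}{\sigma_i^2}} summed over the observables measured at
#' that time point.
#'
#' @param p Adjoint state before the jump.
#' @param model Compiled `model_functions`.
#' @param x_at_tj Forward state at the measurement time.
#' @param theta,u Linear-scale parameters and inputs.
#' @param residual_terms Data frame with columns `obs_idx` (observable row in
#'   the observation map), `residual` (\eqn{\bar y - y}) and `sigma`.
#' @return The adjoint state after the jump.
#' @export
measurement_jump <- function(p, model, x_at_tj, theta, u, residual_terms) {
  if (nrow(residual_terms) == 0L) return(p)
  if (any(residual_terms$sigma <= 0))
    stop_sg("steadygrad_degenerate_noise", "measurement with sigma <= 0")
  dhdx <- model$dhdx(x_at_tj, theta, u)
  for (r in seq_len(nrow(residual_terms))) {
    i <- residual_terms$obs_idx[r]
    p <- p + dhdx[i, ] * residual_terms$residual[r] / residual_terms$sigma[r]^2
  }
  p
}

#' Backward adjoint pass over a checkpointed forward trajectory
#'
#' Integrates the adjoint ODE backward from `t_from` to `t_to`
#' segment-by-segment, applying [measurement_jump()] at every measurement
#' time in `[t_to, t_from]` (a jump exactly at `t_from` is applied before
#' integration starts; one at `t_to` after it ends). Quadratures
#' \eqn{q_k = -\int p^T \partial f/\partial\theta_k \, dt} are accumulated as
#' augmented states so their error is controlled by the integrator.
#'
#' @param model Compiled `model_functions`.
#' @param traj Checkpointed forward trajectory covering `[t_to, t_from]`.
#' @param theta,u Linear-scale parameters and inputs.
#' @param jumps Data frame of measurement jumps: `time`, `obs_idx`,
#'   `residual`, `sigma` (may be empty).
#' @param t_from,t_to Backward integration span (`t_from >= t_to`).
#' @param p_init Adjoint state at `t_from` (before any jump there).
#' @param settings See [gradient_settings()].
#' @param counters,tag Internal RHS counters and which counter to increment
#'   (`"backward_timecourse"` or `"backward_equil"`).
#' @return List with `p` (adjoint at `t_to`, after a jump there if any) and
#'   `q` (accumulated gradient quadratures, length `n_theta`).
#' @export
backward_pass <- function(model, traj, theta, u, jumps, t_from, t_to, p_init,
                          settings = gradient_settings(), counters = NULL,
                          tag = "backward_timecourse") {
  n_x <- model$n_x
  n_th <- model$n_theta
  if (is.null(counters)) counters <- new_counters()
  p <- as.numeric(p_init)
  q <- numeric(n_th)
  stopifnot(t_from >= t_to, length(p) == n_x)

  jt <- if (nrow(jumps)) round(jumps$time, 12) else numeric(0)
  apply_jumps_at <- function(p, tb) {
    rows <- jumps[jt == round(tb, 12), , drop = FALSE]
    if (nrow(rows) == 0L) return(p)
    measurement_jump(p, model, traj_interp(traj, tb), theta, u, rows)
  }

  p <- apply_jumps_at(p, t_from)
  if (t_from == t_to) return(list(p = p, q = q))

  inner <- sort(unique(jt[jt < round(t_from, 12) & jt > round(t_to, 12)]),
                decreasing = TRUE)
  bounds <- c(t_from, inner, t_to)

  func <- function(t, y, parms) {
    counters[[tag]] <- counters[[tag]] + 1L
    x <- traj_interp(traj, t)
    pp <- y[seq_len(n_x)]
    dp <- -as.numeric(crossprod(model$jac(x, theta, u), pp))
    dq <- as.numeric(crossprod(model$dfdtheta(x, theta, u), pp))
    list(c(dp, dq))
  }
  # the adjoint system is linear in (p, q): its Jacobian is analytic
  jacf <- function(t, y, parms) {
    x <- traj_interp(traj, t)
    Jb <- matrix(0, n_x + n_th, n_x + n_th)
    Jb[seq_len(n_x), seq_len(n_x)] <- -t(model$jac(x, theta, u))
    Jb[n_x + seq_len(n_th), seq_len(n_x)] <- t(model$dfdtheta(x, theta, u))
    Jb
  }
  for (k in seq_len(length(bounds) - 1L)) {
    hi <- bounds[k]; lo <- bounds[k + 1L]
    # VODE/BDF with the analytic Jacobian: the adjoint system is stiff
    # wherever the forward system is, and restarts at every jump
    out <- deSolve::ode(y = c(p, q), times = c(hi, lo), func = func,
                        parms = NULL, jacfunc = jacf, jactype = "fullusr",
                        method = "vode",
                        rtol = settings$rtol, atol = settings$atol)
    if (attr(out, "istate")[1L] < 0)
      stop_sg("steadygrad_adjoint_failure",
              "backward integration failed on segment [%.4g, %.4g]", lo, hi)
    y_end <- out[nrow(out), -1L]
    p <- y_end[seq_len(n_x)]
    q <- y_end[n_x + seq_len(n_th)]
    p <- apply_jumps_at(p, lo)
  }
  list(p = as.numeric(p), q = as.numeric(q))
}
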