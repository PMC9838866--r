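# Steady-state computation by numerical equilibration with an optional
# Newton polish.

#' Weighted root-mean-square residual of the steady-state test
#'
#' Convergence test for equilibration: the system is considered at steady
#' state when \deqn{\frac{1}{n_x} \sum_i (\dot x_i w_i)^2 < 1, \qquad
#' w_i = \frac{1}{\mathrm{rtol} \, |x_i| + \mathrm{atol}}.} The magnitude of
#' the state enters the weight so that transient solver undershoots below
#' zero cannot flip weight signs.
#'
#' @param xdot Time derivatives `f(x, theta, u)`.
#' @param x Current state.
#' @param rtol,atol Relative and absolute tolerances of the test.
#' @return The weighted residual; values below 1 indicate convergence.
#' @examples
#' wrms_residual(0.5, 1, rtol = 1, atol = 0)  # 0.25
#' @export
wrms_residual <- function(xdot, x, rtol, atol) {
  stopifnot(length(xdot) == length(x), all(is.finite(xdot)), all(is.finite(x)))
  den <- rtol * abs(x) + atol
  if (any(den == 0))
    stop_sg("steadygrad_degenerate_weight",
            "degenerate steady-state weight: rtol*|x| + atol is zero for state %d",
            which(den == 0)[1L])
  mean((xdot / den)^2)
}

#' Equilibrate a model to steady state
#'
#' Integrates the (stiff) system over windows `[0, W]`, `[W, 3W]`, ... with
#' doubling window lengths until the weighted residual criterion
#' ([wrms_residual()]) falls below 1, then optionally applies Newton
#' iterations on `f(x) = 0`, accepting each step only while it decreases the
#' residual. The convergence test is evaluated at every checkpoint of every
#' window; with `t_min_equil > 0` convergence is only accepted from that
#' horizon on (used to stretch the reference method's tail).
#'
#' @param model Compiled `model_functions`.
#' @param theta Linear-scale parameter vector.
#' @param u Named input vector (may be `NULL` for input-free models).
#' @param x_init Starting state; defaults to `model$x0(theta, u)`.
#' @param settings See [gradient_settings()].
#' @param counters Internal RHS-evaluation counters (optional).
#' @param keep_trajectory Keep the checkpointed equilibration trajectory
#'   (needed by the reference long-simulation adjoint).
#' @return An `equilibration_result`: `x_star` (possibly Newton-polished),
#'   `wrms`, `t_equil`, `n_rhs_evals`, `method`
#'   (`"simulation"`/`"simulation+newton"`), the unpolished simulation
#'   endpoint `x_sim` with its residual `wrms_sim`, and optionally
#'   `trajectory`.
#' @export
equilibrate <- function(model, theta, u = NULL, x_init = NULL,
                        settings = gradient_settings(), counters = NULL,
                        keep_trajectory = FALSE) {
  if (is.null(x_init)) x_init <- model$x0(theta, u)
  if (!all(is.finite(x_init)))
    stop_sg("steadygrad_equilibration_failure", "non-finite initial state")
  if (is.null(counters)) counters <- new_counters()
  n0 <- counters$forward

  rtol <- settings$ss_rtol; atol <- settings$ss_atol
  x <- as.numeric(x_init)
  f0 <- model$f(x, theta, u)
  wr <- wrms_residual(f0, x, rtol, atol)
  traj <- if (keep_trajectory)
    list(times = 0, states = matrix(x, 1L), derivs = matrix(f0, 1L)) else NULL

  t_now <- 0
  converged <- wr < 1 && t_now >= settings$t_min_equil
  W <- settings$t_start_window
  windows <- 0L
  while (!converged && windows < settings$max_doublings) {
    times <- seq(t_now, t_now + W, length.out = settings$n_grid_equil)
    sol <- integrate_states(model, theta, u, x, times, settings, counters)
    seg <- make_trajectory(model, theta, u, sol$times, sol$states)
    hit <- NA_integer_
    for (i in seq_along(seg$times)[-1L]) {
      if (any(seg$states[i, ] < 0))
        warning("negative state during equilibration (transient undershoot)",
                call. = FALSE)
      wr_i <- wrms_residual(seg$derivs[i, ], seg$states[i, ], rtol, atol)
      if (wr_i < 1 && seg$times[i] >= settings$t_min_equil) { hit <- i; wr <- wr_i; break }
    }
    if (!is.na(hit)) {
      seg <- list(times = seg$times[1:hit],
                  states = seg$states[1:hit, , drop = FALSE],
                  derivs = seg$derivs[1:hit, , drop = FALSE])
      converged <- TRUE
    }
    if (keep_trajectory) traj <- traj_append(traj, seg)
    x <- seg$states[nrow(seg$states), ]
    t_now <- seg$times[length(seg$times)]
    W <- 2 * W
    windows <- windows + 1L
  }
  if (!converged)
    stop_sg("steadygrad_equilibration_failure",
            "steady state not reached after %d doubling windows (t = %.4g, wrms = %.4g)",
            windows, t_now, wrms_residual(model$f(x, theta, u), x, rtol, atol))

  x_sim <- x
  wr_sim <- wr
  method <- "simulation"
  if (isTRUE(settings$newton_polish)) {
    polished <- newton_polish(model, theta, u, x, wr, rtol, atol,
                              settings$newton_max_iter)
    if (polished$n_accepted > 0L) {
      x <- polished$x; wr <- polished$wrms
      method <- "simulation+newton"
    }
  }

  structure(list(x_star = x, wrms = wr, t_equil = t_now,
                 n_rhs_evals = counters$forward - n0,
                 method = method, x_sim = x_sim, wrms_sim = wr_sim,
                 trajectory = traj),
            class = "equilibration_result")
}

# Newton iterations on f(x) = 0; keep a step only if the weighted residual
# decreases. Divergence or a singular Jacobian falls back to the simulation
# result with a warning.
newton_polish <- function(model, theta, u, x, wr, rtol, atol, max_iter) {
  n_acc <- 0L
  for (it in seq_len(max_iter)) {
    fx <- model$f(x, theta, u)
    step <- tryCatch(solve(model$jac(x, theta, u), fx), error = function(e) NULL)
    if (is.null(step)) {
      if (n_acc == 0L)
        warning("Newton polish skipped: singular Jacobian; keeping simulation result",
                call. = FALSE)
      break
    }
    x_new <- x - step
    wr_new <- tryCatch(
      wrms_residual(model$f(x_new, theta, u), x_new, rtol, atol),
      error = function(e) Inf)
    if (!is.finite(wr_new) || wr_new >= wr) break
    x <- x_new; wr <- wr_new; n_acc <- n_acc + 1L
    if (wr == 0) break
  }
  list(x = x, wrms = wr, n_accepted = n_acc)
}

#' Steady state for an experiment phase
#'
#' Pre-equilibration runs under the pre-equilibration inputs `u_pre` from
#' `x0(theta, u_pre)`; the returned steady state is the initial state of the
#' subsequent time course. Post-equilibration runs under the experimental
#' inputs `u` from the final time-course state.
#'
#' @param model Compiled `model_functions`.
#' @param theta Linear-scale parameters.
#' @param condition An experiment condition (see [sg_condition()]).
#' @param settings See [gradient_settings()].
#' @param phase `"pre"` or `"post"`.
#' @param x_init Starting state; required for `phase = "post"` (the final
#'   time-course state).
#' @param ... Passed to [equilibrate()].
#' @return An `equilibration_result`; failures are tagged with the phase.
#' @export
steady_state_for_condition <- function(model, theta, condition,
                                       settings = gradient_settings(),
                                       phase = c("pre", "post"),
                                       x_init = NULL, ...) {
  phase <- match.arg(phase)
  if (!isTRUE(condition$preeq) && !isTRUE(condition$posteq))
    stop_sg("steadygrad_noop_error",
            "condition '%s' requires neither pre- nor post-equilibration",
            condition$id %||% "?")
  res <- tryCatch({
    if (phase == "pre") {
      if (!isTRUE(condition$preeq))
        stop_sg("steadygrad_noop_error", "condition does not require pre-equilibration")
      equilibrate(model, theta, condition$u_pre,
                  x_init = model$x0(theta, condition$u_pre),
                  settings = settings, ...)
    } else {
      if (!isTRUE(condition$posteq))
        stop_sg("steadygrad_noop_error", "condition does not require post-equilibration")
      if (is.null(x_init))
        stop_sg("steadygrad_noop_error", "post-equilibration needs the final time-course state")
      equilibrate(model, theta, condition$u, x_init = x_init,
                  settings = settings, ...)
    }
  }, steadygrad_equilibration_failure = function(e) {
    stop_sg("steadygrad_equilibration_failure", "[%s-equilibration] %s",
            phase, conditionMessage(e))
  })
  res
}

#' @export
print.equilibration_result <- function(x, ...) {
  cat(sprintf("<equilibration_result> t_equil = %.4g, wrms = %.3e, method = %s\n",
              x$t_equil, x$wrms, x$method))
  cat("  x* =", paste(signif(x$x_star, 6), collapse = ", "), "\n")
  invisible(x)
}
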