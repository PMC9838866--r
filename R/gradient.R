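# Objective and gradient assembly shared by all gradient methods.
#
# Per condition the simulation runs: (optional) pre-equilibration under
# u_pre from x0(theta, u_pre); the time course under u on [t0 = 0, t_nt]
# (t_nt = last finite measurement time); (optional) post-equilibration under
# u from the final time-course state. The gradient is assembled from the
# direct observation-map terms, the adjoint quadratures (integrated or
# solved), and the initial-state sensitivity term -p(t0)^T dx0/dtheta, which
# is replaced by the pre-equilibration contribution when the initial state
# is itself a steady state. The parameter-scale chain rule is applied last.

# Forward phase of one condition. With use_polished = FALSE the equilibration
# results are taken at the raw simulation endpoints and their trajectories
# are kept — that is what the reference long-simulation adjoint observes.
simulate_condition <- function(model, theta, cond, meas_c, settings,
                               counters = NULL, use_polished = TRUE,
                               keep_equil_traj = !use_polished) {
  u <- cond$u
  tc <- meas_c[is.finite(meas_c$time), , drop = FALSE]
  ss <- meas_c[!is.finite(meas_c$time), , drop = FALSE]
  t_nt <- if (nrow(tc)) max(tc$time) else 0

  eq_pre <- NULL
  if (isTRUE(cond$preeq)) {
    eq_pre <- equilibrate(model, theta, cond$u_pre,
                          x_init = model$x0(theta, cond$u_pre),
                          settings = settings, counters = counters,
                          keep_trajectory = keep_equil_traj)
    x_t0 <- if (use_polished) eq_pre$x_star else eq_pre$x_sim
  } else {
    x_t0 <- model$x0(theta, u)
  }

  sim <- simulate_timecourse(model, theta, u, x_t0, 0, t_nt,
                             sort(unique(tc$time)), settings, counters)

  eq_post <- NULL
  x_ss <- NULL
  if (nrow(ss)) {
    eq_post <- equilibrate(model, theta, u, x_init = sim$x_end,
                           settings = settings, counters = counters,
                           keep_trajectory = keep_equil_traj)
    x_ss <- if (use_polished) eq_post$x_star else eq_post$x_sim
  }

  obs_idx_of <- function(ids) match(ids, model$observables)
  y_of <- function(x, ids) model$h(x, theta, u)[obs_idx_of(ids)]

  tc$obs_idx <- obs_idx_of(tc$observableId)
  if (nrow(tc)) {
    ut <- sort(unique(tc$time))
    xi <- match(round(tc$time, 12), round(ut, 12))
    tc$y <- vapply(seq_len(nrow(tc)), function(r)
      y_of(sim$meas_states[xi[r], ], tc$observableId[r]), numeric(1))
    tc$x_row <- xi
  }
  ss$obs_idx <- obs_idx_of(ss$observableId)
  if (nrow(ss)) ss$y <- vapply(seq_len(nrow(ss)), function(r)
    y_of(x_ss, ss$observableId[r]), numeric(1))
  tc$residual <- if (nrow(tc)) tc$measurement - tc$y else numeric(0)
  ss$residual <- if (nrow(ss)) ss$measurement - ss$y else numeric(0)
  tc$sigma <- tc$sd
  ss$sigma <- ss$sd

  list(u = u, tc = tc, ss = ss, t_nt = t_nt, traj = sim$traj,
       meas_states = sim$meas_states, x_end = sim$x_end, x_t0 = x_t0,
       x_ss = x_ss, eq_pre = eq_pre, eq_post = eq_post)
}

cond_nll <- function(sim) {
  tab <- rbind(sim$tc[c("measurement", "sd", "residual")],
               sim$ss[c("measurement", "sd", "residual")])
  if (nrow(tab) == 0L) return(0)
  sum(0.5 * (log(2 * pi * tab$sd^2) + (tab$residual / tab$sd)^2))
}

# Direct data term over time-course rows: -sum res/sigma^2 dh/dtheta at x(t_j).
direct_term_tc <- function(model, theta, u, sim) {
  g <- numeric(model$n_theta)
  tc <- sim$tc
  for (r in seq_len(nrow(tc))) {
    x <- sim$meas_states[tc$x_row[r], ]
    dhdt <- model$dhdtheta(x, theta, u)
    g <- g - tc$residual[r] / tc$sigma[r]^2 * dhdt[tc$obs_idx[r], ]
  }
  g
}

# ssASA gradient of one condition (linear scale).
cond_gradient_ssasa <- function(model, theta, cond, meas_c, settings, counters,
                                solves) {
  sim <- simulate_condition(model, theta, cond, meas_c, settings, counters,
                            use_polished = TRUE)
  g <- direct_term_tc(model, theta, cond$u, sim)
  p_carry <- numeric(model$n_x)
  tags <- character(0)

  if (nrow(sim$ss)) {
    post <- tryCatch(
      posteq_adjoint_contribution(model, sim$x_ss, theta, cond$u,
                                  sim$ss, settings),
      steadygrad_singular_jacobian = function(e) {
        if (!isTRUE(settings$allow_asa_fallback)) stop(e)
        NULL
      })
    if (is.null(post)) {
      # fall back to backward integration over the equilibration tail
      eq_post <- equilibrate(model, theta, cond$u, x_init = sim$x_end,
                             settings = settings, counters = counters,
                             keep_trajectory = TRUE)
      tail_traj <- eq_post$trajectory
      tail_traj$times <- tail_traj$times + sim$t_nt
      t_pp <- tail_traj$times[length(tail_traj$times)]
      x_pp <- tail_traj$states[nrow(tail_traj$states), ]
      p_pp <- measurement_jump(numeric(model$n_x), model, x_pp, theta,
                               cond$u, sim$ss)
      bw <- backward_pass(model, tail_traj, theta, cond$u,
                          sim$ss[0, ], t_pp, sim$t_nt, p_pp,
                          settings, counters, tag = "backward_equil")
      g <- g + bw$q
      dhdt <- model$dhdtheta(x_pp, theta, cond$u)
      for (r in seq_len(nrow(sim$ss)))
        g <- g - sim$ss$residual[r] / sim$ss$sigma[r]^2 * dhdt[sim$ss$obs_idx[r], ]
      p_carry <- bw$p
      tags <- c(tags, "posteq:asa-fallback")
    } else {
      g <- g + post$gradient
      p_carry <- post$p_carry
      solves$rows[[length(solves$rows) + 1L]] <-
        data.frame(condition = cond$id, phase = "post",
                   residual = post$residual, rcond = post$rcond,
                   norm_p_boundary = post$norm_p_boundary)
      tags <- c(tags, "posteq:linear-solve")
    }
  }

  bw <- backward_pass(model, sim$traj, theta, cond$u,
                      sim$tc[c("time", "obs_idx", "residual", "sigma")],
                      sim$t_nt, 0, p_carry, settings, counters,
                      tag = "backward_timecourse")
  g <- g + bw$q

  if (isTRUE(cond$preeq)) {
    pre <- tryCatch(
      preeq_adjoint_contribution(model, sim$eq_pre$x_star, theta,
                                 cond$u_pre, bw$p, settings),
      steadygrad_singular_jacobian = function(e) {
        if (!isTRUE(settings$allow_asa_fallback)) stop(e)
        NULL
      })
    if (is.null(pre)) {
      eq_pre <- equilibrate(model, theta, cond$u_pre,
                            x_init = model$x0(theta, cond$u_pre),
                            settings = settings, counters = counters,
                            keep_trajectory = TRUE)
      pre_traj <- eq_pre$trajectory
      t_len <- pre_traj$times[length(pre_traj$times)]
      pre_traj$times <- pre_traj$times - t_len  # ends at t0 = 0
      bw_pre <- backward_pass(model, pre_traj, theta, cond$u_pre,
                              sim$tc[0, ], 0, -t_len, bw$p,
                              settings, counters, tag = "backward_equil")
      g <- g + bw_pre$q -
        as.numeric(crossprod(model$dx0dtheta(theta, cond$u_pre), bw_pre$p))
      tags <- c(tags, "preeq:asa-fallback")
    } else {
      g <- g + pre$gradient
      solves$rows[[length(solves$rows) + 1L]] <-
        data.frame(condition = cond$id, phase = "pre",
                   residual = pre$residual, rcond = pre$rcond,
                   norm_p_boundary = pre$norm_p_boundary)
      tags <- c(tags, "preeq:linear-solve")
    }
  } else {
    g <- g - as.numeric(crossprod(model$dx0dtheta(theta, cond$u), bw$p))
  }
  list(nll = cond_nll(sim), gradient = g,
       method = paste(c("timecourse:adjoint", tags), collapse = ";"))
}

# Reference long-simulation adjoint gradient of one condition (linear scale).
cond_gradient_asa <- function(model, theta, cond, meas_c, settings, counters) {
  sim <- simulate_condition(model, theta, cond, meas_c, settings, counters,
                            use_polished = FALSE, keep_equil_traj = TRUE)
  g <- direct_term_tc(model, theta, cond$u, sim)
  p_carry <- numeric(model$n_x)

  if (nrow(sim$ss)) {
    tail_traj <- sim$eq_post$trajectory
    tail_traj$times <- tail_traj$times + sim$t_nt
    t_pp <- tail_traj$times[length(tail_traj$times)]
    p_pp <- measurement_jump(numeric(model$n_x), model, sim$x_ss, theta,
                             cond$u, sim$ss)
    bw_tail <- backward_pass(model, tail_traj, theta, cond$u, sim$ss[0, ],
                             t_pp, sim$t_nt, p_pp, settings, counters,
                             tag = "backward_equil")
    g <- g + bw_tail$q
    p_carry <- bw_tail$p
    dhdt <- model$dhdtheta(sim$x_ss, theta, cond$u)
    for (r in seq_len(nrow(sim$ss)))
      g <- g - sim$ss$residual[r] / sim$ss$sigma[r]^2 * dhdt[sim$ss$obs_idx[r], ]
  }

  bw <- backward_pass(model, sim$traj, theta, cond$u,
                      sim$tc[c("time", "obs_idx", "residual", "sigma")],
                      sim$t_nt, 0, p_carry, settings, counters,
                      tag = "backward_timecourse")
  g <- g + bw$q

  if (isTRUE(cond$preeq)) {
    pre_traj <- sim$eq_pre$trajectory
    t_len <- pre_traj$times[length(pre_traj$times)]
    pre_traj$times <- pre_traj$times - t_len  # pre-equilibration ends at t0 = 0
    bw_pre <- backward_pass(model, pre_traj, theta, cond$u_pre, sim$tc[0, ],
                            0, -t_len, bw$p, settings, counters,
                            tag = "backward_equil")
    g <- g + bw_pre$q
    # scalar product of the pre-equilibration initial-state sensitivities
    # with p(-t'): evaluated, not assumed zero
    g <- g - as.numeric(crossprod(model$dx0dtheta(theta, cond$u_pre), bw_pre$p))
  } else {
    g <- g - as.numeric(crossprod(model$dx0dtheta(theta, cond$u), bw$p))
  }
  list(nll = cond_nll(sim), gradient = g,
       method = "timecourse:adjoint;equilibration:long-simulation")
}

#' Objective function value
#'
#' Simulates every condition (with pre-/post-equilibration where required)
#' and evaluates the negative log-likelihood.
#'
#' @param problem An [sg_problem()].
#' @param theta Parameter vector on the estimation scale; defaults to the
#'   nominal values of the parameters table.
#' @param settings Overrides `problem$settings`.
#' @return The negative log-likelihood (scalar).
#' @export
objective_value <- function(problem, theta = NULL, settings = NULL) {
  settings <- settings %||% problem$settings
  theta <- theta %||% nominal_theta(problem)
  theta_lin <- theta_to_linear(problem, theta)
  nll <- 0
  for (cond in problem$conditions) {
    meas_c <- problem$measurements[problem$measurements$conditionId == cond$id, ,
                                   drop = FALSE]
    if (nrow(meas_c) == 0L) next
    sim <- simulate_condition(problem$model, theta_lin, cond, meas_c, settings)
    nll <- nll + cond_nll(sim)
  }
  nll
}

#' Objective gradient by a selectable method
#'
#' @param problem An [sg_problem()].
#' @param theta Parameter vector on the estimation scale (defaults to the
#'   nominal values).
#' @param method `"ssasa"` (steady-state adjoint; default), `"asa"`
#'   (reference long-simulation adjoint), `"forward"` (forward sensitivities
#'   with steady-state linear solves), or `"fd"` (central finite
#'   differences).
#' @param settings Overrides `problem$settings`.
#' @return A `gradient_result`: `nll`, `gradient` (estimation scale, named),
#'   `gradient_linear`, per-condition `method` tags, RHS-evaluation
#'   `counters`, and steady-state linear-solve diagnostics `solves`.
#' @export
objective_gradient <- function(problem, theta = NULL,
                               method = c("ssasa", "asa", "forward", "fd"),
                               settings = NULL) {
  method <- match.arg(method)
  settings <- settings %||% problem$settings
  theta <- theta %||% nominal_theta(problem)
  scales <- problem$parameters$parameterScale
  theta_lin <- theta_to_linear(problem, theta)
  model <- problem$model
  counters <- new_counters()

  if (method == "fd") {
    fn <- function(th) objective_value(problem, th, settings)
    g <- fd_gradient(fn, theta, step = settings$fd_step)
    return(new_gradient_result(
      nll = fn(theta), gradient = stats::setNames(g, names(theta)),
      gradient_linear = g / dtheta_lin_dscaled(theta_lin, scales),
      method = method, per_condition = list(), counters = counters,
      solves = empty_solves(), theta = theta))
  }

  nll <- 0
  g_lin <- numeric(model$n_theta)
  tags <- list()
  solves <- new.env(parent = emptyenv())
  solves$rows <- list()

  for (cond in problem$conditions) {
    meas_c <- problem$measurements[problem$measurements$conditionId == cond$id, ,
                                   drop = FALSE]
    if (nrow(meas_c) == 0L) next
    res <- switch(method,
      ssasa = cond_gradient_ssasa(model, theta_lin, cond, meas_c, settings,
                                  counters, solves),
      asa = cond_gradient_asa(model, theta_lin, cond, meas_c, settings,
                              counters),
      forward = cond_gradient_forward(model, theta_lin, cond, meas_c,
                                      settings, counters))
    if (anyNA(res$gradient) || any(!is.finite(res$gradient)))
      stop_sg("steadygrad_assembly_error",
              "non-finite gradient contribution for condition '%s'", cond$id)
    nll <- nll + res$nll
    g_lin <- g_lin + res$gradient
    tags[[cond$id]] <- res$method
  }

  new_gradient_result(
    nll = nll,
    gradient = stats::setNames(chain_rule(g_lin, theta_lin, scales),
                               problem$parameters$parameterId),
    gradient_linear = stats::setNames(g_lin, problem$parameters$parameterId),
    method = method, per_condition = tags, counters = counters,
    solves = if (length(solves$rows)) do.call(rbind, solves$rows)
             else empty_solves(),
    theta = theta)
}

dtheta_lin_dscaled <- function(theta_lin, scales) {
  scales <- normalize_scales(scales, length(theta_lin))
  d <- rep(1, length(theta_lin))
  d[scales == "log10"] <- theta_lin[scales == "log10"] * log(10)
  d
}

empty_solves <- function() {
  data.frame(condition = character(0), phase = character(0),
             residual = numeric(0), rcond = numeric(0),
             norm_p_boundary = numeric(0))
}

new_gradient_result <- function(nll, gradient, gradient_linear, method,
                                per_condition, counters, solves, theta) {
  structure(list(nll = nll, gradient = gradient,
                 gradient_linear = gradient_linear, method = method,
                 per_condition = per_condition,
                 counters = counters_as_list(counters),
                 solves = solves, theta = theta),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("<gradient_result> method = %s, nll = %.6g\n", x$method, x$nll))
  cat("  gradient (estimation scale):\n")
  print(signif(x$gradient, 6))
  cat(sprintf("  RHS evals: forward %d, backward (time course) %d, backward (equilibration) %d\n",
              x$counters$forward_rhs, x$counters$backward_rhs_timecourse,
              x$counters$backward_rhs_equil))
  invisible(x)
}

#' Steady-state adjoint (ssASA) gradient
#'
#' Convenience wrapper around [objective_gradient()] with
#' `method = "ssasa"`. Backward RHS evaluations over equilibration spans are
#' zero by construction (see the `counters` field of the result).
#'
#' @inheritParams objective_gradient
#' @return A `gradient_result`.
#' @export
ssasa_gradient <- function(problem, theta = NULL, settings = NULL)
  objective_gradient(problem, theta, method = "ssasa", settings = settings)

#' Reference long-simulation adjoint gradient
#'
#' Standard adjoint sensitivity analysis in which equilibration intervals
#' are handled by backward numerical integration over the same span the
#' forward equilibration used.
#'
#' @inheritParams objective_gradient
#' @return A `gradient_result`.
#' @export
asa_gradient_longsim <- function(problem, theta = NULL, settings = NULL)
  objective_gradient(problem, theta, method = "asa", settings = settings)
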