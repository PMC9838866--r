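# Steady-state adjoint sensitivity analysis (ssASA): over an equilibration
# interval the Jacobian is constant and the adjoint relaxes exponentially to
# p = 0 (backward-time stability of an exponentially stable steady state),
# so the gradient quadrature collapses to a matrix-vector product with
#   J(x*)^T p_integral = -p_boundary
# replacing backward numerical integration by one linear solve.

norm2 <- function(v) sqrt(sum(v^2))

# Solve J^T p_integral = -p_boundary with LU, with diagnostics.
ss_adjoint_solve <- function(model, x_star, theta, u, p_boundary, settings) {
  J <- model$jac(x_star, theta, u)
  rc <- assert_nonsingular(J, settings$rcond_tol)
  p_int <- solve(t(J), -p_boundary)
  list(p_integral = as.numeric(p_int),
       residual = norm2(as.numeric(t(J) %*% p_int) + p_boundary),
       rcond = as.numeric(rc),
       norm_p_boundary = norm2(p_boundary))
}

#' Post-equilibration gradient contribution by a steady-state linear solve
#'
#' Forms the adjoint boundary value from the steady-state residuals,
#' \eqn{p(t'') = \sum_i (\partial h_i/\partial x)^T (\bar y_i^* - y_i^*) /
#' \sigma_i^{*2}}, solves \eqn{J(x^*)^T p_{int} = -p(t'')}, and returns the
#' gradient contribution \eqn{-p_{int}^T \partial f/\partial\theta|_{x^*}}
#' together with the direct steady-state data term
#' \eqn{-\sum_i (\bar y_i^* - y_i^*)/\sigma_i^{*2} \,
#' \partial h_i/\partial\theta|_{x^*}}. Because `p = 0` is stable in
#' backward time, the adjoint handed to the time-course backward pass at
#' `t_nt` is exactly zero (`p_carry`).
#'
#' @param model Compiled `model_functions`.
#' @param x_star Converged steady state under `u`.
#' @param theta,u Linear-scale parameters and inputs.
#' @param ss_rows Data frame of steady-state measurements: `obs_idx`,
#'   `residual`, `sigma`.
#' @param settings See [gradient_settings()].
#' @return List: `gradient` (length `n_theta`), `p_carry` (zero vector),
#'   `p_boundary`, `p_integral`, linear-solve `residual`, `rcond`.
#' @export
posteq_adjoint_contribution <- function(model, x_star, theta, u, ss_rows,
                                        settings = gradient_settings()) {
  n_x <- model$n_x
  p_b <- measurement_jump(numeric(n_x), model, x_star, theta, u, ss_rows)
  sol <- ss_adjoint_solve(model, x_star, theta, u, p_b, settings)
  g <- -as.numeric(crossprod(model$dfdtheta(x_star, theta, u), sol$p_integral))
  if (nrow(ss_rows)) {
    dhdt <- model$dhdtheta(x_star, theta, u)
    for (r in seq_len(nrow(ss_rows)))
      g <- g - ss_rows$residual[r] / ss_rows$sigma[r]^2 * dhdt[ss_rows$obs_idx[r], ]
  }
  c(list(gradient = g, p_carry = numeric(n_x), p_boundary = p_b), sol)
}

#' Pre-equilibration gradient contribution by a steady-state linear solve
#'
#' The adjoint state reaching the start of the time course, `p(t0)`
#' (including any jump exactly at `t0`), seeds the backward pre-equilibration
#' problem. At the pre-equilibration steady state the quadrature collapses
#' to \eqn{J(x^*(\theta, u^e))^T p_{int} = -p(t_0)} and the contribution is
#' \eqn{-p_{int}^T \partial f/\partial\theta} evaluated at
#' \eqn{(x^*(\theta, u^e), u^e)}. No initial-state sensitivity term is added:
#' the adjoint has relaxed to zero at the far end of the pre-equilibration
#' interval, so its scalar product with the initial state sensitivities
#' vanishes.
#'
#' @param model Compiled `model_functions`.
#' @param x_star_pre Converged pre-equilibration steady state.
#' @param theta Linear-scale parameters.
#' @param u_pre Pre-equilibration inputs.
#' @param p_at_t0 Adjoint state after the time-course backward pass.
#' @param settings See [gradient_settings()].
#' @return List: `gradient`, `p_boundary`, `p_integral`, `residual`, `rcond`.
#' @export
preeq_adjoint_contribution <- function(model, x_star_pre, theta, u_pre,
                                       p_at_t0, settings = gradient_settings()) {
  sol <- ss_adjoint_solve(model, x_star_pre, theta, u_pre, p_at_t0, settings)
  g <- -as.numeric(crossprod(model$dfdtheta(x_star_pre, theta, u_pre),
                             sol$p_integral))
  c(list(gradient = g, p_boundary = as.numeric(p_at_t0)), sol)
}
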