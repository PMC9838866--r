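# Multi-start bounded gradient-based maximum-likelihood estimation.

#' Multi-start maximum-likelihood parameter estimation
#'
#' Draws `n_starts` start points uniformly within the parameter bounds on
#' the estimation scale (seeded, reproducible) and runs a bounded
#' quasi-Newton local optimizer (`L-BFGS-B`) from each, using the selected
#' gradient method. The optimizer contract is: bounded, gradient-based,
#' deterministic given a start point.
#'
#' @param problem An [sg_problem()] with finite bounds for every parameter.
#' @param n_starts Number of local optimizations.
#' @param seed Seed for the start-point draws.
#' @param max_iter Iteration cap per local optimization.
#' @param gradient_method Passed to [objective_gradient()].
#' @param settings Overrides `problem$settings`.
#' @param starts Optional matrix of start points (`n_starts` x `n_theta`,
#'   estimation scale) overriding the uniform draws.
#' @return An `estimation_report`: `results` (one row per start, sorted by
#'   final negative log-likelihood: `nll`, convergence flag, iteration
#'   counts, parameters on the estimation scale), `best` (list with `theta`
#'   on the estimation and linear scales and the final `nll`), `starts`,
#'   `seed`.
#' @export
estimate <- function(problem, n_starts = 20, seed = 1, max_iter = 150,
                     gradient_method = "ssasa", settings = NULL,
                     starts = NULL) {
  settings <- settings %||% problem$settings
  p <- problem$parameters
  lb <- to_estimation_scale(p$lowerBound, p$parameterScale)
  ub <- to_estimation_scale(p$upperBound, p$parameterScale)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop_sg("steadygrad_domain_error",
            "estimation requires finite bounds for every parameter")
  n_th <- nrow(p)

  if (is.null(starts)) {
    set.seed(seed)
    # one draw per start (row-wise) so the seeded start stream is stable:
    # the first k starts are identical regardless of n_starts
    starts <- t(vapply(seq_len(n_starts),
                       function(s) lb + stats::runif(n_th) * (ub - lb),
                       numeric(n_th)))
  } else {
    starts <- as.matrix(starts)
    n_starts <- nrow(starts)
  }
  colnames(starts) <- p$parameterId

  # fn and gr share one simulation per parameter vector
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  refresh <- function(th) {
    if (is.null(cache$theta) || !identical(cache$theta, th)) {
      res <- tryCatch(
        objective_gradient(problem, stats::setNames(th, p$parameterId),
                           method = gradient_method, settings = settings),
        error = function(e) NULL)
      if (is.null(res)) {
        cache$nll <- 1e10
        cache$grad <- numeric(n_th)
      } else {
        cache$nll <- res$nll
        cache$grad <- unname(res$gradient)
      }
      cache$theta <- th
    }
  }
  fn <- function(th) { refresh(th); cache$nll }
  gr <- function(th) { refresh(th); cache$grad }

  rows <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[s, ], fn, gr, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[s]] <- data.frame(start = s, nll = NA_real_, converged = FALSE,
                              n_fn = NA_integer_, n_gr = NA_integer_,
                              message = "optimizer error")
      next
    }
    par <- pmin(pmax(fit$par, lb), ub)
    row <- data.frame(start = s, nll = fit$value,
                      converged = fit$convergence == 0L,
                      n_fn = fit$counts[1L], n_gr = fit$counts[2L],
                      message = fit$message %||% "")
    for (k in seq_len(n_th)) row[[p$parameterId[k]]] <- par[k]
    rows[[s]] <- row
  }
  ok <- !vapply(rows, function(r) is.na(r$nll), logical(1))
  if (!any(ok))
    stop_sg("steadygrad_estimation_failure",
            "all %d starts failed; see per-start diagnostics", n_starts)
  results <- do.call(rbind, c(rows[ok], rows[!ok]))
  results <- results[order(results$nll), ]
  rownames(results) <- NULL

  best_est <- stats::setNames(as.numeric(results[1L, p$parameterId]),
                              p$parameterId)
  structure(list(
    results = results,
    best = list(theta = best_est,
                theta_linear = stats::setNames(
                  apply_scale(best_est, p$parameterScale), p$parameterId),
                nll = results$nll[1L]),
    starts = starts, seed = seed, gradient_method = gradient_method,
    bounds = list(lower = lb, upper = ub)),
    class = "estimation_report")
}

#' @export
print.estimation_report <- function(x, ...) {
  cat(sprintf("<estimation_report> %d start(s), gradient method = %s\n",
              nrow(x$results), x$gradient_method))
  cat(sprintf("  best nll = %.6g\n", x$best$nll))
  cat("  best parameters (linear scale):\n")
  print(signif(x$best$theta_linear, 6))
  invisible(x)
}

#' Compare gradient methods on one problem
#'
#' Computes the gradient with each requested method and tabulates the
#' per-parameter values and the pairwise maximum relative differences
#' (infinity norm of the difference over the larger infinity norm).
#'
#' @inheritParams objective_gradient
#' @param methods Methods to compare.
#' @return List with `table` (per-parameter gradients, estimation scale),
#'   `pairwise` (matrix of relative differences), and the `gradient_result`
#'   objects in `results`.
#' @export
check_gradients <- function(problem, theta = NULL,
                            methods = c("ssasa", "asa", "forward", "fd"),
                            settings = NULL) {
  results <- lapply(methods, function(m)
    objective_gradient(problem, theta, method = m, settings = settings))
  names(results) <- methods
  tab <- data.frame(parameterId = problem$parameters$parameterId)
  for (m in methods) tab[[m]] <- unname(results[[m]]$gradient)
  pw <- matrix(0, length(methods), length(methods),
               dimnames = list(methods, methods))
  for (a in methods) for (b in methods)
    pw[a, b] <- grad_rel_diff(results[[a]]$gradient, results[[b]]$gradient)
  list(table = tab, pairwise = pw, results = results)
}

# max |g1 - g2| relative to the larger gradient magnitude
grad_rel_diff <- function(g1, g2) {
  scale <- max(max(abs(g1)), max(abs(g2)), .Machine$double.eps)
  max(abs(g1 - g2)) / scale
}
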