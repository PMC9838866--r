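#' Compile a reaction network into evaluable model functions
#'
#' Generates every derivative the gradient methods need symbolically (via
#' [stats::D]; no numerical differentiation) and wraps them as plain R
#' closures of `(x, theta, u)`:
#' \itemize{
#'   \item `f(x, theta, u)` — right-hand side, length `n_x`
#'   \item `jac(x, theta, u)` — Jacobian \eqn{\partial f / \partial x}, `n_x` x `n_x`
#'   \item `dfdtheta(x, theta, u)` — \eqn{\partial f / \partial \theta}, `n_x` x `n_theta`
#'   \item `x0(theta, u)`, `dx0dtheta(theta, u)` — initial state and its sensitivity
#'   \item `h(x, theta, u)`, `dhdx(...)`, `dhdtheta(...)` — observation map and derivatives
#' }
#' Evaluation is side-effect free and repeatable. Inputs `u` enter
#' expressions like parameters but carry no sensitivities. For speed, each
#' function is materialized as a single closure whose body is the vector (or
#' matrix) of substituted expressions, so one call evaluates the whole
#' quantity without per-element dispatch — right-hand sides are evaluated
#' inside stiff integrators many thousands of times per gradient.
#'
#' @param network A `reaction_network` from [parse_model()].
#' @return An object of class `model_functions`; also carries `species`,
#'   `parameters`, `inputs`, `observables` (names), the dimensions
#'   `n_x`, `n_theta`, `n_y`, and the originating `network`.
#' @examples
#' net <- parse_model("A -> B at k1*A; B -> A at k2*B")
#' m <- compile_model(net)
#' m$jac(c(A = 1, B = 0), c(k1 = 2, k2 = 1), NULL)
#' @export
compile_model <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  sp <- network$species
  pa <- network$parameters
  inp <- network$inputs
  n_x <- length(sp)
  n_th <- length(pa)
  obs <- network$observables
  n_y <- length(obs)

  # symbol -> positional indexing into the closure arguments
  map <- c(
    stats::setNames(lapply(seq_along(sp), function(i) call("[", quote(x), i)), sp),
    stats::setNames(lapply(seq_along(pa), function(j) call("[", quote(theta), j)), pa),
    stats::setNames(lapply(seq_along(inp), function(k) call("[", quote(u), k)), inp))

  vec_body <- function(exprs) {
    if (length(exprs) == 0L) return(quote(numeric(0)))
    as.call(c(quote(c), lapply(unname(exprs), subst_symbols, map = map)))
  }
  mat_body <- function(exprs_ij, nr, nc) {
    if (nr == 0L || nc == 0L)
      return(call("matrix", quote(numeric(0)), nr, nc))
    flat <- vector("list", nr * nc)
    for (j in seq_len(nc)) for (i in seq_len(nr))
      flat[[(j - 1L) * nr + i]] <- subst_symbols(exprs_ij[[i]][[j]], map)
    call("matrix", as.call(c(quote(c), flat)), nr, nc)
  }
  make_fun <- function(body_expr, with_x = TRUE) {
    fn <- if (with_x) function(x, theta, u = NULL) NULL
          else function(theta, u = NULL) NULL
    body(fn) <- body_expr
    environment(fn) <- new.env(parent = baseenv())
    fn
  }
  # reorder/strip names from the input vector once per call
  order_u <- function(u) {
    if (length(inp) == 0L) return(NULL)
    v <- if (is.null(names(u))) u else u[inp]
    if (length(v) != length(inp) || anyNA(v))
      stop_sg("steadygrad_domain_error", "inputs must supply values for: %s",
              paste(inp, collapse = ", "))
    unname(as.numeric(v))
  }
  wrap_xtu <- function(fn) function(x, theta, u = NULL)
    fn(unname(as.numeric(x)), unname(as.numeric(theta)), order_u(u))
  wrap_tu <- function(fn) function(theta, u = NULL)
    fn(unname(as.numeric(theta)), order_u(u))

  f_ex    <- network$odes
  jac_ex  <- d_expr_matrix(f_ex, sp)
  dfdt_ex <- d_expr_matrix(f_ex, pa)
  x0_ex   <- network$x0
  dx0_ex  <- d_expr_matrix(x0_ex, pa)
  h_ex    <- obs
  dhdx_ex <- d_expr_matrix(h_ex, sp)
  dhdt_ex <- d_expr_matrix(h_ex, pa)

  model <- list(
    f         = wrap_xtu(make_fun(vec_body(f_ex))),
    jac       = wrap_xtu(make_fun(mat_body(jac_ex, n_x, n_x))),
    dfdtheta  = wrap_xtu(make_fun(mat_body(dfdt_ex, n_x, n_th))),
    x0        = wrap_tu(make_fun(vec_body(x0_ex), with_x = FALSE)),
    dx0dtheta = wrap_tu(make_fun(mat_body(dx0_ex, n_x, n_th), with_x = FALSE)),
    h         = wrap_xtu(make_fun(vec_body(h_ex))),
    dhdx      = wrap_xtu(make_fun(mat_body(dhdx_ex, n_y, n_x))),
    dhdtheta  = wrap_xtu(make_fun(mat_body(dhdt_ex, n_y, n_th))),
    species = sp, parameters = pa, inputs = inp,
    observables = names(obs),
    n_x = n_x, n_theta = n_th, n_y = n_y,
    network = network
  )
  class(model) <- "model_functions"
  model
}

#' @export
print.model_functions <- function(x, ...) {
  cat(sprintf("<model_functions> n_x = %d, n_theta = %d, n_y = %d\n",
              x$n_x, x$n_theta, x$n_y))
  invisible(x)
}
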