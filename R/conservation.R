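# Conserved-moiety detection and model reduction.
#
# A conserved quantity is a linear combination of states that is constant
# along every trajectory: L S = 0 implies d(L x)/dt = L f = L S v = 0. Its
# presence makes the steady-state Jacobian singular, which blocks the
# steady-state adjoint linear solves; eliminating one state per conserved
# law restores nonsingularity for exponentially stable steady states.
# The left null space is computed exactly over the rationals (integer
# fraction-free elimination), which is robust at the model sizes this
# package targets.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}
gcd_vec <- function(v) {
  g <- 0
  for (x in v) g <- gcd2(g, x)
  g
}

# Fraction-free row echelon form of an integer matrix; rows stay integral.
# Returns list(mat, pivots) where pivots[k] is the pivot column of row k.
rref_int <- function(A) {
  A <- round(A)
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    cand <- which(A[row:m, col] != 0) + row - 1L
    if (!length(cand)) next
    # smallest magnitude pivot limits coefficient growth
    pr <- cand[which.min(abs(A[cand, col]))]
    if (pr != row) A[c(row, pr), ] <- A[c(pr, row), ]
    p <- A[row, col]
    for (r in seq_len(m)) {
      if (r == row || A[r, col] == 0) next
      A[r, ] <- p * A[r, ] - A[r, col] * A[row, ]
      g <- gcd_vec(A[r, ])
      if (g > 1) A[r, ] <- A[r, ] / g
    }
    g <- gcd_vec(A[row, ])
    if (g > 1) A[row, ] <- A[row, ] / g
    if (A[row, col] < 0) A[row, ] <- -A[row, ]
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(mat = A, pivots = pivots, rank = length(pivots))
}

# Integer basis of the null space of an integer matrix A (A y = 0).
nullspace_int <- function(A) {
  n <- ncol(A)
  rr <- rref_int(A)
  piv <- rr$pivots
  free <- setdiff(seq_len(n), piv)
  lapply(free, function(fc) {
    # for pivot row k: p_k * y[piv[k]] + A[k, fc] = 0; clear denominators by
    # the exact lcm of the pivots so entries stay integral
    dens <- vapply(seq_along(piv), function(k) rr$mat[k, piv[k]], numeric(1))
    D <- 1
    for (d in dens) D <- D * d / gcd2(D, d)
    y <- numeric(n)
    y[fc] <- D
    for (k in seq_along(piv)) y[piv[k]] <- -rr$mat[k, fc] * (D / dens[k])
    g <- gcd_vec(y)
    if (g > 1) y <- y / g
    if (y[which(y != 0)[1L]] < 0) y <- -y
    y
  })
}

#' Detect conserved quantities of a stoichiometric matrix
#'
#' Computes an exact integer basis of the left null space of `S`
#' (\eqn{L S = 0}), i.e. the conserved linear combinations of states, and
#' selects one state to eliminate per conservation law: the state with the
#' largest absolute coefficient, ties broken by the highest declaration
#' index. The chosen column is cleared from the other laws by exact row
#' operations, so each eliminated state appears in exactly one law and every
#' replacement expression references only kept states.
#'
#' @param S Integer stoichiometric matrix (`n_x` rows = species, columns =
#'   reactions).
#' @param network Optional `reaction_network`; when given, symbolic total
#'   expressions \eqn{T_c(\theta, u) = L_c x_0(\theta, u)} are attached so a
#'   reduced model can propagate the parameter dependence of the totals.
#' @return A `conservation_analysis`: `L` (integer matrix, `n_c` x `n_x`,
#'   rows in smallest integer form), `n_c`, `eliminated_indices`,
#'   `kept_indices`, and (with `network`) `totals_expr`.
#' @examples
#' S <- matrix(c(-1, 1, 1, -1), nrow = 2)  # A <-> B
#' find_conserved_quantities(S)$L          # total A + B conserved
#' @export
find_conserved_quantities <- function(S, network = NULL) {
  S <- as.matrix(S)
  n_x <- nrow(S)
  basis <- nullspace_int(t(S))
  n_c <- length(basis)
  if (n_c == 0L) {
    L <- matrix(0, 0L, n_x)
  } else {
    L <- do.call(rbind, basis)
  }
  eliminated <- integer(0)
  if (n_c > 0L) {
    for (c_i in seq_len(n_c)) {
      cand <- setdiff(seq_len(n_x), eliminated)
      coefs <- abs(L[c_i, cand])
      if (all(coefs == 0))
        stop_sg("steadygrad_reduction_error",
                "conservation law %d has no eliminable state", c_i)
      best <- max(coefs)
      e <- max(cand[coefs == best])  # ties -> highest declaration index
      eliminated <- c(eliminated, e)
      for (r in seq_len(n_c)) {
        if (r == c_i || L[r, e] == 0) next
        L[r, ] <- L[c_i, e] * L[r, ] - L[r, e] * L[c_i, ]
        g <- gcd_vec(L[r, ])
        if (g > 1) L[r, ] <- L[r, ] / g
      }
      if (L[c_i, e] < 0) L[c_i, ] <- -L[c_i, ]
    }
  }
  totals_expr <- NULL
  if (!is.null(network) && n_c > 0L) {
    totals_expr <- lapply(seq_len(n_c), function(c_i)
      linear_combination_expr(L[c_i, ], network$x0))
  }
  if (!is.null(network) && n_c > 0L) colnames(L) <- network$species
  structure(list(L = L, n_c = n_c,
                 eliminated_indices = eliminated,
                 kept_indices = setdiff(seq_len(n_x), eliminated),
                 totals_expr = totals_expr),
            class = "conservation_analysis")
}

# Sum coef_i * expr_i as a language object, skipping zero coefficients.
linear_combination_expr <- function(coefs, exprs) {
  acc <- NULL
  for (i in seq_along(coefs)) {
    if (coefs[i] == 0) next
    term <- if (coefs[i] == 1) exprs[[i]] else call("*", as.numeric(coefs[i]), exprs[[i]])
    acc <- if (is.null(acc)) term else call("+", acc, term)
  }
  if (is.null(acc)) 0 else acc
}

#' @export
print.conservation_analysis <- function(x, ...) {
  cat(sprintf("<conservation_analysis> %d conserved law(s)\n", x$n_c))
  if (x$n_c > 0) print(x$L)
  invisible(x)
}

#' Eliminate conserved moieties from a compiled model
#'
#' Substitutes each eliminated state symbolically by
#' \eqn{(T_c - \sum_{j \ne e} L_{cj} x_j) / L_{ce}} in the right-hand side
#' and observation map, where the total \eqn{T_c = L_c x_0(\theta, u)} is
#' itself kept symbolic so that its dependence on parameters propagates into
#' the reduced \eqn{\partial f/\partial \theta} and
#' \eqn{\partial x_0/\partial \theta}. The reduced steady-state Jacobian is
#' nonsingular for exponentially stable steady states, which is the
#' applicability condition of the steady-state adjoint solves.
#'
#' @param model A compiled `model_functions` whose network is reaction-defined.
#' @param analysis A `conservation_analysis`; defaults to analysing the
#'   model's stoichiometric matrix. With `n_c = 0` the model is returned
#'   unchanged.
#' @return A compiled `model_functions` on the kept states, with a
#'   `reduction` field recording `L`, eliminated/kept indices and the full
#'   model (used to reconstruct eliminated states for reporting).
#' @export
reduce_model <- function(model, analysis = NULL) {
  stopifnot(inherits(model, "model_functions"))
  network <- model$network
  if (is.null(analysis)) {
    if (is.null(network$S)) {
      warning("raw-ODE model without stoichiometry: conserved-moiety detection skipped")
      return(model)
    }
    analysis <- find_conserved_quantities(network$S, network)
  }
  if (analysis$n_c == 0L) return(model)
  if (is.null(analysis$totals_expr))
    analysis$totals_expr <- lapply(seq_len(analysis$n_c), function(c_i)
      linear_combination_expr(analysis$L[c_i, ], network$x0))

  sp <- network$species
  L <- analysis$L
  elim <- analysis$eliminated_indices
  kept <- analysis$kept_indices

  # replacement map: eliminated symbol -> (T_c - sum_j L_cj x_j) / L_ce
  map <- list()
  for (c_i in seq_len(analysis$n_c)) {
    e <- elim[c_i]
    acc <- analysis$totals_expr[[c_i]]
    for (j in kept) {
      if (L[c_i, j] == 0) next
      acc <- call("-", acc, if (L[c_i, j] == 1) as.name(sp[j])
                            else call("*", as.numeric(L[c_i, j]), as.name(sp[j])))
    }
    if (L[c_i, e] != 1) acc <- call("/", acc, as.numeric(L[c_i, e]))
    map[[sp[e]]] <- acc
  }

  red <- network
  red$species <- sp[kept]
  red$S <- NULL
  red$rates <- list()
  red$odes <- lapply(network$odes[kept], subst_symbols, map = map)
  red$x0 <- network$x0[kept]
  red$observables <- lapply(network$observables, subst_symbols, map = map)

  out <- compile_model(structure(red, class = "reaction_network"))
  out$reduction <- list(L = L, eliminated_indices = elim, kept_indices = kept,
                        eliminated_species = sp[elim], full_model = model,
                        totals_expr = analysis$totals_expr)
  out
}

#' Check that a steady-state Jacobian is numerically nonsingular
#'
#' The steady-state adjoint linear systems have a unique solution only if
#' the (transposed) Jacobian at the steady state is nonsingular. This helper
#' estimates the reciprocal condition number and raises a classed error
#' (`steadygrad_singular_jacobian`) below the tolerance, recommending
#' conserved-moiety removal via [reduce_model()].
#'
#' @param jac_at_ss Square numeric matrix (Jacobian at the steady state).
#' @param tolerance Reciprocal-condition threshold; default `1e-10`, a
#'   machine-precision safety factor for double-precision solves.
#' @return The reciprocal condition estimate, invisibly.
#' @export
assert_nonsingular <- function(jac_at_ss, tolerance = 1e-10) {
  jac_at_ss <- as.matrix(jac_at_ss)
  stopifnot(nrow(jac_at_ss) == ncol(jac_at_ss))
  rc <- tryCatch(rcond(jac_at_ss), error = function(e) 0)
  if (!is.finite(rc) || rc < tolerance)
    stop_sg("steadygrad_singular_jacobian",
            paste0("steady-state Jacobian is numerically singular ",
                   "(reciprocal condition %.3e < %.1e); if the model has ",
                   "conserved quantities, removing them with reduce_model() ",
                   "typically restores nonsingularity"),
            rc, tolerance)
  invisible(rc)
}

#' Tabulate a conservation analysis
#'
#' @param analysis A `conservation_analysis` with species column names.
#' @param model Optional compiled full model, used with `theta`/`conditions`
#'   to evaluate the conserved totals per experimental condition.
#' @param theta Linear-scale parameter vector.
#' @param conditions Named list of input vectors (one per condition).
#' @param file Optional TSV path to write the report to.
#' @return A data frame: law index, one column per species coefficient, and
#'   one `total.<condition>` column per supplied condition.
#' @export
conservation_report <- function(analysis, model = NULL, theta = NULL,
                                conditions = NULL, file = NULL) {
  df <- as.data.frame(analysis$L)
  df <- cbind(law = seq_len(analysis$n_c), df)
  if (!is.null(model) && !is.null(theta) && length(conditions)) {
    for (cn in names(conditions)) {
      x0 <- model$x0(theta, conditions[[cn]])
      df[[paste0("total.", cn)]] <- as.numeric(analysis$L %*% x0)
    }
  }
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
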