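# Expression-level helpers shared by model compilation and moiety reduction.
# Rate laws, initial conditions and observables are stored as R language
# objects; all derivatives are taken symbolically with stats::D.

#' @importFrom stats D
NULL

# Signal a classed error so callers can distinguish failure modes.
stop_sg <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "steadygrad_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Parse a scalar string into a single R expression (language object).
parse_expr1 <- function(text, what = "expression") {
  ex <- tryCatch(parse(text = text, keep.source = FALSE),
                 error = function(e) stop_sg("steadygrad_parse_error",
                                             "cannot parse %s '%s': %s", what, text, conditionMessage(e)))
  if (length(ex) != 1L)
    stop_sg("steadygrad_parse_error", "%s '%s' must be a single expression", what, text)
  ex[[1L]]
}

# Replace symbols by language objects throughout an expression.
# `map` is a named list: symbol name -> replacement language object.
subst_symbols <- function(expr, map) {
  if (is.symbol(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(map)) return(map[[nm]])
    return(expr)
  }
  if (is.call(expr)) {
    for (k in seq_along(expr)[-1L]) {
      if (!is.null(expr[[k]])) expr[[k]] <- subst_symbols(expr[[k]], map)
    }
    return(expr)
  }
  expr
}

# Symbolic derivative with a package-classed error on failure.
d_expr <- function(expr, var) {
  tryCatch(D(expr, var),
           error = function(e) stop_sg("steadygrad_compile_error",
                                       "expression '%s' is not differentiable in '%s': %s",
                                       deparse1(expr), var, conditionMessage(e)))
}

# Differentiate a list of expressions w.r.t. a vector of variable names;
# returns a list-of-lists indexed [[i]][[j]] = d expr_i / d var_j.
d_expr_matrix <- function(exprs, vars) {
  lapply(exprs, function(e) lapply(vars, function(v) d_expr(e, v)))
}

# Evaluate a list of expressions to a numeric vector under named values.
eval_expr_vec <- function(exprs, vals) {
  out <- numeric(length(exprs))
  for (i in seq_along(exprs)) out[i] <- eval(exprs[[i]], vals)
  out
}

# Evaluate a list-of-lists of expressions to a numeric matrix.
eval_expr_mat <- function(exprs, vals, nr, nc) {
  m <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    row <- exprs[[i]]
    for (j in seq_len(nc)) m[i, j] <- eval(row[[j]], vals)
  }
  m
}

# All symbols used in an expression (excluding call heads / function names).
expr_symbols <- function(expr) all.vars(expr)
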