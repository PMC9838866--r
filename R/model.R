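#' Parse a model definition into a reaction network
#'
#' Builds a validated `reaction_network` from a plain-text model definition.
#' The canonical form is the `steadygrad-model-v1` YAML dialect with keys
#' `species`, `parameters`, `inputs` (optional), `reactions` (each either a
#' string `"2 A + B -> C at k*A^2*B"` or a list with `reactants`, `products`,
#' `rate`), `odes` (raw right-hand sides, allowed only when `reactions` is
#' empty), `initials` and `observables`. A bare reaction string such as
#' `"A -> B at k1*A; B -> A at k2*B"` is accepted as a shorthand: species are
#' taken in order of first appearance and every remaining rate symbol becomes
#' a parameter.
#'
#' The model class is \deqn{\dot x = f(x, \theta, u), \quad x(t_0) = x_0(\theta, u)}
#' with constant experimental inputs \eqn{u}; for reaction-defined models the
#' right-hand side is assembled symbolically as \eqn{f = S v(x, \theta, u)}
#' from the stoichiometric matrix \eqn{S} and the rate vector \eqn{v}. Rate
#' expressions may be arbitrary differentiable closed forms (mass action,
#' Michaelis--Menten, ...). State ordering is declaration order and is used
#' consistently by every matrix in the package.
#'
#' @param definition A list (already-parsed YAML), a path to a YAML file, or
#'   a reaction-string shorthand.
#' @return An object of class `reaction_network` with fields `species`,
#'   `parameters`, `inputs`, `S` (stoichiometric matrix or `NULL` for raw-ODE
#'   models), `rates`, `odes` (assembled right-hand sides, one expression per
#'   species), `x0`, and `observables`.
#' @examples
#' net <- parse_model("A -> B at k1*A; B -> A at k2*B")
#' net$S
#' @export
parse_model <- function(definition) {
  if (is.character(definition) && length(definition) == 1L) {
    if (file.exists(definition)) {
      definition <- yaml::read_yaml(definition)
    } else if (grepl("->", definition, fixed = TRUE)) {
      definition <- reaction_shorthand_to_list(definition)
    } else {
      stop_sg("steadygrad_parse_error",
              "model definition '%s' is neither an existing file nor a reaction string",
              definition)
    }
  }
  if (!is.list(definition))
    stop_sg("steadygrad_parse_error", "model definition must be a list, file path or reaction string")

  fmt <- definition$format
  if (!is.null(fmt) && !identical(fmt, "steadygrad-model-v1"))
    stop_sg("steadygrad_parse_error", "unsupported model format '%s'", fmt)

  species <- as.character(unlist(definition$species))
  if (length(species) == 0L)
    stop_sg("steadygrad_parse_error", "model declares no species")
  if (anyDuplicated(species))
    stop_sg("steadygrad_parse_error", "duplicate species declaration: %s",
            paste(unique(species[duplicated(species)]), collapse = ", "))
  parameters <- as.character(unlist(definition$parameters))
  inputs <- as.character(unlist(definition$inputs))
  known <- c(species, parameters, inputs)
  if (anyDuplicated(known))
    stop_sg("steadygrad_parse_error", "symbol declared twice (species/parameter/input): %s",
            paste(unique(known[duplicated(known)]), collapse = ", "))

  check_symbols <- function(expr, allowed, where) {
    bad <- setdiff(expr_symbols(expr), c(allowed, "pi"))
    if (length(bad))
      stop_sg("steadygrad_parse_error", "undeclared symbol '%s' in %s '%s'",
              bad[1L], where, deparse1(expr))
  }

  reactions <- definition$reactions
  odes_def <- definition$odes
  n_x <- length(species)

  if (length(reactions)) {
    if (length(odes_def))
      stop_sg("steadygrad_parse_error", "a model may declare reactions or raw odes, not both")
    parsed <- lapply(reactions, parse_reaction_entry, species = species)
    n_r <- length(parsed)
    S <- matrix(0L, n_x, n_r, dimnames = list(species, NULL))
    rates <- vector("list", n_r)
    for (r in seq_len(n_r)) {
      pr <- parsed[[r]]
      for (nm in names(pr$reactants)) S[nm, r] <- S[nm, r] - as.integer(pr$reactants[[nm]])
      for (nm in names(pr$products))  S[nm, r] <- S[nm, r] + as.integer(pr$products[[nm]])
      rates[[r]] <- parse_expr1(pr$rate, "rate expression")
      check_symbols(rates[[r]], known, "rate")
    }
    odes <- assemble_rhs(S, rates)
  } else {
    if (is.null(odes_def))
      stop_sg("steadygrad_parse_error", "model must declare reactions or raw odes")
    missing <- setdiff(species, names(odes_def))
    if (length(missing))
      stop_sg("steadygrad_parse_error", "no ODE right-hand side for species: %s",
              paste(missing, collapse = ", "))
    S <- NULL
    rates <- list()
    odes <- lapply(species, function(sp) {
      e <- parse_expr1(as.character(odes_def[[sp]]), sprintf("ODE for %s", sp))
      check_symbols(e, known, sprintf("d%s/dt", sp))
      e
    })
  }
  names(odes) <- species

  init_def <- definition$initials
  x0 <- lapply(species, function(sp) {
    v <- if (!is.null(init_def) && sp %in% names(init_def)) init_def[[sp]] else 0
    e <- parse_expr1(as.character(v), sprintf("initial condition for %s", sp))
    check_symbols(e, c(parameters, inputs), sprintf("initial condition of %s", sp))
    e
  })
  names(x0) <- species

  obs_def <- definition$observables
  observables <- lapply(obs_def, function(v) {
    e <- parse_expr1(as.character(v), "observable")
    check_symbols(e, known, "observable")
    e
  })

  structure(list(
    species = species, parameters = parameters, inputs = inputs,
    S = S, rates = rates, odes = odes, x0 = x0, observables = observables,
    format = "steadygrad-model-v1"
  ), class = "reaction_network")
}

# f = S . v as language objects, so the symbolic identity holds by construction.
assemble_rhs <- function(S, rates) {
  lapply(seq_len(nrow(S)), function(i) {
    expr <- NULL
    for (r in seq_along(rates)) {
      s <- S[i, r]
      if (s == 0) next
      term <- if (s == 1L) rates[[r]] else call("*", as.numeric(s), rates[[r]])
      expr <- if (is.null(expr)) term else call("+", expr, term)
    }
    if (is.null(expr)) 0 else expr
  })
}

# One reaction, either a "lhs -> rhs at rate" string or a list.
parse_reaction_entry <- function(entry, species) {
  if (is.character(entry)) {
    m <- regmatches(entry, regexec("^\\s*(.*?)\\s*->\\s*(.*?)\\s+at\\s+(.*)$", entry))[[1L]]
    if (length(m) != 4L)
      stop_sg("steadygrad_parse_error",
              "cannot parse reaction '%s' (expected 'reactants -> products at rate')", entry)
    entry <- list(reactants = parse_side(m[2L]), products = parse_side(m[3L]), rate = m[4L])
  }
  for (side in c("reactants", "products")) {
    nm <- names(entry[[side]])
    bad <- setdiff(nm, species)
    if (length(bad))
      stop_sg("steadygrad_parse_error", "undeclared species '%s' in reaction %s", bad[1L], side)
  }
  if (is.null(entry$rate))
    stop_sg("steadygrad_parse_error", "reaction without a rate expression")
  entry
}

# "2 A + B" -> list(A = 2, B = 1); "0", "" and unicode empty-set mean no species.
parse_side <- function(text) {
  text <- trimws(text)
  if (text == "" || text == "0" || text == "∅") return(list())
  out <- list()
  for (term in trimws(strsplit(text, "+", fixed = TRUE)[[1L]])) {
    m <- regmatches(term, regexec("^([0-9]+)?\\s*([A-Za-z._][A-Za-z0-9._]*)$", term))[[1L]]
    if (length(m) != 3L)
      stop_sg("steadygrad_parse_error", "cannot parse reaction term '%s'", term)
    coef <- if (m[2L] == "") 1L else as.integer(m[2L])
    out[[m[3L]]] <- coef + (out[[m[3L]]] %||% 0L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shorthand "A -> B at k1*A; B -> A at k2*B": species in order of first
# appearance, leftover rate symbols become parameters.
reaction_shorthand_to_list <- function(text) {
  rxn_strings <- trimws(strsplit(text, ";", fixed = TRUE)[[1L]])
  rxn_strings <- rxn_strings[nzchar(rxn_strings)]
  species <- character(0)
  syms <- character(0)
  for (rs in rxn_strings) {
    m <- regmatches(rs, regexec("^\\s*(.*?)\\s*->\\s*(.*?)\\s+at\\s+(.*)$", rs))[[1L]]
    if (length(m) != 4L)
      stop_sg("steadygrad_parse_error", "cannot parse reaction '%s'", rs)
    for (side in m[2:3]) species <- union(species, names(parse_side(side)))
    syms <- union(syms, expr_symbols(parse_expr1(m[4L], "rate")))
  }
  list(species = as.list(species),
       parameters = as.list(setdiff(syms, c(species, "pi"))),
       reactions = as.list(rxn_strings))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d parameters, %d inputs, %s\n",
              length(x$species), length(x$parameters), length(x$inputs),
              if (is.null(x$S)) "raw ODE form" else sprintf("%d reactions", ncol(x$S))))
  cat("  species:    ", paste(x$species, collapse = ", "), "\n")
  cat("  parameters: ", paste(x$parameters, collapse = ", "), "\n")
  if (length(x$inputs)) cat("  inputs:     ", paste(x$inputs, collapse = ", "), "\n")
  if (length(x$observables))
    cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  invisible(x)
}
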