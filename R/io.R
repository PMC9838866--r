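# Problem bundle IO: model YAML (steadygrad-model-v1) plus a documented
# PEtab subset — conditions.tsv, observables.tsv, measurements.tsv,
# parameters.tsv. Steady-state measurements use the conventional infinite
# time marker (`inf`); noise is a fixed number per measurement row;
# parameter scales are `lin` or `log10`.

# shortest decimal string that round-trips the double exactly
num_to_str <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(if (is.infinite(v) && v > 0) "inf" else
                              if (is.infinite(v)) "-inf" else "nan")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}

write_tsv <- function(df, path) {
  for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- num_to_str(df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path))
    stop_sg("steadygrad_load_error", "missing file '%s'", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# Serialize a reaction network back to the YAML dialect. Reaction-defined
# models are written as reactions reconstructed from the stoichiometry (pure
# mass-transfer networks round-trip exactly; catalytic species appearing
# only in rates are not representable and such models are written as raw
# ODEs), raw-ODE models as `odes`.
network_to_yaml_list <- function(network) {
  def <- list(format = "steadygrad-model-v1",
              species = as.list(network$species),
              parameters = as.list(network$parameters))
  if (length(network$inputs)) def$inputs <- as.list(network$inputs)
  if (!is.null(network$S)) {
    def$reactions <- lapply(seq_along(network$rates), function(r) {
      side <- function(sgn) {
        idx <- which(sgn * network$S[, r] > 0)
        if (!length(idx)) return("0")
        paste(vapply(idx, function(i) {
          cf <- abs(network$S[i, r])
          if (cf == 1) network$species[i] else paste(cf, network$species[i])
        }, character(1)), collapse = " + ")
      }
      sprintf("%s -> %s at %s", side(-1), side(1), deparse1(network$rates[[r]]))
    })
  } else {
    def$odes <- lapply(network$odes, deparse1)
  }
  def$initials <- lapply(network$x0, deparse1)
  if (length(network$observables))
    def$observables <- lapply(network$observables, deparse1)
  def
}

#' Write a problem bundle to a directory
#'
#' Writes `model.yaml` plus the PEtab-subset tables `conditions.tsv`,
#' `observables.tsv`, `measurements.tsv` and `parameters.tsv`. When the
#' problem's model is moiety-reduced, the original full model is written
#' (reduction is re-applied on load).
#'
#' @param problem An [sg_problem()] (or a [make_fixture()] result).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_problem <- function(problem, dir) {
  if (!is.null(problem$problem)) problem <- problem$problem
  stopifnot(inherits(problem, "sg_problem"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- problem$model
  network <- if (!is.null(model$reduction))
    model$reduction$full_model$network else model$network
  yaml::write_yaml(network_to_yaml_list(network), file.path(dir, "model.yaml"))

  conds <- problem$conditions
  crows <- list()
  pre_of <- character(0)
  for (cc in conds) {
    row <- data.frame(conditionId = cc$id)
    for (nm in network$inputs) row[[nm]] <- unname(cc$u[nm])
    crows[[length(crows) + 1L]] <- row
    if (isTRUE(cc$preeq)) {
      pid <- paste0(cc$id, "__pre")
      prow <- data.frame(conditionId = pid)
      for (nm in network$inputs) prow[[nm]] <- unname(cc$u_pre[nm])
      crows[[length(crows) + 1L]] <- prow
      pre_of[cc$id] <- pid
    }
  }
  write_tsv(do.call(rbind, crows), file.path(dir, "conditions.tsv"))

  obs_net <- if (!is.null(model$reduction))
    model$reduction$full_model$network$observables else network$observables
  write_tsv(data.frame(observableId = names(obs_net),
                       observableFormula = vapply(obs_net, deparse1, character(1))),
            file.path(dir, "observables.tsv"))

  meas <- problem$measurements
  out <- data.frame(simulationConditionId = meas$conditionId,
                    preequilibrationConditionId =
                      ifelse(meas$conditionId %in% names(pre_of),
                             pre_of[meas$conditionId], ""),
                    observableId = meas$observableId,
                    time = meas$time, measurement = meas$measurement,
                    noiseParameters = meas$sd)
  write_tsv(out, file.path(dir, "measurements.tsv"))

  p <- problem$parameters
  write_tsv(data.frame(parameterId = p$parameterId,
                       parameterScale = ifelse(p$parameterScale == "linear",
                                               "lin", p$parameterScale),
                       lowerBound = p$lowerBound, upperBound = p$upperBound,
                       nominalValue = p$nominalValue),
            file.path(dir, "parameters.tsv"))
  invisible(dir)
}

#' Load a problem bundle from a directory
#'
#' Reads `model.yaml` and the PEtab-subset tables, validates referential
#' integrity (every measurement's condition and observable must exist, every
#' parameter must appear in the model), applies conserved-moiety reduction
#' when the model's stoichiometry admits it, and marks conditions that need
#' pre-equilibration (a `preequilibrationConditionId` entry) or
#' post-equilibration (a steady-state time marker `inf`).
#'
#' An optional `config.yaml` in the bundle directory overrides numerical
#' settings and the default gradient method, e.g.
#' ```yaml
#' equilibration: {rtol: 1.0e-8, atol: 1.0e-16, newton: true}
#' integration:   {rtol: 1.0e-10, atol: 1.0e-12}
#' gradient_method: ssasa
#' ```
#'
#' @param dir Directory containing the bundle.
#' @param reduce `"auto"` (reduce when conserved moieties are found) or
#'   `"never"`.
#' @param settings See [gradient_settings()]; entries from `config.yaml`
#'   take precedence.
#' @return An [sg_problem()] (with a `gradient_method` field when the config
#'   sets one).
#' @export
load_problem <- function(dir, reduce = c("auto", "never"),
                         settings = gradient_settings()) {
  reduce <- match.arg(reduce)
  gradient_method <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    eqc <- cfg$equilibration
    if (!is.null(eqc$rtol)) settings$ss_rtol <- as.numeric(eqc$rtol)
    if (!is.null(eqc$atol)) settings$ss_atol <- as.numeric(eqc$atol)
    if (!is.null(eqc$newton)) settings$newton_polish <- isTRUE(eqc$newton)
    if (!is.null(cfg$integration$rtol))
      settings$rtol <- as.numeric(cfg$integration$rtol)
    if (!is.null(cfg$integration$atol))
      settings$atol <- as.numeric(cfg$integration$atol)
    gradient_method <- cfg$gradient_method
  }
  network <- parse_model(file.path(dir, "model.yaml"))

  obs <- read_tsv(file.path(dir, "observables.tsv"))
  network$observables <- stats::setNames(
    lapply(obs$observableFormula, parse_expr1, what = "observable"),
    obs$observableId)
  for (e in network$observables) {
    bad <- setdiff(expr_symbols(e),
                   c(network$species, network$parameters, network$inputs, "pi"))
    if (length(bad))
      stop_sg("steadygrad_load_error",
              "observables.tsv: undeclared symbol '%s'", bad[1L])
  }

  model <- compile_model(network)
  if (reduce == "auto" && !is.null(network$S)) {
    analysis <- find_conserved_quantities(network$S, network)
    if (analysis$n_c > 0L) {
      message(sprintf("removing %d conserved moiety(ies)", analysis$n_c))
      model <- reduce_model(model, analysis)
    }
  }

  ctab <- read_tsv(file.path(dir, "conditions.tsv"))
  miss <- setdiff(network$inputs, names(ctab))
  if (length(miss))
    stop_sg("steadygrad_load_error", "conditions.tsv lacks input column(s): %s",
            paste(miss, collapse = ", "))
  u_of <- function(id) {
    row <- ctab[ctab$conditionId == id, , drop = FALSE]
    if (nrow(row) != 1L)
      stop_sg("steadygrad_load_error",
              "condition '%s' not found (or duplicated) in conditions.tsv", id)
    stats::setNames(as.numeric(row[1L, network$inputs]), network$inputs)
  }

  mtab <- read_tsv(file.path(dir, "measurements.tsv"))
  if (!"preequilibrationConditionId" %in% names(mtab))
    mtab$preequilibrationConditionId <- ""
  mtab$preequilibrationConditionId[is.na(mtab$preequilibrationConditionId)] <- ""
  sim_ids <- unique(mtab$simulationConditionId)
  conditions <- lapply(sim_ids, function(id) {
    pre_ids <- unique(mtab$preequilibrationConditionId[
      mtab$simulationConditionId == id])
    pre_ids <- pre_ids[nzchar(pre_ids)]
    if (length(pre_ids) > 1L)
      stop_sg("steadygrad_load_error",
              "condition '%s' has conflicting pre-equilibration conditions", id)
    sg_condition(id, u = u_of(id),
                 u_pre = if (length(pre_ids)) u_of(pre_ids) else NULL)
  })
  meas <- data.frame(conditionId = mtab$simulationConditionId,
                     observableId = mtab$observableId,
                     time = as.numeric(mtab$time),
                     measurement = as.numeric(mtab$measurement),
                     sd = as.numeric(mtab$noiseParameters))

  ptab <- read_tsv(file.path(dir, "parameters.tsv"))
  parameters <- data.frame(parameterId = ptab$parameterId,
                           parameterScale = ptab$parameterScale,
                           lowerBound = as.numeric(ptab$lowerBound),
                           upperBound = as.numeric(ptab$upperBound),
                           nominalValue = as.numeric(ptab$nominalValue))

  problem <- sg_problem(model, meas, conditions = conditions,
                        parameters = parameters, settings = settings)
  if (!is.null(gradient_method)) problem$gradient_method <- gradient_method
  problem
}
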