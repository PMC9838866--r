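# Estimation problem container: model + conditions + measurements +
# parameter scales/bounds + numerical settings.

#' Define an experiment condition
#'
#' @param id Condition identifier.
#' @param u Named numeric vector of constant inputs (over the model's
#'   declared inputs; may be empty).
#' @param u_pre Optional named input vector of a pre-equilibration phase;
#'   its presence flags the condition as requiring pre-equilibration.
#' @return A `sg_condition` list with flags `preeq` (from `u_pre`) and
#'   `posteq` (set by [sg_problem()] when steady-state measurements
#'   reference the condition).
#' @export
sg_condition <- function(id, u = numeric(0), u_pre = NULL) {
  structure(list(id = id, u = u, u_pre = u_pre,
                 preeq = !is.null(u_pre), posteq = FALSE),
            class = "sg_condition")
}

#' Assemble a parameter-estimation problem
#'
#' @param model Compiled `model_functions` (typically moiety-reduced, see
#'   [reduce_model()]).
#' @param measurements Data frame with columns `conditionId`, `observableId`,
#'   `time` (`Inf` marks a steady-state measurement), `measurement`, `sd`
#'   (noise standard deviation, > 0).
#' @param conditions List of [sg_condition()] objects; defaults to one
#'   input-free condition named `"c1"`.
#' @param parameters Data frame with columns `parameterId`,
#'   `parameterScale` (`"lin"`/`"linear"` or `"log10"`), `lowerBound`,
#'   `upperBound` (linear scale), `nominalValue` (linear scale). Defaults to
#'   linear scale with infinite bounds and `NA` nominal values.
#' @param settings See [gradient_settings()].
#' @return An object of class `sg_problem`.
#' @export
sg_problem <- function(model, measurements, conditions = NULL,
                       parameters = NULL, settings = gradient_settings()) {
  stopifnot(inherits(model, "model_functions"))
  if (is.null(conditions)) conditions <- list(sg_condition("c1"))
  names(conditions) <- vapply(conditions, function(cc) cc$id, character(1))

  if (is.null(parameters)) {
    parameters <- data.frame(parameterId = model$parameters,
                             parameterScale = "linear",
                             lowerBound = -Inf, upperBound = Inf,
                             nominalValue = NA_real_)
  }
  parameters$parameterScale[parameters$parameterScale == "lin"] <- "linear"
  if (!setequal(parameters$parameterId, model$parameters))
    stop_sg("steadygrad_load_error",
            "parameters table does not match model parameters (missing: %s)",
            paste(setdiff(model$parameters, parameters$parameterId), collapse = ", "))
  parameters <- parameters[match(model$parameters, parameters$parameterId), ]
  lg <- parameters$parameterScale == "log10"
  if (any(lg & (parameters$lowerBound <= 0 & is.finite(parameters$lowerBound))))
    stop_sg("steadygrad_domain_error",
            "log10-scaled parameter '%s' needs a positive linear-scale lower bound",
            parameters$parameterId[lg & parameters$lowerBound <= 0][1L])

  measurements <- validate_measurements(measurements, model, conditions)
  for (i in seq_along(conditions)) {
    rows <- measurements$conditionId == conditions[[i]]$id
    conditions[[i]]$posteq <- any(rows & !is.finite(measurements$time))
  }
  used <- vapply(conditions, function(cc)
    any(measurements$conditionId == cc$id), logical(1))
  if (!any(used))
    stop_sg("steadygrad_load_error", "no condition is referenced by any measurement")

  structure(list(model = model, conditions = conditions,
                 measurements = measurements, parameters = parameters,
                 settings = settings),
            class = "sg_problem")
}

validate_measurements <- function(meas, model, conditions) {
  need <- c("conditionId", "observableId", "time", "measurement", "sd")
  miss <- setdiff(need, names(meas))
  if (length(miss))
    stop_sg("steadygrad_load_error", "measurement table lacks column(s): %s",
            paste(miss, collapse = ", "))
  bad_cond <- setdiff(unique(meas$conditionId), names(conditions))
  if (length(bad_cond))
    stop_sg("steadygrad_load_error",
            "measurement references unknown condition '%s'", bad_cond[1L])
  bad_obs <- setdiff(unique(meas$observableId), model$observables)
  if (length(bad_obs))
    stop_sg("steadygrad_load_error",
            "measurement references unknown observable '%s'", bad_obs[1L])
  if (any(!is.finite(meas$sd) | meas$sd <= 0))
    stop_sg("steadygrad_degenerate_noise",
            "noise standard deviation must be positive (row %d)",
            which(!is.finite(meas$sd) | meas$sd <= 0)[1L])
  if (any(is.na(meas$time)) || any(meas$time < 0))
    stop_sg("steadygrad_load_error", "measurement times must be >= 0 (Inf marks steady state)")
  meas <- meas[order(meas$conditionId, meas$time, meas$observableId), ]
  rownames(meas) <- NULL
  meas
}

# Nominal parameter vector on the estimation scale.
nominal_theta <- function(problem) {
  p <- problem$parameters
  if (anyNA(p$nominalValue))
    stop_sg("steadygrad_domain_error",
            "no parameter vector supplied and the parameters table has no nominal values")
  stats::setNames(to_estimation_scale(p$nominalValue, p$parameterScale), p$parameterId)
}

theta_to_linear <- function(problem, theta) {
  p <- problem$parameters
  if (!is.null(names(theta))) theta <- theta[p$parameterId]
  stats::setNames(apply_scale(as.numeric(theta), p$parameterScale), p$parameterId)
}

#' @export
print.sg_problem <- function(x, ...) {
  cat(sprintf("<sg_problem> %d state(s), %d parameter(s), %d condition(s), %d measurement row(s)\n",
              x$model$n_x, x$model$n_theta, length(x$conditions), nrow(x$measurements)))
  flags <- vapply(x$conditions, function(cc)
    paste0(cc$id, if (cc$preeq) " [pre]" else "", if (cc$posteq) " [post]" else ""),
    character(1))
  cat("  conditions:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' Negative log-likelihood of simulated observables against a table
#'
#' For independent Gaussian noise the negative log-likelihood is
#' \deqn{J = \frac{1}{2} \sum \left[\log(2\pi\sigma^2) +
#' \left(\frac{\bar y - y}{\sigma}\right)^2\right]} summed over time-course
#' rows and steady-state rows alike. The constant \eqn{\log(2\pi\sigma^2)}
#' terms are included so printed objective values are comparable across runs.
#'
#' @param y_sim Numeric vector of simulated observable values, aligned with
#'   the rows of `table`; an `NA` entry raises an assembly error naming the
#'   row.
#' @param table Measurement table (columns `measurement`, `sd`, optionally
#'   `conditionId` for the per-condition split).
#' @return An `objective_value` list: `nll` (nats) and `per_condition`.
#' @examples
#' tab <- data.frame(measurement = 1, sd = 1)
#' negative_log_likelihood(1, tab)$nll  # 0.5 * log(2*pi)
#' @export
negative_log_likelihood <- function(y_sim, table) {
  if (nrow(table) == 0L)
    return(structure(list(nll = 0, per_condition = numeric(0)),
                     class = "objective_value"))
  if (length(y_sim) != nrow(table))
    stop_sg("steadygrad_assembly_error",
            "simulated values (%d) do not match measurement rows (%d)",
            length(y_sim), nrow(table))
  if (anyNA(y_sim))
    stop_sg("steadygrad_assembly_error",
            "missing simulated value for measurement row %d", which(is.na(y_sim))[1L])
  ll <- 0.5 * (log(2 * pi * table$sd^2) + ((table$measurement - y_sim) / table$sd)^2)
  per <- if ("conditionId" %in% names(table))
    vapply(split(ll, table$conditionId), sum, numeric(1)) else numeric(0)
  structure(list(nll = sum(ll), per_condition = per), class = "objective_value")
}
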