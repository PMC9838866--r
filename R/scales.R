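#' Parameter scales: estimation scale vs linear (model) scale
#'
#' Parameters may be estimated on a `log10` scale to improve optimizer
#' convergence; model functions always see linear-scale values.
#' `apply_scale()` maps estimation-scale values to linear scale,
#' `to_estimation_scale()` is its inverse, and `chain_rule()` converts a
#' linear-scale objective gradient to the estimation scale
#' (log10 entries are multiplied by \eqn{\theta \ln 10}).
#'
#' @param theta_scaled Numeric vector on the estimation scale.
#' @param scales Character vector, each entry `"linear"` (alias `"lin"`) or
#'   `"log10"`, recycled to the parameter length.
#' @return `apply_scale()` / `to_estimation_scale()`: a numeric vector of the
#'   same length (names preserved); `chain_rule()`: the rescaled gradient.
#' @examples
#' apply_scale(c(0, 2), c("log10", "linear"))   # 1, 2
#' chain_rule(c(1, 1), c(2, 2), c("log10", "linear"))
#' @export
apply_scale <- function(theta_scaled, scales) {
  scales <- normalize_scales(scales, length(theta_scaled))
  out <- theta_scaled
  out[scales == "log10"] <- 10^theta_scaled[scales == "log10"]
  out
}

#' @rdname apply_scale
#' @param theta_linear Numeric vector on the linear scale.
#' @export
to_estimation_scale <- function(theta_linear, scales) {
  scales <- normalize_scales(scales, length(theta_linear))
  lg <- scales == "log10"
  if (any(theta_linear[lg] <= 0))
    stop_sg("steadygrad_domain_error",
            "log10-scaled parameter must be positive on the linear scale (got %s)",
            paste(theta_linear[lg][theta_linear[lg] <= 0], collapse = ", "))
  out <- theta_linear
  out[lg] <- log10(theta_linear[lg])
  out
}

#' @rdname apply_scale
#' @param grad_linear Gradient w.r.t. linear-scale parameters.
#' @param theta Parameter values on the linear scale.
#' @export
chain_rule <- function(grad_linear, theta, scales) {
  scales <- normalize_scales(scales, length(grad_linear))
  lg <- scales == "log10"
  if (any(theta[lg] <= 0))
    stop_sg("steadygrad_domain_error",
            "log10-scaled parameter must be positive on the linear scale")
  out <- grad_linear
  out[lg] <- grad_linear[lg] * theta[lg] * log(10)
  out
}

normalize_scales <- function(scales, n) {
  scales[scales == "lin"] <- "linear"
  bad <- setdiff(unique(scales), c("linear", "log10"))
  if (length(bad))
    stop_sg("steadygrad_domain_error", "unknown parameter scale '%s'", bad[1L])
  rep_len(scales, n)
}
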