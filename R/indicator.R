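#' Hill occupancy of the indicator
#'
#' @param ca Ca2+ concentration(s), nM.
#' @param indicator An [indicator_model()].
#' @return Occupancy \eqn{\theta = Ca^n / (Ca^n + K_d^n)} in [0, 1);
#'   exactly 0.5 at \code{ca == kd}.
#' @export
hill_occupancy <- function(ca, indicator) {
  stopifnot(inherits(indicator, "indicator_model"))
  if (any(!is.finite(ca)) || any(ca < 0))
    stop("ca must be finite and nonnegative")
  r <- (ca / indicator$kd)^indicator$hill_n
  r / (1 + r)
}

#' Saturation ceiling of dF/F
#'
#' @param indicator An [indicator_model()].
#' @param ca_rest Resting Ca2+ (nM) defining the dF/F reference.
#' @return The analytic ceiling
#'   \eqn{r_{max}(1-\theta_{rest})/(1+r_{max}\theta_{rest})}.
#' @export
dff_ceiling <- function(indicator, ca_rest) {
  th0 <- hill_occupancy(ca_rest, indicator)
  indicator$rmax * (1 - th0) / (1 + indicator$rmax * th0)
}

#' Indicator fluorescence response to a calcium trace
#'
#' Converts a Ca2+ time series into dF/F. Quasi-static occupancy is computed
#' from the Hill equation and, when \code{binding_tau > 0}, relaxed
#' first-order with that time constant (exact exponential update per step,
#' treating the target as constant within a step). dF/F is referenced to
#' occupancy at \code{ca_rest}:
#' \eqn{\Delta F/F = r_{max}(\theta - \theta_{rest})/(1 + r_{max}\theta_{rest})}.
#'
#' @param ca_trace Ca2+ series, nM.
#' @param indicator An [indicator_model()].
#' @param ca_rest Resting Ca2+ (nM); reference for dF/F.
#' @param dt Grid spacing in seconds (needed when \code{binding_tau > 0}).
#' @param theta0 Initial occupancy (default: rest occupancy).
#' @return Numeric dF/F series, same length as \code{ca_trace}.
#' @export
fluorescence_from_calcium <- function(ca_trace, indicator, ca_rest = 50,
                                      dt = NULL, theta0 = NULL) {
  theta_qs <- hill_occupancy(ca_trace, indicator)
  th0 <- hill_occupancy(ca_rest, indicator)
  if (indicator$binding_tau > 0) {
    if (is.null(dt)) stop("dt is required when binding_tau > 0")
    a <- exp(-dt / indicator$binding_tau)
    theta <- numeric(length(theta_qs))
    cur <- if (is.null(theta0)) th0 else theta0
    for (i in seq_along(theta_qs)) {
      cur <- theta_qs[i] + (cur - theta_qs[i]) * a
      theta[i] <- cur
    }
  } else {
    theta <- theta_qs
  }
  indicator$rmax * (theta - th0) / (1 + indicator$rmax * th0)
}
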