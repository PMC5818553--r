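# One clearance step of width dt starting at absolute time t0, state u =
# Ca - ca_rest. Exact exponential when the pump is off; RK4 otherwise
# (smooth, non-stiff between jumps).
.ca_step <- function(u, t0, dt, model) {
  s <- model$pump_scale_schedule
  if (model$pump_vmax == 0)
    return(u * exp(-model$k_leak * dt))
  f <- function(tt, uu) {
    uu <- max(uu, 0)
    -model$k_leak * uu - s(tt) * model$pump_vmax * uu / (uu + model$pump_km)
  }
  k1 <- f(t0, u)
  k2 <- f(t0 + dt / 2, u + dt / 2 * k1)
  k3 <- f(t0 + dt / 2, u + dt / 2 * k2)
  k4 <- f(t0 + dt, u + dt * k3)
  max(u + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
}

#' Simulate cytosolic calcium from an AP event list
#'
#' Integrates the leaky-integrator clearance model of [calcium_model()] on
#' the supplied time grid. Each AP adds an instantaneous jump of
#' \code{delta_ca_per_ap}; between jumps the linear leak is stepped with the
#' exact exponential and the saturable pump with classical RK4. Events
#' falling inside a grid interval split the interval so jump timing is
#' exact.
#'
#' @param ap_times Sorted AP event times, s.
#' @param model A [calcium_model()].
#' @param time_grid Strictly increasing time grid, s. Resolution should be
#'   at most the intra-burst spacing so no two events share a step.
#'
#' @return Numeric vector of Ca2+ (nM) at \code{time_grid}.
#' @examples
#' m <- calcium_model(k_leak = 1, delta_ca_per_ap = 100)
#' tg <- seq(0, 5, by = 0.004)
#' ca <- simulate_calcium(1, m, tg)   # single AP at t = 1 s
#' @export
simulate_calcium <- function(ap_times, model, time_grid) {
  stopifnot(inherits(model, "calcium_model"))
  ap_times <- sort(as.numeric(ap_times))
  n <- length(time_grid)
  stopifnot(n >= 2, all(diff(time_grid) > 0))
  ca <- numeric(n)
  u <- 0  # Ca - ca_rest
  # events at/before the first grid point jump immediately
  pre <- sum(ap_times <= time_grid[1])
  u <- u + pre * model$delta_ca_per_ap
  ev <- ap_times[ap_times > time_grid[1]]
  ca[1] <- model$ca_rest + u
  j <- 1L
  for (i in 2:n) {
    t0 <- time_grid[i - 1]; t1 <- time_grid[i]
    while (j <= length(ev) && ev[j] <= t1) {
      u <- .ca_step(u, t0, ev[j] - t0, model)
      u <- u + model$delta_ca_per_ap
      t0 <- ev[j]
      j <- j + 1L
    }
    u <- .ca_step(u, t0, t1 - t0, model)
    if (!is.finite(u))
      stop(sprintf("calcium solver produced a non-finite state at t = %g s", t1))
    ca[i] <- model$ca_rest + u
  }
  ca
}

#' Average consecutive samples into frames
#'
#' Downsamples a fine-grid trace by frame-interval averaging, emulating
#' camera exposure integration. The fine grid must tile frames exactly.
#'
#' @param x Numeric vector on the fine grid.
#' @param factor Integer number of fine samples per frame.
#' @return Numeric vector of length \code{length(x) / factor}.
#' @export
frame_average <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1, length(x) %% factor == 0)
  if (factor == 1L) return(x)
  colMeans(matrix(x, nrow = factor))
}
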