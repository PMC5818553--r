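#' Simulate a focal (loose-patch) release-event record
#'
#' Emits one stereotyped biexponential deflection per action potential plus
#' Gaussian noise, emulating extracellular focal recordings of evoked
#' release (efEJP-like events). The kernel is
#' \eqn{e^{-t/\tau_d} - e^{-t/\tau_r}} with \eqn{\tau_r = \tau_d / 5},
#' normalized so the peak equals \code{quantal_amplitude}.
#'
#' @param ap_times AP event times, s.
#' @param record_duration Record length, s.
#' @param quantal_amplitude Peak deflection per event, arbitrary units.
#' @param kernel_tau Decay time constant \eqn{\tau_d}, s.
#' @param noise_sigma Noise SD, same units.
#' @param sample_rate Samples per second; must be at least
#'   \code{10 / kernel_tau}.
#' @param seed Integer seed for the noise stream.
#' @return Data frame with columns \code{time_s}, \code{amplitude}.
#' @export
generate_focal_record <- function(ap_times, record_duration,
                                  quantal_amplitude = 1,
                                  kernel_tau = 0.003,
                                  noise_sigma = 0,
                                  sample_rate = 10000, seed = 1L) {
  stopifnot(kernel_tau > 0, noise_sigma >= 0, record_duration > 0)
  if (sample_rate < 10 / kernel_tau)
    stop("sample_rate must be at least 10 / kernel_tau")
  n <- floor(record_duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  tau_r <- kernel_tau / 5
  # kernel support: 8 decay constants
  kt <- seq(0, 8 * kernel_tau, by = 1 / sample_rate)
  kern <- exp(-kt / kernel_tau) - exp(-kt / tau_r)
  kern <- kern / max(kern) * quantal_amplitude
  amp <- numeric(n)
  for (t0 in ap_times) {
    i0 <- floor(t0 * sample_rate) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    if (idx[1] > n) next
    amp[idx] <- amp[idx] + kern[seq_along(idx)]
  }
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    amp <- amp + stats::rnorm(n, 0, noise_sigma)
    .Random.seed_restore(old)
  }
  data.frame(time_s = tt, amplitude = amp)
}
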