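#' Axonal excitability profile
#'
#' Parameterizes how a motor axon translates stimulus pulses into action
#' potentials at the terminal. Hyperexcitable terminals fire bursts of
#' \code{aps_per_stimulus} APs at \code{burst_rate} per pulse (supernumerary
#' firing); hypoexcitable terminals fail to conduct pulses that arrive
#' within \code{failure_recovery_time} of the previous AP. Post-train
#' discharge ("rebound") fires at \code{rebound_rate} for
#' \code{rebound_duration}, starting \code{rebound_delay} after train end.
#'
#' Two optional conduction-block fields extend the recovery rule to the
#' multi-pulse failure patterns seen in type II terminals:
#' \code{block_after_pulse} silences all pulses after the given delivered
#' pulse count (activity-dependent block; "aborted" traces), and
#' \code{block_cycle = c(on, off)} alternates delivered and failed pulse
#' blocks ("intermittent" traces).
#'
#' @param aps_per_stimulus APs fired per delivered pulse (>= 0).
#' @param burst_rate Intra-burst firing rate, Hz; must exceed 0 when
#'   \code{aps_per_stimulus > 1}.
#' @param refractory_period Minimum AP spacing, s.
#' @param failure_recovery_time A pulse fails when the previous AP lies
#'   within this window of the pulse, s.
#' @param rebound_rate,rebound_duration,rebound_delay Post-train firing rate
#'   (Hz), duration (s) and delay after train end (s).
#' @param block_after_pulse Optional: permanent conduction block after this
#'   many delivered pulses (NA = none).
#' @param block_cycle Optional length-2 integer vector \code{c(on, off)}:
#'   deliver \code{on} pulses, fail \code{off} pulses, repeat (NULL = none).
#'
#' @return An object of class \code{excitability_profile}.
#' @export
excitability_profile <- function(aps_per_stimulus = 1, burst_rate = 100,
                                 refractory_period = 0.002,
                                 failure_recovery_time = 0,
                                 rebound_rate = 0, rebound_duration = 0,
                                 rebound_delay = 0,
                                 block_after_pulse = NA_integer_,
                                 block_cycle = NULL) {
  stopifnot(aps_per_stimulus >= 0, refractory_period >= 0,
            failure_recovery_time >= 0, rebound_rate >= 0,
            rebound_duration >= 0, rebound_delay >= 0)
  if (aps_per_stimulus > 1) {
    stopifnot(burst_rate > 0)
    if (1 / burst_rate < refractory_period)
      stop("burst spacing 1/burst_rate is shorter than refractory_period")
  }
  if (!is.null(block_cycle))
    stopifnot(length(block_cycle) == 2L, all(block_cycle >= 1))
  structure(list(aps_per_stimulus = aps_per_stimulus,
                 burst_rate = burst_rate,
                 refractory_period = refractory_period,
                 failure_recovery_time = failure_recovery_time,
                 rebound_rate = rebound_rate,
                 rebound_duration = rebound_duration,
                 rebound_delay = rebound_delay,
                 block_after_pulse = block_after_pulse,
                 block_cycle = block_cycle),
            class = "excitability_profile")
}

#' Single-compartment calcium clearance model
#'
#' Cytosolic free Ca2+ as a leaky integrator of AP-driven influx:
#' \deqn{dCa/dt = -k_{leak}(Ca - Ca_{rest})
#'   - s(t)\,V_{max}\frac{Ca - Ca_{rest}}{(Ca - Ca_{rest}) + K_m}
#'   + \Delta_{AP}\sum_i \delta(t - t_i)}
#' The linear leak lumps buffering and passive loss; the saturable
#' Michaelis-Menten term models active extrusion (PMCA) and
#' mitochondria-powered uptake. \code{pump_scale_schedule(t)} multiplies the
#' pump term (1 = intact; constant < 1 = PMCA suppression at high pH; a
#' rundown to 0 = DNP/azide metabolic poisoning).
#'
#' @param ca_rest Resting Ca2+, nM.
#' @param delta_ca_per_ap Ca2+ increment per AP, nM.
#' @param k_leak Linear clearance rate, 1/s.
#' @param pump_vmax Pump maximal rate, nM/s.
#' @param pump_km Pump half-saturation (above rest), nM.
#' @param pump_scale_schedule Function of time (s) returning a multiplier in
#'   [0, 1]; default constant 1.
#'
#' @return An object of class \code{calcium_model}.
#' @export
calcium_model <- function(ca_rest = 50, delta_ca_per_ap = 20,
                          k_leak = 1.386, pump_vmax = 0, pump_km = 150,
                          pump_scale_schedule = NULL) {
  stopifnot(ca_rest >= 0, delta_ca_per_ap >= 0, k_leak >= 0,
            pump_vmax >= 0, pump_km > 0)
  if (is.null(pump_scale_schedule)) pump_scale_schedule <- function(t) 1
  stopifnot(is.function(pump_scale_schedule))
  structure(list(ca_rest = ca_rest, delta_ca_per_ap = delta_ca_per_ap,
                 k_leak = k_leak, pump_vmax = pump_vmax, pump_km = pump_km,
                 pump_scale_schedule = pump_scale_schedule),
            class = "calcium_model")
}

#' Hill-type indicator binding model
#'
#' GCaMP fluorescence from Ca2+ through cooperative binding: occupancy
#' \eqn{\theta = Ca^n / (Ca^n + K_d^n)} relaxes first-order with time
#' constant \code{binding_tau} toward its quasi-static value, and
#' \eqn{\Delta F/F = r_{max}(\theta - \theta_{rest}) / (1 + r_{max}\theta_{rest})}
#' where \eqn{\theta_{rest}} is the occupancy at resting Ca2+, so the
#' simulator emits dF/F in the same convention the extractor measures.
#'
#' @param kd Dissociation constant, nM (> 0).
#' @param hill_n Hill coefficient (>= 1).
#' @param rmax Maximal fractional fluorescence enhancement at saturation.
#' @param binding_tau Binding relaxation time constant, s (0 = quasi-static).
#' @param f0 Baseline fluorescence per bouton, arbitrary units (used by the
#'   movie renderer).
#'
#' @return An object of class \code{indicator_model}.
#' @seealso [indicator_preset()] for GCaMP1.3 / GCaMP6m / myrGCaMP5.
#' @export
indicator_model <- function(kd = 234, hill_n = 3.3, rmax = 10,
                            binding_tau = 0.08, f0 = 100) {
  if (!is.numeric(kd) || kd <= 0) stop("kd must be > 0")
  stopifnot(hill_n >= 1, rmax > 0, binding_tau >= 0, f0 > 0)
  structure(list(kd = kd, hill_n = hill_n, rmax = rmax,
                 binding_tau = binding_tau, f0 = f0),
            class = "indicator_model")
}

#' GCaMP variant presets
#'
#' Published affinities and cooperativities: GCaMP1.3 (Kd 234 nM, Hill 3.3),
#' GCaMP6m (Kd 167 nM, Hill 2.96), myrGCaMP5 (Kd 447 nM). A "linear" preset
#' (Hill 1, very low affinity) puts the indicator in its linear regime where
#' dF/F kinetics track Ca2+ kinetics; used for clearance-rate recovery.
#'
#' @param name One of "GCaMP1.3", "GCaMP6m", "myrGCaMP5", "linear".
#' @param ... Overrides passed to [indicator_model()].
#' @return An \code{indicator_model}.
#' @export
indicator_preset <- function(name = c("GCaMP1.3", "GCaMP6m", "myrGCaMP5",
                                      "linear"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "GCaMP1.3"  = list(kd = 234, hill_n = 3.3),
    "GCaMP6m"   = list(kd = 167, hill_n = 2.96),
    "myrGCaMP5" = list(kd = 447, hill_n = 3.3),
    "linear"    = list(kd = 1e5, hill_n = 1, rmax = 2000, binding_tau = 0))
  do.call(indicator_model, utils::modifyList(base, list(...)))
}

#' Imaging model for synthetic movie rendering
#'
#' @param frame_rate Frames per second.
#' @param frame_shape Integer c(rows, cols) in pixels.
#' @param bouton_specs Data frame with columns \code{x, y, radius, f0, type}
#'   (center in 0-based pixel coordinates, radius px, peak brightness,
#'   terminal type "Ib"/"Is"/"II").
#' @param background_level Additive background intensity.
#' @param noise_sigma Gaussian read-noise SD per pixel (0 = deterministic).
#' @param rng_seed Integer seed for the noise stream.
#'
#' @return An object of class \code{imaging_model}.
#' @export
imaging_model <- function(frame_rate = 25, frame_shape = c(256L, 256L),
                          bouton_specs = NULL, background_level = 10,
                          noise_sigma = 0, rng_seed = 1L) {
  stopifnot(frame_rate > 0, length(frame_shape) == 2L, all(frame_shape >= 1),
            background_level >= 0, noise_sigma >= 0)
  if (!is.null(bouton_specs)) {
    stopifnot(is.data.frame(bouton_specs),
              all(c("x", "y", "radius", "f0") %in% names(bouton_specs)))
    if (is.null(bouton_specs$type)) bouton_specs$type <- "Ib"
    inside <- bouton_specs$x - bouton_specs$radius >= 0 &
      bouton_specs$x + bouton_specs$radius <= frame_shape[2] - 1 &
      bouton_specs$y - bouton_specs$radius >= 0 &
      bouton_specs$y + bouton_specs$radius <= frame_shape[1] - 1
    if (!all(inside)) stop("bouton footprints must lie inside the frame")
  }
  structure(list(frame_rate = frame_rate,
                 frame_shape = as.integer(frame_shape),
                 bouton_specs = bouton_specs,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "imaging_model")
}
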