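#' Simulate one NMJ terminal: spikes, calcium, fluorescence, traces
#'
#' Full forward chain at trace level: stimulus train -> axonal spike
#' delivery -> latent Ca2+ on a fine grid (10x the frame rate by default)
#' -> indicator dF/F -> frame-interval averaging (camera exposure) ->
#' per-bouton background-subtracted fluorescence with additive Gaussian
#' noise. All boutons of the terminal share the spike train and latent
#' Ca2+ (terminals behave uniformly); noise is independent per bouton.
#'
#' @param preset An \code{nmj_preset} from [scenario_preset()], or one
#'   assembled by hand with the same fields.
#' @param protocol A [stimulus_protocol()].
#' @param n_boutons Boutons sampled from the terminal.
#' @param seed Integer seed (spike generation and noise).
#' @param nmj_id NMJ identifier carried into the traces.
#' @param oversample Fine-grid samples per frame (default 10).
#' @param excitability Optional override of the preset's profile.
#' @return List of class \code{nmj_simulation}: \code{traces} (list of
#'   \code{bouton_trace}), \code{truth} (list: \code{ap_times},
#'   \code{delivery}, \code{ca} and \code{dff} on the frame grid,
#'   \code{label}, \code{spikes}), \code{protocol}, \code{preset}.
#' @export
simulate_nmj <- function(preset, protocol, n_boutons = 5L, seed = 1L,
                         nmj_id = 1L, oversample = 10L,
                         excitability = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  ex <- if (is.null(excitability)) preset$excitability else excitability
  spikes <- generate_spike_trains(protocol, ex, seed = seed)

  fr <- preset$frame_rate
  dt_fine <- 1 / (fr * oversample)
  if (ex$aps_per_stimulus > 1 && dt_fine > 1 / ex$burst_rate)
    stop("fine grid coarser than the burst spacing; increase oversample")
  n_frames <- round(protocol$record_duration * fr)
  grid <- (seq_len(n_frames * oversample) - 0.5) * dt_fine

  ca_fine <- simulate_calcium(spikes$ap_times, preset$calcium, grid)
  dff_fine <- fluorescence_from_calcium(ca_fine, preset$indicator,
                                        ca_rest = preset$calcium$ca_rest,
                                        dt = dt_fine)
  dff_frames <- frame_average(dff_fine, oversample)
  ca_frames <- frame_average(ca_fine, oversample)

  f0 <- preset$indicator$f0
  sigma <- preset$noise_sigma_dff * f0
  old <- .Random.seed_save()
  set.seed(seed)
  traces <- lapply(seq_len(n_boutons), function(b) {
    noise <- if (sigma > 0) stats::rnorm(n_frames, 0, sigma) else 0
    bouton_trace(f0 * (1 + dff_frames) + noise, frame_rate = fr,
                 bouton_id = b, nmj_id = nmj_id, type = preset$type)
  })
  .Random.seed_restore(old)

  structure(list(traces = traces,
                 truth = list(ap_times = spikes$ap_times,
                              delivery = spikes$delivery,
                              ca = ca_frames, dff = dff_frames,
                              label = true_waveform_label(spikes),
                              spikes = spikes),
                 protocol = protocol, preset = preset, seed = seed),
            class = "nmj_simulation")
}

#' Quantify one trace end to end
#'
#' Baseline, dF/F, kinetics and waveform label for a single
#' \code{bouton_trace}.
#'
#' @param trace A \code{bouton_trace} (with \code{f_t} filled).
#' @param protocol A [stimulus_protocol()].
#' @param rules [waveform_rules()] for classification.
#' @return A \code{kinetics_result} with an added \code{waveform} element.
#' @export
analyze_trace <- function(trace, protocol, rules = waveform_rules()) {
  trace <- compute_baseline(trace, protocol)
  trace <- compute_dff(trace)
  kin <- bouton_kinetics(trace, protocol)
  kin$waveform <- classify_waveform(kin, protocol, rules)
  kin
}

#' Frequency sweep over simulated NMJs
#'
#' Runs the full simulate -> extract -> kinetics chain for one terminal
#' type across stimulation frequencies and several NMJs, and assembles the
#' frequency-response summary used for threshold/saturation estimates.
#'
#' @param scenario Preset name (see [list_presets()]).
#' @param type Terminal type.
#' @param frequencies Tested train frequencies, Hz.
#' @param n_nmjs Simulated NMJs per frequency.
#' @param n_boutons Boutons per NMJ.
#' @param seed Integer base seed; NMJ s at frequency f uses a distinct
#'   derived seed.
#' @param incubation_min Passed to [scenario_preset()].
#' @param record_duration Record length per trial, s.
#' @return List: \code{table} ([kinetics_table()] rows for every bouton),
#'   \code{response} ([frequency_response()]).
#' @export
run_frequency_sweep <- function(scenario = "wt", type = "Ib",
                                frequencies = c(2, 10, 20, 40),
                                n_nmjs = 3L, n_boutons = 8L, seed = 1L,
                                incubation_min = 0,
                                record_duration = 8) {
  preset <- scenario_preset(scenario, type, incubation_min)
  rows <- list()
  for (fi in seq_along(frequencies)) {
    protocol <- stimulus_protocol(frequencies[fi],
                                  record_duration = record_duration)
    for (j in seq_len(n_nmjs)) {
      sim <- simulate_nmj(preset, protocol, n_boutons = n_boutons,
                          seed = seed + 1000L * fi + j, nmj_id = j)
      kin <- lapply(sim$traces, analyze_trace, protocol = protocol)
      rows[[length(rows) + 1L]] <- kinetics_table(kin)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab, response = frequency_response(tab))
}

#' Waveform scenario bank
#'
#' Ground-truth labelled simulation settings spanning the full waveform
#' taxonomy, built on the type II terminal at 20 Hz (where irregular
#' waveforms concentrate) plus a type Ib normal control: regular delivery
#' (normal), permanent conduction block after 10 delivered pulses
#' (aborted), alternating 10-pulse delivery blocks (intermittent),
#' post-train rebound discharge (rebound), and total conduction failure
#' (no_response).
#'
#' @return Named list of scenarios; each holds \code{preset},
#'   \code{protocol}, \code{excitability} and the expected \code{label}.
#' @export
waveform_scenarios <- function() {
  protocol <- stimulus_protocol(20, record_duration = 8)
  ii <- scenario_preset("wt", "II")
  burst <- function(...) excitability_profile(aps_per_stimulus = 3,
                                              burst_rate = 100, ...)
  list(
    normal = list(preset = scenario_preset("wt", "Ib"),
                  protocol = stimulus_protocol(40, record_duration = 8),
                  excitability = excitability_profile(),
                  label = "normal"),
    aborted = list(preset = ii, protocol = protocol,
                   excitability = burst(block_after_pulse = 10L),
                   label = "aborted"),
    intermittent = list(preset = ii,
                        protocol = stimulus_protocol(10, train_duration = 4,
                                                     record_duration = 10),
                        excitability = burst(block_cycle = c(10L, 10L)),
                        label = "intermittent"),
    rebound = list(preset = ii, protocol = protocol,
                   excitability = excitability_profile(
                     rebound_rate = 60, rebound_duration = 0.4,
                     rebound_delay = 1.2),
                   label = "rebound"),
    no_response = list(preset = ii, protocol = protocol,
                       excitability = excitability_profile(
                         aps_per_stimulus = 0),
                       label = "no_response"))
}

#' Run the waveform scenario bank through the classifier
#'
#' Simulates every scenario of [waveform_scenarios()], classifies each
#' bouton trace and compares with ground truth.
#'
#' @param n_runs Seeded repetitions per scenario.
#' @param seed Base seed.
#' @param noise_sigma_dff Trace noise SD in dF/F units; the default 0 is
#'   the noiseless bank. For an SNR-10 bank pass one tenth of each
#'   scenario's peak (see vignette); a single value applies to all.
#' @param rules [waveform_rules()].
#' @return Data frame: scenario, run, truth, predicted, correct.
#' @export
run_waveform_bank <- function(n_runs = 1L, seed = 1L, noise_sigma_dff = 0,
                              rules = waveform_rules()) {
  bank <- waveform_scenarios()
  out <- list()
  for (nm in names(bank)) {
    sc <- bank[[nm]]
    preset <- sc$preset
    if (length(noise_sigma_dff) == 1L)
      preset$noise_sigma_dff <- noise_sigma_dff
    else preset$noise_sigma_dff <- noise_sigma_dff[[nm]]
    for (r in seq_len(n_runs)) {
      sim <- simulate_nmj(preset, sc$protocol, n_boutons = 1L,
                          seed = seed + 7919L * r,
                          excitability = sc$excitability)
      kin <- analyze_trace(sim$traces[[1]], sc$protocol, rules)
      out[[length(out) + 1L]] <- data.frame(
        scenario = nm, run = r, truth = sc$label,
        predicted = kin$waveform$label,
        correct = kin$waveform$label == sc$label)
    }
  }
  do.call(rbind, out)
}

#' Movie-level round trip for one simulated NMJ
#'
#' Renders the simulated dF/F into a synthetic movie, builds the matching
#' ROI set and re-extracts traces — the end-to-end check that the
#' extraction pipeline recovers the simulator's ground truth.
#'
#' @param sim An \code{nmj_simulation}.
#' @param imaging An [imaging_model()]; its \code{bouton_specs} row count
#'   must equal the number of simulated boutons.
#' @return List: \code{movie}, \code{rois}, \code{traces} (extracted),
#'   \code{truth_dff} (the rendered ground truth per frame).
#' @export
render_and_extract <- function(sim, imaging) {
  n_b <- length(sim$traces)
  stopifnot(nrow(imaging$bouton_specs) == n_b)
  dff <- matrix(rep(sim$truth$dff, n_b), ncol = n_b)
  movie <- render_movie(dff, imaging)
  rois <- rois_from_imaging(imaging)
  traces <- extract_traces(movie, rois)
  list(movie = movie, rois = rois, traces = traces,
       truth_dff = sim$truth$dff)
}
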