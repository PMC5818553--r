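#' List available scenario presets
#'
#' @return Character vector of preset names shipped with the package.
#' @export
list_presets <- function() {
  sub("\\.json$", "",
      list.files(system.file("extdata", "presets", package = "presynCa"),
                 pattern = "\\.json$"))
}

#' Load a scenario preset for one terminal type
#'
#' Presets are JSON files pairing the wild-type per-terminal parameters
#' (clearance Ib > Is > II, per-AP influx II > Is > Ib) with
#' genotype/pharmacology overrides: \code{sh_4ap}, \code{eag_sh} (burst
#' firing, giant single-pulse signals), \code{tea_shab} (type II bursts and
#' post-train rebound), \code{para_ts1} (conduction failure),
#' \code{para_bss1} (intermittent delivery blocks), \code{high_ph} (PMCA
#' suppression, pump scaled to 0.6), \code{dnp} (linear pump rundown with
#' incubation time). Parameter files mark which values are illustrative
#' placeholders.
#'
#' @param scenario Preset name (see [list_presets()]).
#' @param type Terminal type: "Ib", "Is" or "II".
#' @param incubation_min Simulated incubation time in minutes (used by
#'   rundown scenarios such as \code{dnp}; the pump multiplier is held
#'   constant within one short record).
#' @return List of class \code{nmj_preset} with elements \code{calcium}
#'   ([calcium_model()]), \code{excitability} ([excitability_profile()]),
#'   \code{indicator} ([indicator_model()]), \code{noise_sigma_dff},
#'   \code{frame_rate}, \code{type}, \code{scenario}.
#' @export
scenario_preset <- function(scenario = "wt", type = c("Ib", "Is", "II"),
                            incubation_min = 0) {
  type <- match.arg(type)
  dir <- system.file("extdata", "presets", package = "presynCa")
  wt <- jsonlite::read_json(file.path(dir, "wt.json"), simplifyVector = TRUE)
  pars <- wt$types[[type]]
  meta <- wt[c("indicator", "noise_sigma_dff", "frame_rate")]
  pump_scale <- 1.0
  if (scenario != "wt") {
    path <- file.path(dir, paste0(scenario, ".json"))
    if (!file.exists(path))
      stop(sprintf("unknown preset '%s'; see list_presets()", scenario))
    ov <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(ov$types[[type]]))
      pars <- utils::modifyList(pars, as.list(ov$types[[type]]))
    for (k in names(meta))
      if (!is.null(ov[[k]])) meta[[k]] <- ov[[k]]
    if (!is.null(ov$pump_scale)) {
      if (identical(ov$pump_scale, "rundown")) {
        rd <- if (is.null(ov$rundown_minutes)) 60 else ov$rundown_minutes
        pump_scale <- max(0, 1 - incubation_min / rd)
      } else pump_scale <- as.numeric(ov$pump_scale)
    }
  }
  cal <- calcium_model(
    ca_rest = pars$ca_rest, delta_ca_per_ap = pars$delta_ca_per_ap,
    k_leak = pars$k_leak, pump_vmax = pars$pump_vmax,
    pump_km = pars$pump_km,
    pump_scale_schedule = local({
      s <- pump_scale
      function(t) s
    }))
  ex <- excitability_profile(
    aps_per_stimulus = pars$aps_per_stimulus,
    burst_rate = pars$burst_rate,
    refractory_period = pars$refractory_period,
    failure_recovery_time = pars$failure_recovery_time,
    rebound_rate = pars$rebound_rate,
    rebound_duration = pars$rebound_duration,
    rebound_delay = pars$rebound_delay)
  structure(list(calcium = cal, excitability = ex,
                 indicator = indicator_preset(meta$indicator),
                 noise_sigma_dff = meta$noise_sigma_dff,
                 frame_rate = meta$frame_rate,
                 type = type, scenario = scenario,
                 pump_scale = pump_scale),
            class = "nmj_preset")
}

#' @export
print.nmj_preset <- function(x, ...) {
  cat(sprintf("Preset %s / type %s: influx %g nM/AP, k_leak %g /s, pump %g nM/s (scale %.2g), %d AP(s)/stimulus\n",
              x$scenario, x$type, x$calcium$delta_ca_per_ap,
              x$calcium$k_leak, x$calcium$pump_vmax, x$pump_scale,
              x$excitability$aps_per_stimulus))
  invisible(x)
}
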