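#' 5-point running average
#'
#' Centered 5-point moving mean; at the edges the window is truncated to the
#' available indices (\code{max(1, i-2)..min(n, i+2)}), so the first and
#' last points average 3 values. Length is preserved.
#'
#' @param x Numeric series with at least 5 points.
#' @return Smoothed series, same length.
#' @export
smooth_dff <- function(x) {
  n <- length(x)
  if (n < 5) stop("need at least 5 frames to smooth")
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - 2L, 1L)
  hi <- pmin(seq_len(n) + 2L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Peak dF/F within the post-onset window
#'
#' Maximum of the smoothed trace over the window from stimulation onset to
#' \code{onset + window} (2 s, per the measurement convention); ties take
#' the earliest frame.
#'
#' @param dff_smoothed Smoothed dF/F series.
#' @param time Frame times, s.
#' @param protocol A [stimulus_protocol()].
#' @param window Window length after onset, s (default 2).
#' @return List with \code{max_dff} and \code{t_max} (argmax time, s).
#' @export
max_dff <- function(dff_smoothed, time, protocol, window = 2) {
  dt <- diff(time[1:2])
  if (protocol$onset_time + window > utils::tail(time, 1) + dt)
    stop("record does not cover the measurement window")
  idx <- which(time >= protocol$onset_time &
                 time <= protocol$onset_time + window)
  if (length(idx) == 0) stop("no frames in the measurement window")
  i <- idx[which.max(dff_smoothed[idx])]
  list(max_dff = dff_smoothed[i], t_max = time[i])
}

# first linearly interpolated crossing of `level` by y(time) over idx,
# direction "up" (from below) or "down" (from above); NA if none
.first_crossing <- function(time, y, idx, level, direction = "up") {
  for (k in seq_along(idx)[-1]) {
    i0 <- idx[k - 1]; i1 <- idx[k]
    y0 <- y[i0]; y1 <- y[i1]
    hit <- if (direction == "up") y0 < level && y1 >= level
           else y0 > level && y1 <= level
    if (hit) {
      if (y1 == y0) return(time[i1])
      return(time[i0] + (level - y0) / (y1 - y0) * (time[i1] - time[i0]))
    }
    # boundary case: the first sample already beyond the level
    if (k == 2) {
      beyond <- if (direction == "up") y0 >= level else y0 <= level
      if (beyond) return(time[i0])
    }
  }
  NA_real_
}

#' Half-rise time
#'
#' Time from stimulation onset to the first (linearly interpolated)
#' crossing of 50% of the peak dF/F.
#'
#' @param dff_smoothed Smoothed dF/F series.
#' @param time Frame times, s.
#' @param protocol A [stimulus_protocol()].
#' @param peak Peak value (\code{max_dff}).
#' @return List with \code{t_half_rise} (s, relative to onset) and
#'   \code{rise_censored}.
#' @export
half_rise <- function(dff_smoothed, time, protocol, peak) {
  idx <- which(time >= protocol$onset_time)
  tc <- .first_crossing(time, dff_smoothed, idx, 0.5 * peak, "up")
  list(t_half_rise = if (is.na(tc)) NA_real_ else tc - protocol$onset_time,
       rise_censored = is.na(tc))
}

#' Half-decay time
#'
#' Time from the end of the stimulus train to the first (linearly
#' interpolated) crossing below 50% of the reference level. The reference
#' is the smoothed trace value at train end — identical to the peak when
#' the signal peaks at train end, and robust when the peak precedes train
#' end (intermittent traces). If the record ends before the crossing the
#' value is censored and the elapsed record is reported as a lower bound.
#'
#' @param dff_smoothed Smoothed dF/F series.
#' @param time Frame times, s.
#' @param protocol A [stimulus_protocol()].
#' @return List with \code{t_half_decay} (s from train end),
#'   \code{decay_censored}, and \code{decay_reference} (the level halved).
#' @export
half_decay <- function(dff_smoothed, time, protocol) {
  te <- train_end(protocol)
  ref <- stats::approx(time, dff_smoothed, xout = te, rule = 2)$y
  idx <- which(time >= te)
  tc <- .first_crossing(time, dff_smoothed, idx, 0.5 * ref, "down")
  if (is.na(tc)) {
    list(t_half_decay = utils::tail(time, 1) - te, decay_censored = TRUE,
         decay_reference = ref)
  } else {
    list(t_half_decay = tc - te, decay_censored = FALSE,
         decay_reference = ref)
  }
}

#' Responder call
#'
#' A bouton responds iff its peak dF/F strictly exceeds 200% of the
#' baseline noise N_B; a peak exactly at 2 x N_B is nonresponding.
#' Nonresponders are excluded from kinetics aggregation downstream.
#'
#' @param max_dff Peak smoothed dF/F.
#' @param n_b Baseline noise (dF/F units).
#' @return Logical.
#' @export
classify_responder <- function(max_dff, n_b) {
  isTRUE(max_dff > 2 * n_b)
}

#' Full kinetic quantification of one trace
#'
#' Smooths the dF/F trace (5-point running average), measures the peak in
#' the 2-s post-onset window, applies the responder gate, and — for
#' responders — the half-rise and half-decay times.
#'
#' @param trace A \code{bouton_trace} with \code{dff} computed.
#' @param protocol A [stimulus_protocol()].
#' @param window Peak-search window after onset, s.
#' @return An object of class \code{kinetics_result}.
#' @export
bouton_kinetics <- function(trace, protocol, window = 2) {
  stopifnot(inherits(trace, "bouton_trace"))
  if (is.null(trace$dff)) stop("compute_dff first")
  sm <- smooth_dff(trace$dff)
  pk <- max_dff(sm, trace$time, protocol, window)
  responder <- classify_responder(pk$max_dff, trace$n_b)
  rise <- list(t_half_rise = NA_real_, rise_censored = FALSE)
  decay <- list(t_half_decay = NA_real_, decay_censored = FALSE,
                decay_reference = NA_real_)
  if (responder) {
    rise <- half_rise(sm, trace$time, protocol, pk$max_dff)
    decay <- half_decay(sm, trace$time, protocol)
  }
  structure(list(bouton_id = trace$bouton_id, nmj_id = trace$nmj_id,
                 type = trace$type,
                 frequency_hz = protocol$frequency,
                 max_dff = pk$max_dff, t_max = pk$t_max,
                 t_half_rise = rise$t_half_rise,
                 rise_censored = rise$rise_censored,
                 t_half_decay = decay$t_half_decay,
                 decay_censored = decay$decay_censored,
                 responder = responder, n_b = trace$n_b,
                 dff_smoothed = sm, time = trace$time),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf(
    "Kinetics (bouton %s, NMJ %s, %s, %g Hz): max dF/F = %.3g [%s]",
    x$bouton_id, x$nmj_id, x$type, x$frequency_hz, x$max_dff,
    if (x$responder) "responder" else "nonresponding"))
  if (x$responder)
    cat(sprintf(", t1/2rise = %.3g s, t1/2decay = %.3g s%s",
                x$t_half_rise, x$t_half_decay,
                if (x$decay_censored) " (censored)" else ""))
  cat("\n")
  invisible(x)
}

#' Collect kinetics results into a data frame
#'
#' @param results List of \code{kinetics_result}.
#' @return Data frame, one row per result.
#' @export
kinetics_table <- function(results) {
  do.call(rbind, lapply(results, function(x)
    data.frame(bouton_id = x$bouton_id, nmj_id = x$nmj_id, type = x$type,
               frequency_hz = x$frequency_hz, max_dff = x$max_dff,
               t_half_rise_s = x$t_half_rise,
               t_half_decay_s = x$t_half_decay,
               responder = x$responder,
               rise_censored = x$rise_censored,
               decay_censored = x$decay_censored, n_b = x$n_b)))
}

#' Frequency-response summary
#'
#' Per tested frequency: mean/SD/SEM of peak dF/F at bouton grain (all
#' boutons pooled) and at NMJ grain (boutons averaged within terminal
#' first), plus the responder fraction. Censored decay values are excluded
#' from means but counted. Threshold frequency: lowest tested frequency
#' with responder fraction >= 0.5 (NA when never reached). Saturation
#' frequency: lowest tested frequency whose mean peak reaches 95% of the
#' maximum across frequencies. Both are operational definitions of terms
#' the field uses qualitatively.
#'
#' @param ktab Data frame from [kinetics_table()] (possibly several
#'   frequencies).
#' @return An object of class \code{frequency_response}: list with
#'   \code{per_frequency} (data frame), \code{threshold_frequency},
#'   \code{saturation_frequency}.
#' @export
frequency_response <- function(ktab) {
  stopifnot(nrow(ktab) >= 1)
  freqs <- sort(unique(ktab$frequency_hz))
  rows <- lapply(freqs, function(f) {
    d <- ktab[ktab$frequency_hz == f, ]
    nmj_means <- tapply(d$max_dff, d$nmj_id, mean)
    resp <- mean(d$responder)
    data.frame(frequency_hz = f,
               mean_max_dff = mean(d$max_dff), sd_max_dff = stats::sd(d$max_dff),
               sem_max_dff = stats::sd(d$max_dff) / sqrt(nrow(d)),
               nmj_mean_max_dff = mean(nmj_means),
               nmj_sd_max_dff = stats::sd(nmj_means),
               responder_fraction = resp,
               n_boutons = nrow(d), n_nmjs = length(nmj_means))
  })
  per <- do.call(rbind, rows)
  thr <- per$frequency_hz[per$responder_fraction >= 0.5]
  threshold <- if (length(thr)) min(thr) else NA_real_
  sat_level <- 0.95 * max(per$mean_max_dff)
  sat <- per$frequency_hz[per$mean_max_dff >= sat_level]
  saturation <- if (length(sat)) min(sat) else NA_real_
  structure(list(per_frequency = per, threshold_frequency = threshold,
                 saturation_frequency = saturation),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat("Frequency response:\n")
  print(x$per_frequency, row.names = FALSE, digits = 3)
  cat(sprintf("threshold frequency: %s Hz; saturation frequency: %s Hz\n",
              format(x$threshold_frequency), format(x$saturation_frequency)))
  invisible(x)
}
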