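#' ROI set for bouton trace extraction
#'
#' Pairs each bouton region with one adjacent homogeneous background region,
#' a terminal-type tag and an NMJ id. Pixels are stored as linear indices
#' into the frame matrix (0-based pixel convention \code{(px, py)} maps to
#' matrix element \code{[py + 1, px + 1]}).
#'
#' @param boutons List of integer pixel-index vectors, one per bouton.
#' @param backgrounds List of integer pixel-index vectors, one per bouton,
#'   disjoint from its bouton.
#' @param frame_shape Integer c(rows, cols).
#' @param type Terminal type per bouton ("Ib", "Is", "II").
#' @param nmj_id NMJ id per bouton.
#' @return An object of class \code{roi_set}.
#' @export
roi_set <- function(boutons, backgrounds, frame_shape,
                    type = rep("Ib", length(boutons)),
                    nmj_id = rep(1L, length(boutons))) {
  stopifnot(length(boutons) == length(backgrounds),
            length(type) == length(boutons),
            length(nmj_id) == length(boutons))
  for (i in seq_along(boutons)) {
    if (length(boutons[[i]]) == 0)
      stop(sprintf("empty bouton ROI for label %d", i))
    if (length(backgrounds[[i]]) == 0)
      stop(sprintf("empty background ROI for label %d", i))
    if (length(intersect(boutons[[i]], backgrounds[[i]])) > 0)
      stop(sprintf("bouton %d overlaps its background region", i))
  }
  structure(list(boutons = boutons, backgrounds = backgrounds,
                 frame_shape = as.integer(frame_shape),
                 type = type, nmj_id = nmj_id),
            class = "roi_set")
}

#' Build the ROI set matching an imaging model
#'
#' Bouton ROIs are the rendered footprints; each background region is a
#' small square placed adjacent to its bouton, avoiding every bouton
#' footprint (tried right, left, below, above).
#'
#' @param imaging An [imaging_model()] with \code{bouton_specs}.
#' @param bg_halfwidth Half-width of the square background region, px.
#' @param nmj_id Optional NMJ id per bouton.
#' @return A [roi_set()].
#' @export
rois_from_imaging <- function(imaging, bg_halfwidth = 2L, nmj_id = NULL) {
  bs <- imaging$bouton_specs
  fps <- suppressWarnings(bouton_footprints(imaging))
  sh <- imaging$frame_shape
  all_fp <- unique(unlist(lapply(fps, `[[`, "idx")))
  square <- function(cx, cy) {
    xs <- (cx - bg_halfwidth):(cx + bg_halfwidth)
    ys <- (cy - bg_halfwidth):(cy + bg_halfwidth)
    if (min(xs) < 0 || max(xs) > sh[2] - 1 || min(ys) < 0 || max(ys) > sh[1] - 1)
      return(NULL)
    g <- expand.grid(px = xs, py = ys)
    as.integer(g$px * sh[1] + g$py + 1L)
  }
  bgs <- vector("list", nrow(bs))
  for (i in seq_len(nrow(bs))) {
    off <- bs$radius[i] + bg_halfwidth + 2
    for (d in list(c(off, 0), c(-off, 0), c(0, off), c(0, -off),
                   c(2 * off, 0), c(-2 * off, 0))) {
      cand <- square(round(bs$x[i] + d[1]), round(bs$y[i] + d[2]))
      if (!is.null(cand) && length(intersect(cand, all_fp)) == 0) {
        bgs[[i]] <- cand
        break
      }
    }
    if (is.null(bgs[[i]]))
      stop(sprintf("could not place a background region for bouton %d", i))
  }
  roi_set(lapply(fps, `[[`, "idx"), bgs, sh, type = bs$type,
          nmj_id = if (is.null(nmj_id)) rep(1L, nrow(bs)) else nmj_id)
}

#' Extract background-subtracted bouton traces from a movie
#'
#' Per frame and bouton: \code{f_raw} is the mean intensity over the bouton
#' pixels, \code{f_bg} the mean over the paired background region, and
#' \code{f_t = f_raw - f_bg} (background subtraction is per frame).
#'
#' @param movie A [frame_stack()].
#' @param rois A [roi_set()].
#' @return List of \code{bouton_trace} objects with \code{time},
#'   \code{f_raw}, \code{f_bg}, \code{f_t} filled (baseline fields NA until
#'   [compute_baseline()]).
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "frame_stack"), inherits(rois, "roi_set"))
  d <- dim(movie$data)
  if (!all(d[1:2] == rois$frame_shape))
    stop("ROI frame_shape does not match the movie")
  npix <- d[1] * d[2]
  flat <- matrix(movie$data, nrow = npix)  # pixels x frames
  tt <- frame_times(movie)
  lapply(seq_along(rois$boutons), function(i) {
    f_raw <- colMeans(flat[rois$boutons[[i]], , drop = FALSE])
    f_bg <- colMeans(flat[rois$backgrounds[[i]], , drop = FALSE])
    structure(list(bouton_id = i, nmj_id = rois$nmj_id[i],
                   type = rois$type[i], time = tt,
                   frame_rate = movie$frame_rate,
                   f_raw = f_raw, f_bg = f_bg, f_t = f_raw - f_bg,
                   f_b = NA_real_, n_b = NA_real_, dff = NULL),
              class = "bouton_trace")
  })
}

#' Construct a bouton trace directly from a background-subtracted series
#'
#' Entry point for trace-level simulation and tests that bypass movie
#' rendering: supply \code{f_t} on a frame grid.
#'
#' @param f_t Background-subtracted fluorescence series.
#' @param frame_rate Frames per second.
#' @param bouton_id,nmj_id,type Identifiers.
#' @return A \code{bouton_trace}.
#' @export
bouton_trace <- function(f_t, frame_rate = 25, bouton_id = 1L,
                         nmj_id = 1L, type = "Ib") {
  structure(list(bouton_id = bouton_id, nmj_id = nmj_id, type = type,
                 time = (seq_along(f_t) - 0.5) / frame_rate,
                 frame_rate = frame_rate,
                 f_raw = f_t, f_bg = rep(0, length(f_t)), f_t = f_t,
                 f_b = NA_real_, n_b = NA_real_, dff = NULL),
            class = "bouton_trace")
}

#' @export
print.bouton_trace <- function(x, ...) {
  cat(sprintf("Bouton trace: id %s (NMJ %s, type %s), %d frames @ %g Hz",
              x$bouton_id, x$nmj_id, x$type, length(x$f_t), x$frame_rate))
  if (!is.na(x$f_b))
    cat(sprintf("; F_B = %.3g, N_B = %.3g", x$f_b, x$n_b))
  cat("\n")
  invisible(x)
}

#' @export
plot.bouton_trace <- function(x, ...) {
  y <- if (!is.null(x$dff)) x$dff else x$f_t
  graphics::plot(x$time, y, type = "l", xlab = "time (s)",
                 ylab = if (!is.null(x$dff)) expression(Delta * F / F) else
                   expression(F[t]), ...)
  invisible(x)
}

#' Baseline fluorescence and noise of a trace
#'
#' \code{f_b} (baseline, F_B) is the mean of \code{f_t} over the 25 frames
#' immediately preceding stimulation onset (1 s at 25 Hz); the frame
#' containing the onset is excluded. \code{n_b} (noise, N_B) is the RMS of
#' the baseline dF/F deviations, \code{sqrt(mean(((f_t - f_b)/f_b)^2))}
#' over those frames — i.e. the SD of baseline F_t divided by F_B — which
#' puts N_B on the same scale as max dF/F for the 200% responder gate.
#'
#' @param trace A \code{bouton_trace}.
#' @param protocol A [stimulus_protocol()].
#' @param n_baseline Number of baseline frames (default 25).
#' @return The trace with \code{f_b} and \code{n_b} filled.
#' @export
compute_baseline <- function(trace, protocol, n_baseline = 25L) {
  stopifnot(inherits(trace, "bouton_trace"),
            inherits(protocol, "stimulus_protocol"))
  idx <- which(trace$time < protocol$onset_time)
  if (length(idx) < n_baseline)
    stop(sprintf("need %d frames before stimulation onset, have %d",
                 n_baseline, length(idx)))
  idx <- utils::tail(idx, n_baseline)
  trace$baseline_idx <- idx
  trace$f_b <- mean(trace$f_t[idx])
  trace$n_b <- sqrt(mean(((trace$f_t[idx] - trace$f_b) / trace$f_b)^2))
  trace
}

#' Fractional fluorescence change of a trace
#'
#' \code{dff[i] = (f_t[i] - f_b) / f_b} for every frame, no smoothing.
#' A nonpositive baseline is a QC failure, not an exception: \code{dff}
#' stays NULL and the trace is flagged.
#'
#' @param trace A \code{bouton_trace} with baseline computed.
#' @return The trace with \code{dff} filled (or \code{qc_low_baseline} set).
#' @export
compute_dff <- function(trace) {
  stopifnot(inherits(trace, "bouton_trace"))
  if (is.na(trace$f_b)) stop("compute_baseline first")
  if (trace$f_b <= 0) {
    trace$qc_low_baseline <- TRUE
    return(trace)
  }
  trace$dff <- (trace$f_t - trace$f_b) / trace$f_b
  trace
}

#' Quality-control filter over a set of traces
#'
#' Flags traces whose baseline falls below an absolute floor or whose noise
#' exceeds a ceiling, plus manual contraction-artifact flags passed through
#' unchanged. Thresholds are configuration values, not taken from any
#' publication.
#'
#' @param traces List of \code{bouton_trace} with baselines computed.
#' @param f_b_floor Minimum acceptable baseline (absolute intensity).
#' @param n_b_ceiling Maximum acceptable baseline noise (dF/F units).
#' @param manual_exclude Integer indices excluded by eye (contraction
#'   artifacts).
#' @return List with \code{passing} (traces), \code{report} (data frame of
#'   per-trace flags) and \code{exclusion_fraction}.
#' @export
qc_filter <- function(traces, f_b_floor = 1, n_b_ceiling = 0.1,
                      manual_exclude = integer(0)) {
  rep_df <- data.frame(
    bouton = vapply(traces, function(x) x$bouton_id, numeric(1)),
    f_b = vapply(traces, function(x) x$f_b, numeric(1)),
    n_b = vapply(traces, function(x) x$n_b, numeric(1)))
  rep_df$low_baseline <- rep_df$f_b < f_b_floor |
    vapply(traces, function(x) isTRUE(x$qc_low_baseline), logical(1))
  rep_df$high_noise <- rep_df$n_b > n_b_ceiling
  rep_df$contraction_artifact <- seq_along(traces) %in% manual_exclude
  rep_df$pass <- !(rep_df$low_baseline | rep_df$high_noise |
                     rep_df$contraction_artifact)
  list(passing = traces[rep_df$pass], report = rep_df,
       exclusion_fraction = mean(!rep_df$pass))
}
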