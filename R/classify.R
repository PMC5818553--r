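#' Waveform classification rules
#'
#' All thresholds are fractional, so classification is invariant to uniform
#' scaling of the trace. The boundaries operationalize a taxonomy the
#' original observers applied by eye.
#'
#' @param drop_frac A stall/fall episode requires the trace to drop below
#'   \code{(1 - drop_frac)} of its running maximum during the train.
#' @param min_gap Minimum episode length in frames.
#' @param rebound_frac A post-train excursion must exceed
#'   \code{rebound_frac * max_dff} (after the trace has fallen below 50% of
#'   the peak) to count as rebound.
#' @return List of class \code{waveform_rules}.
#' @export
waveform_rules <- function(drop_frac = 0.3, min_gap = 3L,
                           rebound_frac = 0.5) {
  stopifnot(drop_frac > 0, drop_frac < 1, min_gap >= 1, rebound_frac > 0)
  structure(list(drop_frac = drop_frac, min_gap = as.integer(min_gap),
                 rebound_frac = rebound_frac), class = "waveform_rules")
}

#' Classify the waveform of a dF/F trace
#'
#' Rule cascade over the smoothed trace: (1) nonresponders are
#' \code{no_response}; (2) during the train, stall/fall episodes — runs of
#' at least \code{min_gap} frames below \code{(1 - drop_frac)} of the
#' running maximum, once the signal has reached responder grade — mark the
#' trace \code{aborted} when the final episode never recovers before train
#' end, or \code{intermittent} when delivery resumes; (3) after train end,
#' a renewed excursion above \code{rebound_frac * max_dff} following a fall
#' below 50% of the peak marks \code{rebound} (upgrades \code{normal} only;
#' reported as a flag otherwise); else \code{normal}.
#'
#' @param kin A \code{kinetics_result} from [bouton_kinetics()] (carries
#'   the smoothed trace and responder call).
#' @param protocol A [stimulus_protocol()].
#' @param rules A [waveform_rules()].
#' @return Object of class \code{waveform_label}: list with \code{label},
#'   \code{evidence} (episode onset times, s), \code{rebound_flag}.
#' @export
classify_waveform <- function(kin, protocol, rules = waveform_rules()) {
  stopifnot(inherits(kin, "kinetics_result"))
  if (!kin$responder)
    return(structure(list(label = "no_response", evidence = numeric(0),
                          rebound_flag = FALSE), class = "waveform_label"))
  time <- kin$time
  y <- kin$dff_smoothed
  te <- train_end(protocol)
  tr_idx <- which(time >= protocol$onset_time & time <= te)
  runmax <- cummax(y[tr_idx])
  # consider episodes only once a responder-grade amplitude is reached
  armed <- runmax > 2 * kin$n_b
  below <- armed & (y[tr_idx] < (1 - rules$drop_frac) * runmax)
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  epi <- which(runs$values & runs$lengths >= rules$min_gap)
  evidence <- time[tr_idx][starts[epi]]
  label <- "normal"
  if (length(epi) > 0) {
    terminal <- max(ends[epi]) == length(tr_idx)
    label <- if (terminal && length(epi) == 1L) "aborted" else "intermittent"
  }
  # post-train rebound: fall below 50% of peak, then a renewed excursion
  rebound_flag <- FALSE
  post <- which(time > te)
  if (length(post) > 2) {
    fell <- .first_crossing(time, y, post, 0.5 * kin$max_dff, "down")
    if (!is.na(fell)) {
      after <- post[time[post] > fell]
      if (length(after) > 0 &&
          max(y[after]) > rules$rebound_frac * kin$max_dff)
        rebound_flag <- TRUE
    }
  }
  if (rebound_flag && label == "normal") label <- "rebound"
  structure(list(label = label, evidence = evidence,
                 rebound_flag = rebound_flag), class = "waveform_label")
}

#' @export
print.waveform_label <- function(x, ...) {
  cat(sprintf("Waveform: %s", x$label))
  if (length(x$evidence))
    cat(sprintf(" (episodes at %s s)",
                paste(signif(x$evidence, 3), collapse = ", ")))
  if (x$rebound_flag && x$label != "rebound") cat(" [rebound flag]")
  cat("\n")
  invisible(x)
}

#' Terminal-level consensus label
#'
#' Boutons of one terminal behave uniformly; the consensus is the majority
#' label over its boutons (ties broken by the more irregular label, in the
#' order no_response > aborted > intermittent > rebound > normal).
#'
#' @param labels Character vector of per-bouton labels for one terminal.
#' @return Single consensus label.
#' @export
consensus_label <- function(labels) {
  severity <- c(no_response = 5, aborted = 4, intermittent = 3,
                rebound = 2, normal = 1)
  tab <- table(labels)
  best <- names(tab)[tab == max(tab)]
  best[order(-severity[best])][1]
}

#' Tally waveform labels per group
#'
#' Counts of NMJs exhibiting each waveform per group (e.g. genotype),
#' mirroring the reporting convention "counts out of NMJs examined".
#'
#' @param df Data frame with columns \code{group}, \code{nmj_id},
#'   \code{label} (per-bouton rows allowed; NMJs are collapsed to their
#'   consensus first).
#' @return Data frame: group, label, n_nmjs, total_nmjs.
#' @export
tally_waveforms <- function(df) {
  stopifnot(all(c("group", "nmj_id", "label") %in% names(df)))
  cons <- stats::aggregate(label ~ group + nmj_id, data = df,
                           FUN = consensus_label)
  lv <- c("normal", "aborted", "intermittent", "rebound", "no_response")
  out <- do.call(rbind, lapply(split(cons, cons$group), function(g) {
    data.frame(group = g$group[1], label = lv,
               n_nmjs = as.integer(table(factor(g$label, levels = lv))),
               total_nmjs = nrow(g))
  }))
  rownames(out) <- NULL
  out
}
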