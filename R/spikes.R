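#' Generate axonal spike trains from a stimulus protocol
#'
#' Walks the pulse train applying the conduction rules of the excitability
#' profile. A pulse is delivered unless (i) the previous AP lies within
#' \code{failure_recovery_time} of the pulse, (ii) a permanent block
#' (\code{block_after_pulse}) is in force, or (iii) the pulse falls in the
#' "off" phase of \code{block_cycle}. A delivered pulse fires
#' \code{aps_per_stimulus} APs spaced \code{1/burst_rate} apart. After the
#' train, rebound firing (if configured) adds events at \code{rebound_rate}
#' for \code{rebound_duration}, starting \code{rebound_delay} after train
#' end. The walk is deterministic; \code{seed} is reserved for stochastic
#' extensions and recorded in the output.
#'
#' @param protocol A [stimulus_protocol()].
#' @param excitability An [excitability_profile()].
#' @param seed Integer, recorded in the result.
#'
#' @return List of class \code{spike_train} with \code{ap_times} (sorted
#'   event times, s), \code{delivery} (data frame: pulse_index, pulse_time,
#'   delivered), \code{rebound_times}, \code{protocol}, \code{excitability},
#'   \code{seed}.
#' @examples
#' st <- generate_spike_trains(stimulus_protocol(2), excitability_profile())
#' st$ap_times   # one AP per pulse
#' @export
generate_spike_trains <- function(protocol, excitability, seed = 1L) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(excitability, "excitability_profile"))
  ex <- excitability
  if (ex$aps_per_stimulus > 1 && 1 / ex$burst_rate < ex$refractory_period)
    stop("burst spacing 1/burst_rate is shorter than refractory_period")

  pt <- pulse_times(protocol)
  np <- length(pt)
  delivered <- logical(np)
  ap_times <- numeric(0)
  last_ap <- -Inf
  n_delivered <- 0L
  cyc <- ex$block_cycle

  for (i in seq_len(np)) {
    ok <- TRUE
    if (ex$aps_per_stimulus == 0) ok <- FALSE
    if (ok && ex$failure_recovery_time > 0 &&
        (pt[i] - last_ap) < ex$failure_recovery_time) ok <- FALSE
    if (ok && !is.na(ex$block_after_pulse) &&
        n_delivered >= ex$block_after_pulse) ok <- FALSE
    if (ok && !is.null(cyc)) {
      phase <- (i - 1L) %% (cyc[1] + cyc[2])
      if (phase >= cyc[1]) ok <- FALSE
    }
    if (ok) {
      burst <- pt[i] + (seq_len(ex$aps_per_stimulus) - 1) / ex$burst_rate
      ap_times <- c(ap_times, burst)
      last_ap <- burst[length(burst)]
      n_delivered <- n_delivered + 1L
      delivered[i] <- TRUE
    }
  }

  rebound_times <- numeric(0)
  if (ex$rebound_rate > 0 && ex$rebound_duration > 0) {
    t0 <- train_end(protocol) + ex$rebound_delay
    n <- floor(ex$rebound_rate * ex$rebound_duration)
    if (n > 0) {
      rebound_times <- t0 + (seq_len(n) - 1) / ex$rebound_rate
      rebound_times <- rebound_times[rebound_times < protocol$record_duration]
      ap_times <- c(ap_times, rebound_times)
    }
  }

  structure(list(ap_times = sort(ap_times),
                 delivery = data.frame(pulse_index = seq_len(np),
                                       pulse_time = pt,
                                       delivered = delivered),
                 rebound_times = rebound_times,
                 protocol = protocol, excitability = ex,
                 seed = as.integer(seed)),
            class = "spike_train")
}

#' Ground-truth waveform label from a delivery record
#'
#' Derives the Fig-11-style taxonomy directly from the simulator's conduction
#' record: \code{no_response} when no (or only the first) pulse is delivered,
#' \code{aborted} when delivery ceases permanently before train end after at
#' least one delivered pulse, \code{intermittent} when a failed block of >=
#' \code{min_block} pulses is followed by renewed delivery, \code{rebound}
#' when post-train discharge is present (and the train itself is regular),
#' else \code{normal}.
#'
#' @param spike_train A \code{spike_train}.
#' @param min_block Minimum consecutive failed pulses to count as a gap.
#' @return Character label.
#' @export
true_waveform_label <- function(spike_train, min_block = 3L) {
  d <- spike_train$delivery$delivered
  has_rebound <- length(spike_train$rebound_times) > 0
  if (sum(d) <= 1L) return("no_response")
  runs <- rle(d)
  fail_runs <- which(!runs$values & runs$lengths >= min_block)
  n_runs <- length(runs$values)
  label <- "normal"
  if (length(fail_runs) > 0) {
    # terminal failure with no later delivery -> aborted
    if (max(fail_runs) == n_runs && length(fail_runs) == 1L) {
      label <- "aborted"
    } else {
      label <- "intermittent"
    }
  }
  if (label == "normal" && has_rebound) label <- "rebound"
  label
}
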