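#' Stimulation protocol
#'
#' Describes one stimulus train: frequency, train duration, onset within the
#' record, total record duration, pulse width and the inter-trial interval
#' used when trains are delivered sequentially. Pulses are delivered at
#' \code{onset_time, onset_time + 1/frequency, ...}; the number of pulses is
#' \code{floor(frequency * train_duration)}.
#'
#' @param frequency Train frequency in Hz (> 0).
#' @param train_duration Train duration in seconds (default 2 s).
#' @param onset_time Time of the first pulse, seconds from record start.
#' @param record_duration Total recorded duration in seconds.
#' @param pulse_width Stimulus pulse width in seconds (default 0.1 ms).
#' @param inter_trial_interval Gap between successive trains in seconds
#'   (default 4 s); informational, a protocol describes a single train.
#'
#' @return An object of class \code{stimulus_protocol}.
#' @examples
#' p <- stimulus_protocol(20)
#' pulse_times(p)[1:4]
#' @export
stimulus_protocol <- function(frequency, train_duration = 2,
                              onset_time = 2, record_duration = 8,
                              pulse_width = 1e-4,
                              inter_trial_interval = 4) {
  stopifnot(is.numeric(frequency), length(frequency) == 1L, frequency > 0,
            train_duration > 0, onset_time >= 0, pulse_width > 0,
            inter_trial_interval >= 0)
  if (onset_time + train_duration > record_duration)
    stop("train (onset_time + train_duration) must end within record_duration")
  structure(list(frequency = frequency, train_duration = train_duration,
                 onset_time = onset_time, record_duration = record_duration,
                 pulse_width = pulse_width,
                 inter_trial_interval = inter_trial_interval),
            class = "stimulus_protocol")
}

#' Pulse times of a protocol
#'
#' @param protocol A \code{stimulus_protocol}.
#' @return Numeric vector of pulse onset times (s), first at
#'   \code{onset_time}, \code{floor(frequency * train_duration)} in total.
#' @export
pulse_times <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  n <- floor(protocol$frequency * protocol$train_duration)
  protocol$onset_time + (seq_len(n) - 1) / protocol$frequency
}

#' End of the stimulus train
#'
#' @param protocol A \code{stimulus_protocol}.
#' @return \code{onset_time + train_duration}, seconds.
#' @export
train_end <- function(protocol) protocol$onset_time + protocol$train_duration

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Stimulus train: %g Hz x %g s (%d pulses), onset %g s, record %g s\n",
              x$frequency, x$train_duration,
              floor(x$frequency * x$train_duration),
              x$onset_time, x$record_duration))
  invisible(x)
}

#' Read / write a protocol as JSON
#'
#' @param path File path.
#' @return \code{read_protocol} returns a \code{stimulus_protocol}.
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_protocol(x$frequency, x$train_duration, x$onset_time,
                    x$record_duration, x$pulse_width, x$inter_trial_interval)
}

#' @rdname read_protocol
#' @param protocol A \code{stimulus_protocol} to write.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
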