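#' Acquisition protocol for a single stimulation trial
#'
#' Builds the timing description of one 30-s stimulation acquisition: a train
#' of brief current pulses delivered to the contralateral median nerve while
#' composite B-scans (each built from repeated B-scans at one lateral
#' location) are collected at a fixed cadence, with a DCS flow channel
#' sampled concurrently. Defaults reproduce the standard protocol: 65
#' composite frames at 0.46 s over 30 s, stimulus onset 5 s after
#' acquisition start, 12 pulses at 3 Hz (4 s of stimulation), 32 repeated
#' B-scans per composite frame, 9 pre-stimulus baseline frames, and a 4.4-Hz
#' DCS sampling rate.
#'
#' @param ... protocol fields to override. Valid fields and defaults:
#'   `total_duration` (30 s), `stim_onset` (5 s), `stim_pulses` (12),
#'   `stim_rate` (3 Hz), `stim_duration` (4 s), `composite_frame_period`
#'   (0.46 s), `n_frames` (65), `n_baseline_frames` (9),
#'   `n_repeats_per_frame` (32), `dcs_rate` (4.4 Hz),
#'   `n_stim_presentations` (10).
#' @return An object of class `acq_protocol` (a validated named list).
#' @examples
#' p <- make_protocol()
#' p$n_frames                 # 65
#' stim_frames(p)             # 1-based composite frames touched by the stimulus
#' @export
make_protocol <- function(...) {
  proto <- list(
    total_duration = 30, stim_onset = 5, stim_pulses = 12, stim_rate = 3,
    stim_duration = 4, composite_frame_period = 0.46, n_frames = 65L,
    n_baseline_frames = 9L, n_repeats_per_frame = 32L, dcs_rate = 4.4,
    n_stim_presentations = 10L
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides)[1])) {
    overrides <- overrides[[1]]
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(proto))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == ""))
      stop_config("unknown protocol field(s): %s",
                  paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    proto[names(overrides)] <- overrides
  }
  counts <- c("stim_pulses", "n_frames", "n_baseline_frames",
              "n_repeats_per_frame", "n_stim_presentations")
  for (f in counts) {
    if (!is_count(proto[[f]])) stop_config("protocol field '%s' must be a positive integer", f)
    proto[[f]] <- as.integer(proto[[f]])
  }
  for (f in c("total_duration", "stim_onset", "stim_rate", "stim_duration",
              "composite_frame_period", "dcs_rate")) {
    if (!is_number(proto[[f]]) || proto[[f]] <= 0)
      stop_config("protocol field '%s' must be a positive number", f)
  }
  with(proto, {
    if (n_frames * composite_frame_period < total_duration - composite_frame_period)
      stop_config("frames do not cover the acquisition: n_frames * period < total_duration - period")
    if (stim_onset + stim_duration >= total_duration)
      stop_config("stimulus must end before the acquisition does")
    if (n_baseline_frames * composite_frame_period > stim_onset)
      stop_config("baseline frames extend past the stimulus onset")
  })
  structure(proto, class = "acq_protocol")
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat("Acquisition protocol:\n")
  cat(sprintf("  %d composite frames @ %.2f s over %.0f s (%d repeats/frame)\n",
              x$n_frames, x$composite_frame_period, x$total_duration,
              x$n_repeats_per_frame))
  cat(sprintf("  stimulus: %d pulses @ %g Hz, %g s starting at %g s (frames %d-%d)\n",
              x$stim_pulses, x$stim_rate, x$stim_duration, x$stim_onset,
              min(stim_frames(x)), max(stim_frames(x))))
  cat(sprintf("  baseline: first %d frames; DCS @ %g Hz; %d presentations/trial\n",
              x$n_baseline_frames, x$dcs_rate, x$n_stim_presentations))
  invisible(x)
}

#' Composite-frame times and stimulus frame indices
#'
#' `frame_times()` returns the mid-exposure time of each composite frame,
#' `(i - 1/2) * composite_frame_period`. `stim_frames()` returns the 1-based
#' indices of the frames whose exposure interval intersects the stimulus
#' window `[stim_onset, stim_onset + stim_duration)`; under the default
#' protocol these are frames 11 through 20. `baseline_window()` returns the
#' `[0, t)` interval spanned by the pre-stimulus baseline frames.
#'
#' @param protocol an [make_protocol()] object.
#' @return `frame_times`: numeric vector of length `n_frames` (seconds);
#'   `stim_frames`: integer vector; `baseline_window`: numeric length-2.
#' @export
frame_times <- function(protocol) {
  (seq_len(protocol$n_frames) - 0.5) * protocol$composite_frame_period
}

#' @rdname frame_times
#' @export
stim_frames <- function(protocol) {
  p <- protocol$composite_frame_period
  starts <- (seq_len(protocol$n_frames) - 1) * p
  on <- protocol$stim_onset
  off <- on + protocol$stim_duration
  which(starts < off & (starts + p) > on)
}

#' @rdname frame_times
#' @export
baseline_window <- function(protocol) {
  c(0, protocol$n_baseline_frames * protocol$composite_frame_period)
}

#' DCS sample times for one acquisition
#'
#' Samples start at time zero and run at `dcs_rate` for `total_duration`;
#' the default protocol yields `floor(30 * 4.4) = 132` samples.
#'
#' @param protocol an [make_protocol()] object.
#' @return numeric vector of sample times in seconds.
#' @export
dcs_times <- function(protocol) {
  n <- floor(protocol$total_duration * protocol$dcs_rate)
  (seq_len(n) - 1) / protocol$dcs_rate
}
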