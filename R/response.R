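#' Construct a relative-flow waveform
#'
#' A time series of relative blood flow (dimensionless, baseline near 1)
#' with its baseline and stimulus windows and provenance attached. Both the
#' per-class angiogram readouts and the DCS channel use this container.
#'
#' @param times sample times, seconds, strictly increasing.
#' @param values relative flow values.
#' @param baseline_window `[0, t)` interval in seconds used for
#'   normalization.
#' @param stim_window `[onset, onset + duration]` in seconds.
#' @param modality `"OCT-A"` or `"DCS"`.
#' @param vessel_class `"small"`, `"medium"`, `"large"` or `NA`.
#' @param current_mA stimulus current or `NA`.
#' @param n_averaged number of presentations averaged into the waveform.
#' @param sem optional pointwise standard error.
#' @return object of class `flow_waveform`.
#' @export
flow_waveform <- function(times, values, baseline_window = c(0, 4.14),
                          stim_window = c(5, 9), modality = "OCT-A",
                          vessel_class = NA_character_, current_mA = NA_real_,
                          n_averaged = 1L, sem = NULL) {
  stopifnot(length(times) == length(values), !is.unsorted(times, strictly = TRUE))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 baseline_window = baseline_window, stim_window = stim_window,
                 modality = modality, vessel_class = vessel_class,
                 current_mA = current_mA, n_averaged = as.integer(n_averaged),
                 sem = sem),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("%s flow waveform%s: %d samples over %.1f s (n_averaged = %d)\n",
              x$modality,
              if (!is.na(x$vessel_class)) paste0(" [", x$vessel_class, "]") else "",
              length(x$times), diff(range(x$times)), x$n_averaged))
  invisible(x)
}

#' @export
plot.flow_waveform <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (s)",
       ylab = "relative flow", ...)
  graphics::abline(h = 1, col = "grey70", lty = 3)
  graphics::rect(x$stim_window[1], graphics::par("usr")[3], x$stim_window[2],
                 graphics::par("usr")[4],
                 col = grDevices::adjustcolor("red", 0.08), border = NA)
  invisible(x)
}

#' Normalize a raw signal to its pre-stimulus baseline
#'
#' Divides the values by their mean over the baseline window so the output
#' expresses relative flow with baseline mean exactly 1. Idempotent.
#'
#' @param raw a `flow_waveform`, or a list with `times` and `values`.
#' @param baseline_window `[0, t)` seconds; defaults to the waveform's own.
#' @return a `flow_waveform` with baseline mean 1.
#' @export
normalize_to_baseline <- function(raw, baseline_window = NULL) {
  if (is.null(baseline_window)) {
    baseline_window <- if (!is.null(raw$baseline_window)) raw$baseline_window else c(0, 4)
  }
  inb <- raw$times >= baseline_window[1] & raw$times < baseline_window[2]
  if (sum(inb) < 2) stop_config("normalize_to_baseline: need >= 2 baseline samples")
  b <- mean(raw$values[inb])
  if (!is.finite(b) || b <= 0)
    stop_config("normalize_to_baseline: nonpositive baseline mean (signal is not interpretable as flow)")
  out <- if (inherits(raw, "flow_waveform")) raw else
    flow_waveform(raw$times, raw$values, baseline_window = baseline_window)
  out$values <- raw$values / b
  out$baseline_window <- baseline_window
  if (!is.null(out$sem)) out$sem <- out$sem / b
  out
}

#' Average a set of repeated-presentation waveforms
#'
#' Pointwise mean over presentations sharing a time grid; the pointwise
#' standard error of the mean is retained in `sem` and `n_averaged` sums.
#'
#' @param waveforms list of `flow_waveform`s on identical grids.
#' @return a `flow_waveform`.
#' @export
average_presentations <- function(waveforms) {
  stopifnot(length(waveforms) >= 1)
  t0 <- waveforms[[1]]$times
  for (w in waveforms)
    if (length(w$times) != length(t0) || any(abs(w$times - t0) > 1e-9))
      stop_config("average_presentations: time grids differ")
  vals <- vapply(waveforms, `[[`, numeric(length(t0)), "values")
  vals <- matrix(vals, nrow = length(t0))
  out <- waveforms[[1]]
  out$values <- rowMeans(vals)
  out$sem <- if (length(waveforms) > 1)
    apply(vals, 1, stats::sd) / sqrt(length(waveforms)) else NULL
  out$n_averaged <- sum(vapply(waveforms, `[[`, 1L, "n_averaged"))
  out
}

#' Per-class relative-flow waveforms from a trial of angiogram frames
#'
#' Composition of [apply_masks()] and [normalize_to_baseline()]: for each
#' diameter class, the masked angiogram sums over the trial's frames are
#' normalized to the mean of the baseline frames, producing one relative
#' flow waveform per class with time stamps at the frame centers.
#'
#' @param frames list of `angio_frame`s (one trial, protocol-consistent
#'   count).
#' @param masks a [segment_vessels()] object.
#' @param protocol an [make_protocol()] object.
#' @param current_mA stimulus current recorded on the outputs.
#' @return named list of three `flow_waveform`s (`small`, `medium`,
#'   `large`).
#' @export
extract_class_response <- function(frames, masks, protocol,
                                   current_mA = NA_real_) {
  if (length(frames) != protocol$n_frames)
    warning(sprintf("trial has %d frames; protocol specifies %d",
                    length(frames), protocol$n_frames))
  sums <- apply_masks(frames, masks)
  tt <- (seq_along(frames) - 0.5) * protocol$composite_frame_period
  bw <- baseline_window(protocol)
  sw <- c(protocol$stim_onset, protocol$stim_onset + protocol$stim_duration)
  out <- lapply(c("small", "medium", "large"), function(cl) {
    raw <- flow_waveform(tt, sums[, cl], baseline_window = bw,
                         stim_window = sw, modality = "OCT-A",
                         vessel_class = cl, current_mA = current_mA)
    normalize_to_baseline(raw)
  })
  names(out) <- c("small", "medium", "large")
  out
}

#' Resample a waveform onto a target time grid
#'
#' Linear interpolation onto `target_times`; needed to compare the 4.4-Hz
#' DCS channel with the 0.46-s composite-frame grid. Extrapolation is an
#' error.
#'
#' @param waveform a `flow_waveform`.
#' @param target_times times within the waveform's span.
#' @return a `flow_waveform` on the target grid with metadata preserved.
#' @export
resample_to_grid <- function(waveform, target_times) {
  rng <- range(waveform$times)
  if (any(target_times < rng[1] - 1e-9) || any(target_times > rng[2] + 1e-9))
    stop_config("resample_to_grid: target times outside the waveform span [%g, %g]",
                rng[1], rng[2])
  out <- waveform
  out$values <- stats::approx(waveform$times, waveform$values,
                              xout = target_times)$y
  out$times <- as.numeric(target_times)
  out$sem <- NULL
  out
}
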