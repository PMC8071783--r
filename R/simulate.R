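#' Simulate a stack of repeated complex B-scans
#'
#' Generates one composite-frame acquisition: `repeats` complex B-scans of
#' the scene at fixed instantaneous flow. Parenchyma pixels are the scene's
#' static speckle field plus fresh complex detector noise at every repeat,
#' so their repeat-to-repeat magnitude differences come from detector noise
#' only. Pixels inside a vessel cross-section additionally fluctuate in
#' magnitude with standard deviation
#' `flow_contrast_scale * baseline_decorrelation * flow`, drawn fresh at
#' every repeat. The expected average absolute magnitude difference read
#' out by [compute_angiogram()] is therefore
#' `(2/sqrt(pi)) * sqrt(sigma_flow^2 + sigma_detector^2)` - proportional to
#' flow wherever the flow contrast dominates the detector noise, which makes
#' the baseline-normalized angiogram a faithful relative flow measure.
#'
#' @param scene a [make_scene()] object.
#' @param flow_levels numeric vector of relative flow levels (>= 0), one per
#'   scene vessel (recycled from length 1), or a named vector over classes
#'   `c(small=, medium=, large=)`.
#' @param repeats number of repeated B-scans (>= 2 for angiography).
#' @param frame_index,lateral_location_index bookkeeping indices stored on
#'   the output.
#' @param seed optional RNG seed (bit-identical output for equal seeds).
#' @return object of class `bscan_series`: complex array `data` of dim
#'   `(depth_px, lateral_px, repeats)`, plus `scale` (um/px) and indices.
#' @export
simulate_bscan_series <- function(scene, flow_levels = 1, repeats = 32,
                                  frame_index = 1L,
                                  lateral_location_index = 1L, seed = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  if (!is_count(repeats) || repeats < 2)
    stop_config("simulate_bscan_series: repeats must be an integer >= 2")
  nv <- length(scene$vessels)
  if (!is.null(names(flow_levels)) && all(names(flow_levels) != "")) {
    bad <- setdiff(names(flow_levels), c("small", "medium", "large"))
    if (length(bad))
      stop_config("unknown vessel class key(s): %s", paste(bad, collapse = ", "))
    cls <- vapply(scene$vessels, `[[`, "", "class_truth")
    fl <- rep(1, nv)
    for (k in names(flow_levels)) fl[cls == k] <- flow_levels[[k]]
    flow_levels <- fl
  } else if (length(flow_levels) == 1L) {
    flow_levels <- rep(flow_levels, nv)
  }
  if (length(flow_levels) != nv)
    stop_config("flow_levels must have one entry per vessel (%d)", nv)
  if (any(flow_levels < 0)) stop_config("flow levels must be >= 0")

  d <- scene$dim_px
  n <- prod(d)
  with_seed(seed, {
    data <- rep(as.vector(scene$static_field), repeats)
    if (nv > 0) {
      s_flow <- scene$flow_contrast_scale * flow_levels *
        vapply(scene$vessels, `[[`, 0, "baseline_decorrelation")
      vidx <- unlist(lapply(scene$vessel_px, function(vp)
        (vp$idx[, "x"] - 1L) * d[1] + vp$idx[, "z"]))
      npx <- vapply(scene$vessel_px, function(vp) nrow(vp$idx), 0L)
      sds <- rep(s_flow, times = npx)
      phases <- unlist(lapply(scene$vessel_px, `[[`, "phase"))
      K <- length(vidx)
      mags <- scene$vessel_brightness +
        stats::rnorm(K * repeats, 0, rep(sds, repeats))
      pos <- rep(vidx, repeats) + rep((seq_len(repeats) - 1L) * n, each = K)
      data[pos] <- mags * exp(1i * rep(phases, repeats))
    }
    if (scene$detector_noise_sd > 0) {
      data <- data +
        complex(real = stats::rnorm(n * repeats, 0, scene$detector_noise_sd),
                imaginary = stats::rnorm(n * repeats, 0, scene$detector_noise_sd))
    }
    dim(data) <- c(d[1], d[2], repeats)
  })
  structure(list(data = data, scale = scene$scale,
                 frame_index = as.integer(frame_index),
                 lateral_location_index = as.integer(lateral_location_index)),
            class = "bscan_series")
}

#' @export
print.bscan_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("B-scan series: %d repeats of %d x %d px @ %g um/px (frame %d)\n",
              d[3], d[1], d[2], x$scale, x$frame_index))
  invisible(x)
}

# Ground-truth per-vessel flow levels at each composite frame time.
trial_flow_levels <- function(protocol, scene) {
  tt <- frame_times(protocol)
  nv <- length(scene$vessels)
  flows <- matrix(1, length(tt), nv)
  post <- tt >= protocol$stim_onset
  for (v in seq_len(nv)) {
    resp <- scene$vessels[[v]]$response
    if (!is.null(resp))
      flows[post, v] <- 1 + hrf_eval(resp, tt[post] - protocol$stim_onset)
  }
  flows
}

#' Simulate one stimulation trial as a sequence of B-scan stacks
#'
#' Runs the full acquisition clock: each vessel's flow level follows
#' `1 + HRF(t - stim_onset)` from its ground-truth response, and one stack
#' of repeated B-scans is generated per composite frame. Returns the raw
#' stacks (memory-heavy; see [simulate_trial_angiograms()] for the
#' angiogram-only variant used by the experiment driver).
#'
#' @param protocol an [make_protocol()] object.
#' @param scene a [make_scene()] object.
#' @param seed optional RNG seed.
#' @return list with `series` (list of `n_frames` [simulate_bscan_series()]
#'   outputs), `flows` (matrix `n_frames` x n_vessels of ground-truth flow
#'   levels) and `times` (frame centers, seconds).
#' @export
simulate_trial <- function(protocol, scene, seed = NULL) {
  flows <- trial_flow_levels(protocol, scene)
  seeds <- derive_seeds(seed, protocol$n_frames)
  series <- lapply(seq_len(protocol$n_frames), function(i) {
    simulate_bscan_series(scene, flow_levels = flows[i, ],
                          repeats = protocol$n_repeats_per_frame,
                          frame_index = i,
                          seed = if (is.null(seed)) NULL else seeds[i])
  })
  list(series = series, flows = flows, times = frame_times(protocol))
}

#' Simulate a trial and reduce each frame to its angiogram
#'
#' Identical acquisition model to [simulate_trial()], but each frame's stack
#' is converted to an angiogram immediately and discarded, so an
#' 11-animal experiment fits in memory.
#'
#' @inheritParams simulate_trial
#' @return list with `angiograms` (list of `n_frames` [angiogram_frame()]
#'   objects), `flows`, `times`.
#' @export
simulate_trial_angiograms <- function(protocol, scene, seed = NULL) {
  flows <- trial_flow_levels(protocol, scene)
  seeds <- derive_seeds(seed, protocol$n_frames)
  ang <- lapply(seq_len(protocol$n_frames), function(i) {
    s <- simulate_bscan_series(scene, flow_levels = flows[i, ],
                               repeats = protocol$n_repeats_per_frame,
                               frame_index = i,
                               seed = if (is.null(seed)) NULL else seeds[i])
    compute_angiogram(s)
  })
  list(angiograms = ang, flows = flows, times = frame_times(protocol))
}

#' Simulate a DCS relative-flow waveform
#'
#' The diffuse channel shares the trial's response shape: samples at
#' `dcs_rate` over the acquisition equal `1 + HRF(t - stim_onset)` plus
#' i.i.d. Gaussian noise. This stands in for a measured relative
#' blood-flow-index time series; no photon-correlation physics is modeled.
#'
#' @param protocol an [make_protocol()] object.
#' @param response an [hrf_design()] object (ground-truth fractional
#'   response), or `NULL` for no response.
#' @param noise_sd per-sample noise standard deviation (relative flow units).
#' @param seed optional RNG seed.
#' @return a [flow_waveform()] with `modality = "DCS"`; 132 samples under
#'   the default protocol (`floor(30 * 4.4)`).
#' @export
simulate_dcs_waveform <- function(protocol, response = NULL, noise_sd = 0.015,
                                  seed = NULL) {
  stopifnot(noise_sd >= 0)
  tt <- dcs_times(protocol)
  v <- rep(1, length(tt))
  if (!is.null(response)) {
    post <- tt >= protocol$stim_onset
    v[post] <- 1 + hrf_eval(response, tt[post] - protocol$stim_onset)
  }
  if (noise_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(length(tt), 0, noise_sd))
  flow_waveform(tt, v, baseline_window = c(0, 4),
                stim_window = c(protocol$stim_onset,
                                protocol$stim_onset + protocol$stim_duration),
                modality = "DCS")
}

#' Toy intensity autocorrelation model for the diffuse channel
#'
#' A single-exponential normalized intensity autocorrelation,
#' `g2(tau) = 1 + beta * exp(-2 * gamma0 * flow_index * tau)`: the decay
#' rate grows with scatterer motion, which is the property DCS exploits.
#' `extract_flow_index()` inverts it by least squares on
#' `log(g2 - 1)`; the noise-free round trip is exact.
#'
#' @param flow_index relative flow index (> 0).
#' @param beta coherence factor in (0, 1].
#' @param tau_grid lag times in seconds.
#' @param gamma0 decay rate per unit flow index (1/s).
#' @return `simulate_g2`: data frame with `tau` and `g2`;
#'   `extract_flow_index`: the recovered flow index.
#' @examples
#' g2 <- simulate_g2(2.5)
#' extract_flow_index(g2)   # 2.5
#' @export
simulate_g2 <- function(flow_index, beta = 0.5,
                        tau_grid = 10^seq(-6, -2, length.out = 64),
                        gamma0 = 1e4) {
  stopifnot(is_number(flow_index), flow_index > 0, beta > 0, beta <= 1)
  data.frame(tau = tau_grid,
             g2 = 1 + beta * exp(-2 * gamma0 * flow_index * tau_grid))
}

#' @rdname simulate_g2
#' @param curve data frame with columns `tau`, `g2`.
#' @export
extract_flow_index <- function(curve, beta = 0.5, gamma0 = 1e4) {
  stopifnot(all(c("tau", "g2") %in% names(curve)))
  y <- curve$g2 - 1
  keep <- y > 1e-12
  if (sum(keep) < 2) stop_config("extract_flow_index: curve has no decay to fit")
  fit <- stats::lm(log(y[keep] / beta) ~ 0 + curve$tau[keep])
  slope <- unname(stats::coef(fit)[1])
  if (slope >= 0) stop_config("extract_flow_index: non-decaying curve")
  -slope / (2 * gamma0)
}
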