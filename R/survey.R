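#' Build the en-face evoked-response survey video
#'
#' Reduces per-location stimulation trials to a coarse top-down movie of
#' relative flow change, used to locate the activation centroid before
#' committing to a single B-scan location. Four steps, per lateral
#' location:
#' \enumerate{
#'   \item average the angiogram frames over the repeated stimulus
#'     presentations;
#'   \item collapse each B-scan (`block_depth` x 250 px used) into a
#'     25-element vector by summing all pixel values in
#'     `block_width` x `block_depth` pixel blocks;
#'   \item normalize each time point's vector element-wise to the average
#'     of the first `n_baseline` vectors (pre-stimulus baseline);
#'   \item expand the coarse lateral axis from the number of locations to
#'     `n_out` samples by linear (or nearest-neighbor) interpolation.
#' }
#' Under the default protocol and a 10-location, 250-A-scan acquisition the
#' result is a 65-frame video of 25 x 25 pixel frames.
#'
#' @param stacks list over lateral locations; each element a list over
#'   presentations; each presentation a list of per-frame `angio_frame`s
#'   (or plain matrices) with at least `block_depth` rows and exactly
#'   `n_ascans` columns.
#' @param protocol an [make_protocol()] object.
#' @param n_ascans A-scans per B-scan (dense lateral axis).
#' @param block_width,block_depth accumulation block, pixels.
#' @param n_out output size of the coarse lateral axis.
#' @param interpolation `"linear"` or `"nearest"` for step 4.
#' @return object of class `survey_video`: array `frames` of dim
#'   `(n_frames, n_out, n_ascans / block_width)` in relative flow units
#'   (baseline frames average to 1 per pixel), plus grid provenance and
#'   `frame_period`.
#' @export
build_survey <- function(stacks, protocol, n_ascans = 250, block_width = 10,
                         block_depth = 100, n_out = 25,
                         interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  n_loc <- length(stacks)
  if (n_loc < 2) stop_config("build_survey: need >= 2 lateral locations")
  n_vec <- n_ascans / block_width
  if (n_vec != round(n_vec))
    stop_config("build_survey: n_ascans must be a multiple of block_width")
  nf <- protocol$n_frames
  nb <- protocol$n_baseline_frames

  reduced <- array(NA_real_, c(nf, n_loc, n_vec))
  for (L in seq_len(n_loc)) {
    pres <- stacks[[L]]
    if (!length(pres)) stop_config("build_survey: location %d has no presentations", L)
    for (t in seq_len(nf)) {
      # step 1: average over presentations
      acc <- NULL
      for (p in seq_along(pres)) {
        fr <- pres[[p]][[t]]
        v <- if (inherits(fr, "angio_frame")) fr$values else fr
        if (ncol(v) != n_ascans)
          stop_config("build_survey: location %d has %d A-scans, expected %d",
                      L, ncol(v), n_ascans)
        if (nrow(v) < block_depth)
          stop_config("build_survey: location %d is shallower than block_depth", L)
        acc <- if (is.null(acc)) v else acc + v
      }
      v <- acc / length(pres)
      # step 2: block accumulation to a 25-px vector
      v <- v[seq_len(block_depth), , drop = FALSE]
      grp <- rep(seq_len(n_vec), each = block_width)
      reduced[t, L, ] <- as.vector(rowsum(colSums(v), grp))
    }
  }
  # step 3: per-location, element-wise baseline normalization
  for (L in seq_len(n_loc)) {
    base <- colMeans(reduced[seq_len(nb), L, , drop = FALSE][, 1, ])
    if (any(base <= 0)) stop_config("build_survey: nonpositive baseline at location %d", L)
    reduced[, L, ] <- sweep(reduced[, L, , drop = FALSE][, , ], 2, base, "/")
  }
  # step 4: expand coarse axis to n_out
  xin <- seq(0, 1, length.out = n_loc)
  xout <- seq(0, 1, length.out = n_out)
  frames <- array(NA_real_, c(nf, n_out, n_vec))
  for (t in seq_len(nf)) for (j in seq_len(n_vec)) {
    frames[t, , j] <- if (interpolation == "linear") {
      stats::approx(xin, reduced[t, , j], xout = xout)$y
    } else {
      reduced[t, round(xout * (n_loc - 1)) + 1, j]
    }
  }
  structure(list(frames = frames,
                 grid = list(n_coarse_in = n_loc, n_coarse_out = n_out,
                             n_dense_out = n_vec,
                             block = c(width_px = block_width,
                                       depth_px = block_depth)),
                 frame_period = protocol$composite_frame_period,
                 interpolation = interpolation),
            class = "survey_video")
}

#' @export
print.survey_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("En-face survey video: %d frames of %d x %d px @ %.2f s/frame\n",
              d[1], d[2], d[3], x$frame_period))
  invisible(x)
}

#' Simulate a multi-location survey acquisition and build its video
#'
#' Convenience composition for the survey workflow: simulates
#' `n_locations` independent B-scan locations (each its own synthetic
#' scene) for `n_presentations` stimulation trials each, reduces every
#' frame to its angiogram, and assembles the en-face survey video. The
#' scene geometry defaults to the full B-scan focal region (250 A-scans,
#' 100-px depth at 4 um/px).
#'
#' @param protocol an [make_protocol()] object.
#' @param n_locations coarse lateral locations.
#' @param n_presentations stimulus presentations per location.
#' @param scene_args arguments forwarded to [make_scene()].
#' @param responses per-class ground-truth responses for the scenes.
#' @param seed master RNG seed.
#' @return a [build_survey()] result.
#' @export
simulate_survey <- function(protocol, n_locations = 10, n_presentations = 1,
                            scene_args = list(dim_px = c(100, 250)),
                            responses = list(), seed = 1) {
  seeds <- derive_seeds(seed, n_locations * (n_presentations + 1))
  si <- 0L
  stacks <- lapply(seq_len(n_locations), function(L) {
    si <<- si + 1L
    scene <- do.call(make_scene, c(scene_args,
                                   list(responses = responses, seed = seeds[si])))
    lapply(seq_len(n_presentations), function(p) {
      si <<- si + 1L
      simulate_trial_angiograms(protocol, scene, seed = seeds[si])$angiograms
    })
  })
  build_survey(stacks, protocol)
}

#' Locate the peak response pixel of a survey video
#'
#' Simple argmax helper: averages the survey frames over a time window and
#' returns the pixel with the largest relative flow change. Recording
#' locations are normally chosen by eye from the video; this is a
#' convenience only.
#'
#' @param survey a [build_survey()] object.
#' @param frames_window integer frame indices to average (default: frames
#'   after the baseline).
#' @return list with `pixel` (row, col) and `value`.
#' @export
survey_argmax <- function(survey, frames_window = NULL) {
  d <- dim(survey$frames)
  if (is.null(frames_window)) frames_window <- seq(10, min(d[1], 30))
  m <- apply(survey$frames[frames_window, , , drop = FALSE], c(2, 3), mean)
  i <- which.max(m)
  list(pixel = c(row = (i - 1) %% d[2] + 1, col = (i - 1) %/% d[2] + 1),
       value = max(m))
}
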