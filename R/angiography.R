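#' Reflectance frame from repeated B-scans
#'
#' Pixelwise mean of the magnitudes of all repeated B-scans at one lateral
#' location: the structural (static) image, against which flow contrast is
#' computed separately by [compute_angiogram()].
#'
#' @param series a [simulate_bscan_series()] object (or any list with a
#'   complex array `data` of dim depth x lateral x repeats and a `scale`).
#' @return object of class `angio_frame` (matrix `values` >= 0, `scale`,
#'   `frame_index`, `kind = "reflectance"`).
#' @export
compute_reflectance <- function(series) {
  d <- dim(series$data)
  if (is.null(d) || length(d) != 3 || d[3] < 1)
    stop_config("compute_reflectance: need a depth x lateral x repeats array")
  m <- Mod(series$data)
  vals <- rowMeans(m, dims = 2)
  angiogram_frame(vals, scale = series$scale,
                  frame_index = series$frame_index, n_repeats = d[3],
                  kind = "reflectance")
}

#' Angiogram frame from repeated B-scans (average absolute difference)
#'
#' Flow contrast is the average absolute difference of the magnitude of the
#' complex OCT signal across the repeated B-scans: for `N` repeats, the
#' pixelwise mean of `| |S_(i+1)| - |S_i| |` over the `N - 1` consecutive
#' pairs (default), or over all `N(N-1)/2` pairs with `pairs = "all"`.
#' Static tissue cancels; pixels whose speckle decorrelates between repeats
#' (flowing blood) light up. The value is a relative flow measure, not an
#' absolute velocity.
#'
#' @inheritParams compute_reflectance
#' @param pairs `"adjacent"` (default; standard in speckle-variance
#'   processing and O(N)) or `"all"`.
#' @return object of class `angio_frame` (matrix `values` >= 0, `scale`,
#'   `frame_index`, provenance fields `n_repeats`, `pairs`,
#'   `motion_corrected`).
#' @examples
#' p <- make_protocol()
#' sc <- make_scene(n_small = 2, n_medium = 1, n_large = 1, dim_px = c(32, 32))
#' s <- simulate_bscan_series(sc, repeats = 8, seed = 1)
#' a <- compute_angiogram(s)
#' range(a$values)
#' @export
compute_angiogram <- function(series, pairs = c("adjacent", "all")) {
  pairs <- match.arg(pairs)
  d <- dim(series$data)
  if (is.null(d) || length(d) != 3 || d[3] < 2)
    stop_config("compute_angiogram: need >= 2 repeats")
  m <- Mod(series$data)
  n <- d[3]
  if (pairs == "adjacent") {
    acc <- matrix(0, d[1], d[2])
    for (i in seq_len(n - 1)) acc <- acc + abs(m[, , i + 1] - m[, , i])
    vals <- acc / (n - 1)
  } else {
    acc <- matrix(0, d[1], d[2])
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      acc <- acc + abs(m[, , j] - m[, , i])
    vals <- acc / (n * (n - 1) / 2)
  }
  angiogram_frame(vals, scale = series$scale,
                  frame_index = series$frame_index, n_repeats = n,
                  pairs = pairs,
                  motion_corrected = isTRUE(series$motion_corrected))
}

#' Construct an angiogram/reflectance frame object
#'
#' @param values nonnegative numeric matrix (depth x lateral).
#' @param scale pixel scale, micrometers/pixel.
#' @param frame_index acquisition frame index.
#' @param n_repeats number of repeats the frame was computed from.
#' @param pairs differencing convention used (angiograms).
#' @param motion_corrected whether axial motion correction was applied.
#' @param roi depth interval retained, micrometers, or `NULL`.
#' @param kind `"angiogram"` or `"reflectance"`.
#' @return object of class `angio_frame`.
#' @export
angiogram_frame <- function(values, scale, frame_index = 1L, n_repeats = NA_integer_,
                            pairs = NA_character_, motion_corrected = FALSE,
                            roi = NULL, kind = "angiogram") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0)) stop_config("angiogram values must be >= 0")
  structure(list(values = values, scale = scale,
                 frame_index = as.integer(frame_index),
                 n_repeats = as.integer(n_repeats), pairs = pairs,
                 motion_corrected = motion_corrected, roi = roi, kind = kind),
            class = "angio_frame")
}

#' @export
print.angio_frame <- function(x, ...) {
  cat(sprintf("%s frame %d: %d x %d px @ %g um/px (from %s repeats%s)\n",
              x$kind, x$frame_index, nrow(x$values), ncol(x$values), x$scale,
              x$n_repeats, if (isTRUE(x$motion_corrected)) ", motion-corrected" else ""))
  invisible(x)
}

#' Axial motion correction of a repeated B-scan stack
#'
#' Estimates one axial (depth) shift per repeat by cross-correlating its
#' laterally averaged magnitude profile against the first repeat's, with
#' quadratic interpolation of the correlation peak for subpixel precision,
#' then realigns each repeat by linear interpolation along depth. A
#' simplified offline counterpart of real-time A-scan alignment; frame
#' dimensions never change and shifts are clamped to `max_shift` pixels.
#'
#' @inheritParams compute_reflectance
#' @param max_shift maximum |shift| searched, pixels.
#' @return the input series with `data` realigned, plus `shifts` (applied
#'   axial shifts in pixels, one per repeat) and `motion_corrected = TRUE`.
#' @export
axial_motion_correct <- function(series, max_shift = 10) {
  d <- dim(series$data)
  if (is.null(d) || length(d) != 3 || d[3] < 2)
    stop_config("axial_motion_correct: need >= 2 repeats")
  m <- Mod(series$data)
  ref <- rowMeans(m[, , 1, drop = FALSE], dims = 1)
  if (all(ref == 0)) {
    warning("reference repeat is all zero; no correction applied")
    series$shifts <- rep(0, d[3]); series$motion_corrected <- TRUE
    return(series)
  }
  ref <- ref - mean(ref)
  lags <- seq(-max_shift, max_shift)
  shifts <- numeric(d[3])
  out <- series$data
  zi <- seq_len(d[1])
  for (r in seq(2, d[3])) {
    prof <- rowMeans(m[, , r, drop = FALSE], dims = 1)
    if (all(prof == 0)) { warning("all-zero repeat; zero shift"); next }
    prof <- prof - mean(prof)
    cc <- vapply(lags, function(L) {
      if (L >= 0) sum(ref[seq_len(d[1] - L)] * prof[seq_len(d[1] - L) + L])
      else        sum(ref[seq_len(d[1] + L) - L] * prof[seq_len(d[1] + L)])
    }, 0)
    k <- which.max(cc)
    sh <- lags[k]
    if (k > 1 && k < length(lags)) {             # quadratic subpixel peak
      y1 <- cc[k - 1]; y2 <- cc[k]; y3 <- cc[k + 1]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > .Machine$double.eps) sh <- sh + 0.5 * (y1 - y3) / den
    }
    sh <- max(-max_shift, min(max_shift, sh))
    shifts[r] <- sh
    if (sh != 0) {
      src <- zi + sh                             # sample at shifted depth
      for (x in seq_len(d[2])) {
        out[, x, r] <- complex(
          real = stats::approx(zi, Re(series$data[, x, r]), xout = src, rule = 2)$y,
          imaginary = stats::approx(zi, Im(series$data[, x, r]), xout = src, rule = 2)$y)
      }
    }
  }
  series$data <- out
  series$shifts <- shifts
  series$motion_corrected <- TRUE
  series
}

#' Crop a frame to a depth region of interest
#'
#' Keeps the rows covering the half-open depth interval `[top, bottom)` in
#' micrometers from the frame top; `[0, 400)` at 4 um/px keeps 100 rows.
#'
#' @param frame an `angio_frame`.
#' @param depth_interval numeric length-2, micrometers.
#' @return the cropped `angio_frame` with `roi` recorded.
#' @export
crop_roi <- function(frame, depth_interval) {
  stopifnot(inherits(frame, "angio_frame"), length(depth_interval) == 2)
  top <- depth_interval[1]; bottom <- depth_interval[2]
  if (top < 0 || bottom <= top)
    stop_config("crop_roi: need 0 <= top < bottom")
  depth_um <- nrow(frame$values) * frame$scale
  if (bottom > depth_um)
    stop_config("crop_roi: interval [%g, %g) exceeds frame depth %g um",
                top, bottom, depth_um)
  rows <- seq(floor(top / frame$scale) + 1,
              floor(top / frame$scale) + round((bottom - top) / frame$scale))
  if (max(rows) > nrow(frame$values))
    stop_config("crop_roi: interval not representable on the pixel grid")
  frame$values <- frame$values[rows, , drop = FALSE]
  frame$roi <- c(top, bottom)
  frame
}
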