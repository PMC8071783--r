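#' Multilevel Otsu thresholds of an angiogram frame
#'
#' Computes the `n_classes - 1` thresholds that maximize the between-class
#' variance of the frame's intensity histogram (256 bins by default),
#' searched exhaustively over all threshold combinations (vectorized over
#' the last threshold). With `n_classes = 3` this separates the angiogram
#' into background / dim vessels / bright vessels.
#'
#' @param frame an `angio_frame`, or a numeric matrix/vector of intensities.
#' @param n_classes number of intensity classes (2 or 3).
#' @param n_bins histogram bins.
#' @return numeric vector of `n_classes - 1` thresholds (bin upper edges),
#'   increasing.
#' @export
otsu_multithreshold <- function(frame, n_classes = 3, n_bins = 256) {
  v <- if (inherits(frame, "angio_frame")) as.vector(frame$values) else as.vector(frame)
  v <- v[is.finite(v)]
  if (length(unique(v)) < n_classes)
    stop_config("otsu_multithreshold: frame has fewer than %d distinct values",
                n_classes)
  if (!n_classes %in% c(2, 3))
    stop_config("otsu_multithreshold: n_classes must be 2 or 3")
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                     n_bins), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  P <- cumsum(p)                      # class probability up to bin k
  S <- cumsum(p * mids)               # first moment up to bin k
  # between-class variance of the span (a, b]: omega * mu^2 contribution
  contrib <- function(a, b) {         # a, b are bin indices, a < b; span (a, b]
    w <- P[b] - if (a >= 1) P[a] else 0
    s <- S[b] - if (a >= 1) S[a] else 0
    ifelse(w > 0, s^2 / w, 0)
  }
  # empty histogram spans make the criterion flat; break ties at the
  # plateau midpoint so thresholds land mid-gap between classes
  if (n_classes == 2) {
    k <- seq_len(n_bins - 1)
    bcv <- contrib(0, k) + vapply(k, function(kk) contrib(kk, n_bins), 0)
    tied <- which(bcv >= max(bcv) - 1e-12 * abs(max(bcv)))
    return(edges[round(mean(range(tied))) + 1])
  }
  bcv_row <- function(k1) {
    k2 <- seq(k1 + 1, n_bins - 1)
    w2 <- P[k2] - P[k1]; s2 <- S[k2] - S[k1]
    w3 <- P[n_bins] - P[k2]; s3 <- S[n_bins] - S[k2]
    contrib(0, k1) + ifelse(w2 > 0, s2^2 / w2, 0) + ifelse(w3 > 0, s3^2 / w3, 0)
  }
  rows <- lapply(seq_len(n_bins - 2), bcv_row)
  best <- max(unlist(lapply(rows, max)))
  tol <- 1e-12 * abs(best)
  tied <- do.call(rbind, lapply(seq_len(n_bins - 2), function(k1) {
    hit <- which(rows[[k1]] >= best - tol)
    if (length(hit)) cbind(k1 = k1, k2 = k1 + hit) else NULL
  }))
  centroid <- colMeans(tied)
  pick <- tied[which.min((tied[, 1] - centroid[1])^2 +
                           (tied[, 2] - centroid[2])^2), ]
  unname(edges[pick + 1])
}

#' 8-connected component labeling of a binary matrix
#'
#' Flood-fill labeling with 8-connectivity in the B-scan plane (diagonal
#' neighbors connect).
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask != 0)
  cur <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      px <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- (px - 1L) %% nr + 1L
      c <- (px - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] != 0 && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' Segment an angiogram into vessel-diameter classes
#'
#' Implements diameter-resolved vessel segmentation of a (typically
#' time-averaged baseline) angiogram frame:
#' \enumerate{
#'   \item 3-class Otsu thresholds are computed on the frame.
#'   \item Pixels above the upper threshold form candidate vessel cores;
#'     8-connected components are extracted and sized by their
#'     equivalent-circle diameter `d = 2 * sqrt(area_px * scale^2 / pi)`.
#'     Components with `bins[1] <= d <= bins[2]` um become the medium mask,
#'     `d > bins[2]` the large mask.
#'   \item Remaining pixels with non-zero flow - above the lower Otsu
#'     threshold, a noise-floor gate - and outside the medium/large masks
#'     become the small (< `bins[1]` um) mask; sub-resolution vessels are
#'     not individually resolvable, so the small class is a pixel mask, not
#'     a component list.
#' }
#' The three masks are pairwise disjoint by construction.
#'
#' @param frame an `angio_frame` (the ROI-cropped, baseline-averaged
#'   angiogram).
#' @param diameter_bins class edges in micrometers, default `c(10, 20)`.
#' @return object of class `vessel_masks`: logical matrices `small`,
#'   `medium`, `large`; `components` data frame (label, class,
#'   equivalent_diameter_um, pixel_count, centroid row/col); `thresholds`
#'   (the two Otsu levels); `scale`.
#' @export
segment_vessels <- function(frame, diameter_bins = c(10, 20)) {
  stopifnot(inherits(frame, "angio_frame"), length(diameter_bins) == 2)
  v <- frame$values
  if (all(v == v[1])) {
    warning("constant frame: empty mask set")
    empty <- matrix(FALSE, nrow(v), ncol(v))
    return(structure(list(small = empty, medium = empty, large = empty,
                          components = empty_components(), thresholds = c(NA, NA),
                          scale = frame$scale), class = "vessel_masks"))
  }
  th <- otsu_multithreshold(frame, n_classes = 3)
  core <- v > th[2]
  lab <- label_components(core)
  n_comp <- max(lab)
  medium <- matrix(FALSE, nrow(v), ncol(v))
  large <- matrix(FALSE, nrow(v), ncol(v))
  comps <- empty_components()
  if (n_comp > 0) {
    for (k in seq_len(n_comp)) {
      px <- which(lab == k)
      area <- length(px)
      d_eq <- 2 * sqrt(area * frame$scale^2 / pi)
      cls <- diameter_class(d_eq)
      rows <- (px - 1) %% nrow(v) + 1
      cols <- (px - 1) %/% nrow(v) + 1
      comps <- rbind(comps, data.frame(
        label = k, class = cls, equivalent_diameter_um = d_eq,
        pixel_count = area, centroid_row = mean(rows), centroid_col = mean(cols)))
      if (d_eq >= diameter_bins[1] && d_eq <= diameter_bins[2]) medium[px] <- TRUE
      else if (d_eq > diameter_bins[2]) large[px] <- TRUE
      # cores below the small edge fall through to the small mask
    }
  }
  small <- (v > th[1]) & !medium & !large
  if (!any(small | medium | large)) warning("no suprathreshold pixels: empty mask set")
  structure(list(small = small, medium = medium, large = large,
                 components = comps, thresholds = th, scale = frame$scale),
            class = "vessel_masks")
}

empty_components <- function() {
  data.frame(label = integer(), class = character(),
             equivalent_diameter_um = numeric(), pixel_count = integer(),
             centroid_row = numeric(), centroid_col = numeric())
}

#' @export
print.vessel_masks <- function(x, ...) {
  cat(sprintf("Vessel masks (%g um/px): small %d px, medium %d px, large %d px\n",
              x$scale, sum(x$small), sum(x$medium), sum(x$large)))
  cat(sprintf("  Otsu thresholds: %.4g, %.4g; %d core components\n",
              x$thresholds[1], x$thresholds[2], nrow(x$components)))
  invisible(x)
}

#' Sum angiogram signal inside each class mask, per frame
#'
#' For each diameter class and each frame, sums the gray-scale angiogram
#' values over the class's pixel mask: the raw (un-normalized) flow signal
#' per class.
#'
#' @param frames a list of `angio_frame` objects sharing the masks' geometry.
#' @param masks a [segment_vessels()] object.
#' @return numeric matrix `length(frames)` x 3 with columns
#'   `small`, `medium`, `large`.
#' @export
apply_masks <- function(frames, masks) {
  stopifnot(inherits(masks, "vessel_masks"))
  if (inherits(frames, "angio_frame")) frames <- list(frames)
  out <- matrix(NA_real_, length(frames), 3,
                dimnames = list(NULL, c("small", "medium", "large")))
  for (i in seq_along(frames)) {
    v <- frames[[i]]$values
    if (!all(dim(v) == dim(masks$small)))
      stop_config("apply_masks: frame %d geometry does not match masks", i)
    out[i, ] <- c(sum(v[masks$small]), sum(v[masks$medium]), sum(v[masks$large]))
  }
  out
}
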