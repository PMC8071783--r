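#' Specify a vessel cross-section in a synthetic B-scan scene
#'
#' A vessel appears in the B-scan plane as a filled disk of the given
#' diameter whose pixels decorrelate between repeated B-scans at a rate
#' proportional to the instantaneous flow. `baseline_decorrelation` scales
#' that contrast (dimensionless, in \[0, 1\]); larger vessels carry faster
#' flow, so class defaults increase with diameter.
#'
#' @param center numeric length-2, (depth, lateral) in micrometers.
#' @param diameter vessel diameter in micrometers.
#' @param baseline_decorrelation contrast scale in \[0, 1\].
#' @param response an [hrf_design()] object giving this vessel's
#'   ground-truth fractional flow response, or `NULL` for no response.
#' @return object of class `vessel_spec`; `class_truth` is assigned by the
#'   diameter binning rule (small < 10, medium 10-20, large > 20 um).
#' @export
vessel_spec <- function(center, diameter, baseline_decorrelation = NULL,
                        response = NULL) {
  stopifnot(length(center) == 2, is.numeric(center), is_number(diameter),
            diameter > 0)
  cls <- diameter_class(diameter)
  if (is.null(baseline_decorrelation))
    baseline_decorrelation <- c(small = 0.45, medium = 0.8, large = 1.0)[[cls]]
  stopifnot(baseline_decorrelation >= 0, baseline_decorrelation <= 1)
  if (!is.null(response) && !inherits(response, "hrf_params"))
    stop_config("vessel_spec: response must be an 'hrf_params' or NULL")
  structure(list(center = as.numeric(center), diameter = diameter,
                 class_truth = cls,
                 baseline_decorrelation = baseline_decorrelation,
                 response = response),
            class = "vessel_spec")
}

#' Diameter class binning rule
#'
#' Small: d < 10 um; medium: 10 <= d <= 20 um; large: d > 20 um.
#'
#' @param d diameters in micrometers.
#' @return character vector in `c("small", "medium", "large")`.
#' @export
diameter_class <- function(d) {
  ifelse(d < 10, "small", ifelse(d <= 20, "medium", "large"))
}

# Pixel indices (matrix row/col) covered by a disk. Pixel centers sit at
# (i - 1/2) * scale; a pixel belongs to the disk when its center is strictly
# inside the radius, so an 8-um disk at 4 um/px is a single pixel.
rasterize_disk <- function(center, diameter, dim_px, scale) {
  r <- diameter / 2
  zc <- center[1]; xc <- center[2]
  zi <- seq(max(1, floor((zc - r) / scale)), min(dim_px[1], ceiling((zc + r) / scale) + 1))
  xi <- seq(max(1, floor((xc - r) / scale)), min(dim_px[2], ceiling((xc + r) / scale) + 1))
  g <- expand.grid(z = zi, x = xi)
  pz <- (g$z - 0.5) * scale; px <- (g$x - 0.5) * scale
  keep <- (pz - zc)^2 + (px - xc)^2 < r^2
  cbind(z = g$z[keep], x = g$x[keep])
}

#' Build a synthetic B-scan scene
#'
#' Constructs the static content of a synthetic cross-sectional field of
#' view: a fixed speckle parenchyma (zero-mean complex Gaussian field, so
#' magnitudes are Rayleigh) with embedded vessel cross-sections whose
#' repeat-to-repeat decorrelation encodes flow. Vessel cross-sections are
#' placed on a non-overlapping cell lattice with their class assignment
#' shuffled by `seed`, guaranteeing at least one background pixel between
#' any two vessels (so 8-connected components never merge).
#'
#' @param n_small,n_medium,n_large number of vessel cross-sections per
#'   diameter class.
#' @param d_small,d_medium,d_large class diameters in micrometers.
#' @param dim_px field size `(depth_px, lateral_px)`.
#' @param scale pixel scale in micrometers/pixel (both axes).
#' @param parenchyma_noise_sd per-component standard deviation of the static
#'   speckle field.
#' @param detector_noise_sd per-component standard deviation of the additive
#'   complex detector noise drawn fresh at every repeat.
#' @param vessel_brightness static magnitude of vessel pixels.
#' @param flow_contrast_scale magnitude-fluctuation sd per unit
#'   (`baseline_decorrelation` x flow).
#' @param responses named list of `hrf_params` (names among
#'   `small`, `medium`, `large`) giving each class's ground-truth response;
#'   classes absent from the list have none.
#' @param seed RNG seed for placement and the static field.
#' @return object of class `scene_config` with fields `vessels` (list of
#'   [vessel_spec()]), `static_field` (complex matrix), `vessel_px` (index
#'   list per vessel), `dim_px`, `scale`, and the noise parameters.
#' @export
make_scene <- function(n_small = 160, n_medium = 24, n_large = 14,
                       d_small = 8, d_medium = 16, d_large = 28,
                       dim_px = c(80, 176), scale = 4,
                       parenchyma_noise_sd = 0.2, detector_noise_sd = 0.02,
                       vessel_brightness = 1, flow_contrast_scale = 0.25,
                       responses = list(), seed = 1) {
  stopifnot(parenchyma_noise_sd >= 0, detector_noise_sd >= 0,
            flow_contrast_scale >= 0, length(dim_px) == 2)
  dim_px <- as.integer(dim_px)
  n_total <- n_small + n_medium + n_large
  cell <- max(8, ceiling(d_large / scale) + 1)     # px per lattice cell
  nz <- dim_px[1] %/% cell; nx <- dim_px[2] %/% cell
  if (nz * nx < n_total)
    stop_config("scene field too small for %d vessels (%d lattice cells)",
                n_total, nz * nx)
  bad <- setdiff(names(responses), c("small", "medium", "large"))
  if (length(bad)) stop_config("unknown response class(es): %s", paste(bad, collapse = ", "))

  with_seed(seed, {
    cells <- sample.int(nz * nx, n_total)
    classes <- c(rep("small", n_small), rep("medium", n_medium),
                 rep("large", n_large))
    diam <- c(small = d_small, medium = d_medium, large = d_large)
    vessels <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      cz <- ((cells[i] - 1) %% nz)
      cx <- ((cells[i] - 1) %/% nz)
      center <- c((cz * cell + cell / 2) * scale, (cx * cell + cell / 2) * scale)
      vessels[[i]] <- vessel_spec(center, diam[[classes[i]]],
                                  response = responses[[classes[i]]])
    }
    field <- matrix(complex(
      real = stats::rnorm(prod(dim_px), 0, parenchyma_noise_sd),
      imaginary = stats::rnorm(prod(dim_px), 0, parenchyma_noise_sd)),
      dim_px[1], dim_px[2])
    vessel_px <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      px <- rasterize_disk(vessels[[i]]$center, vessels[[i]]$diameter,
                           dim_px, scale)
      if (nrow(px) == 0)
        stop_config("vessel %d rasterizes to zero pixels", i)
      phases <- stats::runif(nrow(px), 0, 2 * pi)
      field[px] <- vessel_brightness * exp(1i * phases)
      vessel_px[[i]] <- list(idx = px, phase = phases)
    }
  })
  structure(list(vessels = vessels, static_field = field,
                 vessel_px = vessel_px, dim_px = dim_px, scale = scale,
                 parenchyma_noise_sd = parenchyma_noise_sd,
                 detector_noise_sd = detector_noise_sd,
                 vessel_brightness = vessel_brightness,
                 flow_contrast_scale = flow_contrast_scale, seed = seed),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cls <- table(vapply(x$vessels, `[[`, "", "class_truth"))
  cat(sprintf("Synthetic B-scan scene: %d x %d px @ %g um/px\n",
              x$dim_px[1], x$dim_px[2], x$scale))
  cat("  vessels:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat(sprintf("  noise: parenchyma %g, detector %g; contrast scale %g\n",
              x$parenchyma_noise_sd, x$detector_noise_sd,
              x$flow_contrast_scale))
  invisible(x)
}

#' Ground-truth vessel classes as a label image
#'
#' @param scene a [make_scene()] object.
#' @return integer matrix: 0 background, 1 small, 2 medium, 3 large.
#' @export
scene_truth_mask <- function(scene) {
  lab <- matrix(0L, scene$dim_px[1], scene$dim_px[2])
  code <- c(small = 1L, medium = 2L, large = 3L)
  for (i in seq_along(scene$vessels))
    lab[scene$vessel_px[[i]]$idx] <- code[[scene$vessels[[i]]$class_truth]]
  lab
}
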