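#' Read and write flow waveforms as tidy CSV
#'
#' Columns: `modality`, `vessel_class`, `current_mA`, `time_s`, `rel_flow`,
#' `sem` (empty when absent).
#'
#' @param waveform a `flow_waveform`.
#' @param path CSV file path.
#' @return `write_waveform_csv`: the path, invisibly;
#'   `read_waveform_csv`: a `flow_waveform`.
#' @export
write_waveform_csv <- function(waveform, path) {
  df <- data.frame(modality = waveform$modality,
                   vessel_class = waveform$vessel_class,
                   current_mA = waveform$current_mA,
                   time_s = waveform$times, rel_flow = waveform$values,
                   sem = if (is.null(waveform$sem)) NA_real_ else waveform$sem)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "rel_flow")
  if (!all(need %in% names(df)))
    stop_config("waveform CSV %s lacks columns %s", path,
                paste(setdiff(need, names(df)), collapse = ", "))
  flow_waveform(df$time_s, df$rel_flow,
                modality = if ("modality" %in% names(df)) df$modality[1] else "OCT-A",
                vessel_class = if ("vessel_class" %in% names(df)) df$vessel_class[1] else NA,
                current_mA = if ("current_mA" %in% names(df)) df$current_mA[1] else NA,
                sem = if ("sem" %in% names(df) && any(is.finite(df$sem))) df$sem else NULL)
}

#' Write and read a complex B-scan stack
#'
#' The complex stack is stored losslessly at complex64 precision as a pair
#' of float32 multi-page TIFFs (real and imaginary parts, one page per
#' repeat) plus a JSON sidecar holding the pixel scale and indices.
#' `write_stack_tiff()` additionally exports magnitudes only (documented as
#' lossy: phase is discarded).
#'
#' @param series a [simulate_bscan_series()] object.
#' @param path base path; `<path>_re.tif`, `<path>_im.tif` and
#'   `<path>.json` are created.
#' @return `write_stack`: the base path, invisibly; `read_stack`: a
#'   `bscan_series`.
#' @export
write_stack <- function(series, path) {
  d <- dim(series$data)
  # the tiff writer stores [0, 1]; affine-code each part and keep the
  # offset/gain in the sidecar (float32 precision, like complex64 storage)
  enc <- function(part) {
    lo <- min(part); hi <- max(part)
    gain <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[3]), function(r) (part[, , r] - lo) / gain)
    list(pages = pages, offset = lo, gain = gain)
  }
  re <- enc(Re(series$data)); im <- enc(Im(series$data))
  tiff::writeTIFF(re$pages, paste0(path, "_re.tif"), bits.per.sample = 32L,
                  reduce = FALSE)
  tiff::writeTIFF(im$pages, paste0(path, "_im.tif"), bits.per.sample = 32L,
                  reduce = FALSE)
  meta <- list(dim = d, scale = series$scale,
               frame_index = series$frame_index,
               lateral_location_index = series$lateral_location_index,
               axes = "depth x lateral x repeat", dtype = "complex64",
               re_offset = re$offset, re_gain = re$gain,
               im_offset = im$offset, im_gain = im$gain)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  jpath <- paste0(path, ".json")
  if (!file.exists(jpath)) stop_config("missing stack sidecar %s", jpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  re <- tiff::readTIFF(paste0(path, "_re.tif"), all = TRUE, as.is = FALSE)
  im <- tiff::readTIFF(paste0(path, "_im.tif"), all = TRUE, as.is = FALSE)
  if (length(re) != meta$dim[3] || length(im) != meta$dim[3])
    stop_config("stack %s: expected %d pages, found %d/%d (truncated file?)",
                path, meta$dim[3], length(re), length(im))
  data <- array(complex(1), dim = meta$dim)
  for (r in seq_len(meta$dim[3])) {
    if (!all(dim(re[[r]]) == meta$dim[1:2]))
      stop_config("stack %s: page %d has wrong shape", path, r)
    data[, , r] <- complex(
      real = re[[r]] * meta$re_gain + meta$re_offset,
      imaginary = im[[r]] * meta$im_gain + meta$im_offset)
  }
  structure(list(data = data, scale = meta$scale,
                 frame_index = meta$frame_index,
                 lateral_location_index = meta$lateral_location_index),
            class = "bscan_series")
}

#' @rdname write_stack
#' @export
write_stack_tiff <- function(series, path) {
  d <- dim(series$data)
  pages <- lapply(seq_len(d[3]), function(r) Mod(series$data[, , r]))
  mx <- max(unlist(pages), 1e-12)
  tiff::writeTIFF(lapply(pages, `/`, mx), path, bits.per.sample = 32L)
  invisible(path)
}

#' Read and validate an experiment configuration from YAML
#'
#' Schema-checked front end to [experiment_config()]: recognized top-level
#' keys are `n_animals`, `currents`, `protocol`, `scene`, `dcs_noise_sd`,
#' `seed`; unknown keys are rejected. Ground-truth responses are rebuilt
#' from the defaults for the listed currents.
#'
#' @param path YAML file.
#' @return an [experiment_config()] object.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_animals", "currents", "protocol", "scene", "dcs_noise_sd", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_config("unknown config key(s): %s", paste(bad, collapse = ", "))
  experiment_config(
    n_animals = cfg$n_animals %||% 11,
    currents = cfg$currents %||% 1,
    protocol_overrides = cfg$protocol %||% list(),
    scene_args = cfg$scene %||% list(),
    dcs_noise_sd = cfg$dcs_noise_sd %||% 0.015,
    seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
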