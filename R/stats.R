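#' Pearson correlation between two flow waveforms
#'
#' Sample Pearson correlation over the full acquisition on a common time
#' grid. Waveforms on different grids must first be aligned with
#' [resample_to_grid()] (convention: the finer DCS grid is resampled onto
#' the coarser composite-frame grid).
#'
#' @param w1,w2 `flow_waveform`s on identical grids (or plain numeric
#'   vectors of equal length).
#' @return the correlation coefficient.
#' @export
pearson_r <- function(w1, w2) {
  v1 <- if (inherits(w1, "flow_waveform")) w1$values else as.numeric(w1)
  v2 <- if (inherits(w2, "flow_waveform")) w2$values else as.numeric(w2)
  if (inherits(w1, "flow_waveform") && inherits(w2, "flow_waveform")) {
    if (length(w1$times) != length(w2$times) ||
        any(abs(w1$times - w2$times) > 1e-9))
      stop_config("pearson_r: waveforms are not on a common time grid")
  }
  if (length(v1) != length(v2) || length(v1) < 3)
    stop_config("pearson_r: need >= 3 paired samples")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop_config("pearson_r: zero variance, correlation undefined")
  stats::cor(v1, v2)
}

#' Noise level giving a prescribed population correlation
#'
#' For a pair built as `w2 = w1 + noise` with i.i.d. Gaussian noise, the
#' population Pearson correlation against the fixed signal `w1` is
#' `rho = 1 / sqrt(1 + sigma^2 / var(w1))`; inverting gives the noise SD
#' that realizes a target `rho`. If the noise is added on a finer grid and
#' then linearly interpolated onto the analysis grid, interpolation shrinks
#' its variance by a computable factor, which is corrected for when both
#' grids are supplied.
#'
#' @param signal the shared signal on the analysis grid (numeric or
#'   `flow_waveform`).
#' @param rho target population correlation in (0, 1).
#' @param noise_times,target_times optional: times at which the noise is
#'   added and the analysis grid it is interpolated onto; when given, the
#'   returned SD is inflated so the post-interpolation variance matches.
#' @return the noise standard deviation.
#' @export
calibrate_noise_for_r <- function(signal, rho, noise_times = NULL,
                                  target_times = NULL) {
  stopifnot(rho > 0, rho < 1)
  v <- if (inherits(signal, "flow_waveform")) signal$values else as.numeric(signal)
  s2 <- stats::var(v)
  sigma2 <- s2 * (1 / rho^2 - 1)
  if (!is.null(noise_times) && !is.null(target_times)) {
    i <- findInterval(target_times, noise_times,
                      rightmost.closed = TRUE, all.inside = TRUE)
    lam <- (target_times - noise_times[i]) / diff(noise_times)[pmin(i, length(noise_times) - 1)]
    shrink <- mean((1 - lam)^2 + lam^2)
    sigma2 <- sigma2 / shrink
  }
  sqrt(sigma2)
}

#' Simulate DCS/OCT-A waveform pairs with a prescribed population correlation
#'
#' Builds repeated waveform pairs sharing one evoked signal: the OCT-A
#' small-class waveform is the noiseless response on the composite-frame
#' grid, and each paired DCS waveform is the same signal sampled at the DCS
#' rate plus i.i.d. noise whose variance is calibrated (including the
#' shrink from resampling, see [calibrate_noise_for_r()]) so the population
#' Pearson correlation on the common 65-point grid equals `rho`. Returns
#' the sample correlations, whose mean estimates `rho` up to the small-n
#' bias of the sample correlation coefficient.
#'
#' @param n_pairs number of simulated pairs.
#' @param rho target population correlation.
#' @param response the shared ground-truth response ([hrf_design()]).
#' @param protocol an [make_protocol()] object.
#' @param seed master RNG seed.
#' @return numeric vector of `n_pairs` sample correlations.
#' @export
simulate_correlation_pairs <- function(n_pairs, rho,
                                       response = NULL,
                                       protocol = make_protocol(), seed = 1) {
  if (is.null(response)) response <- default_class_responses(4)[["4"]]$small
  ft <- frame_times(protocol)
  w1 <- resample_to_grid(simulate_dcs_waveform(protocol, response,
                                               noise_sd = 0), ft)
  w1$modality <- "OCT-A"; w1$vessel_class <- "small"
  sigma <- calibrate_noise_for_r(w1, rho, noise_times = dcs_times(protocol),
                                 target_times = ft)
  seeds <- derive_seeds(seed, n_pairs)
  vapply(seeds, function(s) {
    dcs <- simulate_dcs_waveform(protocol, response, noise_sd = sigma,
                                 seed = s)
    pearson_r(resample_to_grid(dcs, ft), w1)
  }, 0)
}

#' Group-level summary and significance tests for a metric
#'
#' Aggregates a per-animal metric across conditions: mean, sample SD
#' (n - 1), a one-sample Kolmogorov-Smirnov normality p-value on the
#' standardized values, and two-tailed Student's t-tests of every condition
#' against a reference condition (default the lowest stimulus current).
#' Tests are paired when the same animals appear in both conditions
#' (within-animal design) unless `paired = FALSE`.
#'
#' @param metrics data frame with columns `animal`, `condition`, `value`.
#' @param reference the reference condition; default the first level.
#' @param paired use paired t-tests where animals match.
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @return object of class `group_summary`: a data frame with one row per
#'   condition (mean, sd, n, normality_p, t_statistic, p_value vs
#'   reference).
#' @export
group_aggregate <- function(metrics, reference = NULL, paired = TRUE,
                            p_adjust = "none") {
  stopifnot(all(c("animal", "condition", "value") %in% names(metrics)))
  metrics <- metrics[is.finite(metrics$value), ]
  conds <- unique(metrics$condition)
  if (is.null(reference)) reference <- conds[1]
  if (!reference %in% conds) stop_config("reference condition '%s' absent", reference)
  rows <- lapply(conds, function(cd) {
    x <- metrics[metrics$condition == cd, ]
    if (nrow(x) < 2) stop_config("condition '%s' has fewer than 2 animals", cd)
    m <- mean(x$value); s <- stats::sd(x$value)
    norm_p <- if (s > 0)
      suppressWarnings(stats::ks.test((x$value - m) / s, "pnorm")$p.value)
    else NA_real_
    tstat <- NA_real_; pval <- NA_real_; degenerate <- FALSE
    if (cd != reference) {
      ref <- metrics[metrics$condition == reference, ]
      common <- intersect(x$animal, ref$animal)
      if (paired && length(common) >= 2) {
        a <- x$value[match(common, x$animal)]
        b <- ref$value[match(common, ref$animal)]
        if (stats::sd(a - b) == 0) degenerate <- TRUE
        else { tt <- stats::t.test(a, b, paired = TRUE); tstat <- unname(tt$statistic); pval <- tt$p.value }
      } else {
        if (stats::sd(x$value) == 0 && stats::sd(ref$value) == 0) degenerate <- TRUE
        else { tt <- stats::t.test(x$value, ref$value); tstat <- unname(tt$statistic); pval <- tt$p.value }
      }
    }
    data.frame(condition = cd, mean = m, sd = s, n_animals = nrow(x),
               normality_p = norm_p, t_statistic = tstat, p_value = pval,
               degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  attr(out, "reference") <- reference
  class(out) <- c("group_summary", class(out))
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group summary (two-tailed t-tests vs '%s'):\n",
              attr(x, "reference")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
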