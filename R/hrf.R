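#' Evaluate the double-gamma hemodynamic response function
#'
#' The canonical biphasic flow response is modeled as a scaled difference of
#' two gamma probability densities,
#' \deqn{HRF(t) = A\left(\frac{t^{\alpha_1-1}\beta_1^{\alpha_1}e^{-\beta_1 t}}
#'   {\Gamma(\alpha_1)} - c\,\frac{t^{\alpha_2-1}\beta_2^{\alpha_2}e^{-\beta_2 t}}
#'   {\Gamma(\alpha_2)}\right),}
#' where `A` sets the amplitude, `c` the peak-to-undershoot ratio, and the
#' shape (`alpha`, dimensionless) and rate (`beta`, 1/s) pairs set the
#' latency and width of the positive lobe and the undershoot. For
#' `alpha > 1` the curve starts at zero and decays back to zero.
#'
#' @param params named list or vector with elements `A`, `c`, `alpha1`,
#'   `alpha2`, `beta1`, `beta2`.
#' @param t times in seconds (relative to stimulus onset), `t >= 0`.
#' @return numeric vector of HRF values (same units as `A` per second).
#' @examples
#' # with c = 0 the curve is A times a gamma density: peaks at (alpha-1)/beta
#' hrf_eval(list(A = 1, c = 0, alpha1 = 2, alpha2 = 8, beta1 = 1, beta2 = 1), 1)
#' @export
hrf_eval <- function(params, t) {
  p <- as.list(params)
  for (f in c("A", "c", "alpha1", "alpha2", "beta1", "beta2"))
    if (!is_number(p[[f]])) stop_config("hrf_eval: missing or non-finite parameter '%s'", f)
  if (p$alpha1 <= 0 || p$alpha2 <= 0 || p$beta1 <= 0 || p$beta2 <= 0)
    stop_config("hrf_eval: alpha and beta parameters must be positive")
  if (any(t < 0)) stop_config("hrf_eval: t must be >= 0")
  p$A * (stats::dgamma(t, shape = p$alpha1, rate = p$beta1) -
           p$c * stats::dgamma(t, shape = p$alpha2, rate = p$beta2))
}

#' Design a ground-truth double-gamma response with prescribed extrema
#'
#' Solves for double-gamma parameters whose dense-grid maximum equals
#' `peak`, whose minimum equals `-undershoot`, and whose extremum times
#' equal `t_peak` and `t_under` (seconds post-stimulus). Used by the
#' synthetic generator so that a simulated vessel class or DCS channel has a
#' known fractional flow response. The solve alternates (i) rescaling the
#' gamma rates so the extremum times land on target with (ii) a 1-D root
#' solve for the undershoot ratio `c` and an exact rescale of `A`.
#'
#' @param peak positive peak of the curve (fractional flow change, e.g.
#'   0.0219 for a 2.19% peak).
#' @param undershoot magnitude of the negative extremum (same units);
#'   0 gives a monophasic response (`c = 0`).
#' @param t_peak,t_under target extremum times, seconds post-stimulus.
#' @param alpha1,alpha2 gamma shapes controlling lobe widths.
#' @param t_max,dt grid used for dense evaluation.
#' @return object of class `hrf_params`: the six coefficients plus
#'   `peak_fraction` (= `peak`, enforced by construction).
#' @export
hrf_design <- function(peak, undershoot = 0, t_peak = 7.3, t_under = 15,
                       alpha1 = 6, alpha2 = 12, t_max = 25, dt = 0.001) {
  stopifnot(is_number(peak), peak > 0, is_number(undershoot), undershoot >= 0,
            t_peak > 0, t_under > t_peak)
  tg <- seq(0, t_max, by = dt)
  b1 <- (alpha1 - 1) / t_peak
  b2 <- (alpha2 - 1) / t_under
  cc <- 0
  for (iter in 1:25) {
    g1 <- stats::dgamma(tg, alpha1, rate = b1)
    g2 <- stats::dgamma(tg, alpha2, rate = b2)
    if (undershoot > 0) {
      ratio_gap <- function(c0) {
        cv <- g1 - c0 * g2
        -min(cv) / max(cv) - undershoot / peak
      }
      hi <- 1
      while (ratio_gap(hi) < 0 && hi < 1e4) hi <- hi * 2
      cc <- stats::uniroot(ratio_gap, c(0, hi), tol = 1e-12)$root
    }
    cv <- g1 - cc * g2
    tp_hat <- tg[which.max(cv)]
    tu_hat <- if (undershoot > 0) tg[which.min(cv)] else t_under
    if (abs(tp_hat - t_peak) < dt && abs(tu_hat - t_under) < dt) break
    b1 <- b1 * tp_hat / t_peak
    if (undershoot > 0) b2 <- b2 * tu_hat / t_under
  }
  A <- peak / max(cv)
  structure(list(A = A, c = cc, alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = b1, beta2 = b2, peak_fraction = peak),
            class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf(
    "double-gamma response: A=%.4g c=%.3g alpha=(%.3g, %.3g) beta=(%.3g, %.3g) peak=%.4g\n",
    x$A, x$c, x$alpha1, x$alpha2, x$beta1, x$beta2, x$peak_fraction))
  invisible(x)
}

# default multi-start grid for the double-gamma fit (amplitude filled in
# from the data); double-gamma least squares is multimodal.
hrf_start_grid <- function() {
  g <- expand.grid(alpha1 = c(3, 6), alpha2 = c(8, 12), c = c(0.2, 0.8))
  g$beta1 <- 1; g$beta2 <- 1
  g
}

#' Fit the double-gamma hemodynamic response to an evoked waveform
#'
#' Least-squares fit of the double-gamma response to the post-onset segment
#' of a relative-flow waveform. The waveform is baseline-subtracted and
#' expressed in percent (`(value - 1) * 100`) with time re-referenced to
#' stimulus onset, then fit with the Levenberg-Marquardt algorithm
#' (minpack.lm) from a small multi-start grid; the start with the lowest
#' residual sum of squares wins. A fit is `accepted` when its R-squared
#' over the fitted segment exceeds `r2_min` (default 0.9); unaccepted fits
#' are excluded from group metrics downstream.
#'
#' @param waveform a [flow_waveform()] (relative flow, baseline near 1), or
#'   a plain list with `times` and `values`.
#' @param onset stimulus onset in seconds; defaults to the waveform's
#'   `stim_window[1]` when present, else 5.
#' @param r2_min acceptance threshold on R-squared.
#' @param starts data frame of starting values (`alpha1`, `alpha2`, `beta1`,
#'   `beta2`, `c`); default [hrf_start_grid()].
#' @param lower,upper box constraints as named vectors over
#'   `(A, c, alpha1, alpha2, beta1, beta2)`.
#' @return an object of class `hrffit` with components `coefficients`,
#'   `r_squared`, `accepted`, `converged`, `t0` (onset), `t` (post-onset
#'   times, seconds), `y` (percent change data), `fitted.values`,
#'   `residuals`. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`, `fitted`, `simulate`.
#' @examples
#' truth <- hrf_design(0.03, 0.02)
#' p <- make_protocol()
#' wf <- simulate_dcs_waveform(p, truth, noise_sd = 0)
#' fit <- fit_hrf(wf)
#' coef(fit)
#' quantify_response(fit)
#' @export
fit_hrf <- function(waveform, onset = NULL, r2_min = 0.9,
                    starts = hrf_start_grid(),
                    lower = c(A = 0, c = 0, alpha1 = 1 + 1e-6,
                              alpha2 = 1 + 1e-6, beta1 = 1e-6, beta2 = 1e-6),
                    upper = c(A = Inf, c = 5, alpha1 = 30, alpha2 = 30,
                              beta1 = 10, beta2 = 10)) {
  times <- waveform$times
  values <- waveform$values
  if (is.null(onset)) {
    onset <- if (!is.null(waveform$stim_window)) waveform$stim_window[1] else 5
  }
  keep <- times >= onset
  if (sum(keep) < 10) stop_config("fit_hrf: need >= 10 post-onset samples")
  t <- times[keep] - onset
  y <- (values[keep] - 1) * 100
  ord <- c("A", "c", "alpha1", "alpha2", "beta1", "beta2")

  model <- function(par, t) {
    par <- as.list(par)
    par$A * (stats::dgamma(t, par$alpha1, rate = par$beta1) -
               par$c * stats::dgamma(t, par$alpha2, rate = par$beta2))
  }
  resid_fn <- function(par) y - model(par, t)

  A0 <- max(y, 0.5 * stats::sd(y), 1e-3)  # crude amplitude scale (% * s)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- c(A = A0 * 2, c = starts$c[i], alpha1 = starts$alpha1[i],
            alpha2 = starts$alpha2[i], beta1 = starts$beta1[i],
            beta2 = starts$beta2[i])[ord]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower[ord],
                         upper = upper[ord],
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  sst <- sum((y - mean(y))^2)
  if (is.null(best)) {
    out <- structure(list(coefficients = NULL, r_squared = NA_real_,
                          accepted = FALSE, converged = FALSE, t0 = onset,
                          t = t, y = y, fitted.values = NULL,
                          residuals = NULL, r2_min = r2_min),
                     class = "hrffit")
    return(out)
  }
  par <- best$fit$par
  fitted <- model(par, t)
  r2 <- 1 - best$ss / sst
  structure(list(coefficients = par, r_squared = r2,
                 accepted = is.finite(r2) && r2 > r2_min,
                 converged = best$fit$info %in% 1:4, t0 = onset,
                 t = t, y = y, fitted.values = fitted,
                 residuals = y - fitted, r2_min = r2_min),
            class = "hrffit")
}

#' @export
print.hrffit <- function(x, ...) {
  cat("Double-gamma hemodynamic response fit\n")
  if (is.null(x$coefficients)) {
    cat("  fit failed from all starts (accepted = FALSE)\n")
    return(invisible(x))
  }
  cat(sprintf("  R-squared: %.4f (%s, gate %.2f)\n", x$r_squared,
              if (x$accepted) "accepted" else "rejected", x$r2_min))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.hrffit <- function(object, ...) object$coefficients

#' @export
residuals.hrffit <- function(object, ...) object$residuals

#' @export
fitted.hrffit <- function(object, ...) object$fitted.values

#' Predict from a fitted double-gamma response
#'
#' @param object an `hrffit`.
#' @param t times in seconds post-onset; default the fitted time points.
#' @param ... unused.
#' @return fitted percent-change values at `t`.
#' @export
predict.hrffit <- function(object, t = object$t, ...) {
  if (is.null(object$coefficients)) stop_config("predict.hrffit: fit failed")
  p <- as.list(object$coefficients)
  hrf_eval(list(A = p$A, c = p$c, alpha1 = p$alpha1, alpha2 = p$alpha2,
                beta1 = p$beta1, beta2 = p$beta2), t)
}

#' @export
summary.hrffit <- function(object, ...) {
  m <- if (object$accepted) quantify_response(object) else NULL
  out <- list(fit = object, metrics = m)
  class(out) <- "summary.hrffit"
  out
}

#' @export
print.summary.hrffit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$metrics)) {
    with(x$metrics, {
      cat(sprintf("  peak: %+.3f%% at %.2f s post-stimulus\n",
                  peak_amplitude, peak_time))
      if (!is.na(undershoot_amplitude))
        cat(sprintf("  undershoot: %+.3f%% at %.2f s\n",
                    undershoot_amplitude, undershoot_time))
      cat(sprintf("  integrated: %+.2f %%*s positive, %+.2f %%*s negative\n",
                  integral_positive, integral_negative))
    })
  }
  invisible(x)
}

#' @export
plot.hrffit <- function(x, shade = TRUE, ...) {
  plot(x$t, x$y, pch = 16, cex = 0.6, col = "grey40",
       xlab = "time post-stimulus (s)", ylab = "relative flow change (%)", ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  if (!is.null(x$coefficients)) {
    tg <- seq(min(x$t), max(x$t), length.out = 400)
    yg <- predict(x, tg)
    if (shade && x$accepted) {
      m <- quantify_response(x, t_max = max(x$t))
      pos <- tg >= m$positive_interval[1] & tg <= m$positive_interval[2]
      graphics::polygon(c(tg[pos], rev(tg[pos])), c(yg[pos], rep(0, sum(pos))),
                        col = grDevices::adjustcolor("red", 0.2), border = NA)
      if (!any(is.na(m$negative_interval))) {
        neg <- tg >= m$negative_interval[1] & tg <= m$negative_interval[2]
        graphics::polygon(c(tg[neg], rev(tg[neg])), c(yg[neg], rep(0, sum(neg))),
                          col = grDevices::adjustcolor("blue", 0.2), border = NA)
      }
    }
    graphics::lines(tg, yg, col = "red", lwd = 2, lty = 2)
  }
  invisible(x)
}

#' Simulate waveforms from a fitted response
#'
#' Draws `nsim` relative-flow waveforms on the fitted time grid: the fitted
#' curve plus i.i.d. Gaussian noise with the residual standard deviation.
#'
#' @param object an accepted `hrffit`.
#' @param nsim number of waveforms.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data frame with one column per simulated waveform (percent change).
#' @export
simulate.hrffit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$coefficients)) stop_config("simulate.hrffit: fit failed")
  s <- stats::sd(object$residuals)
  with_seed(seed, {
    out <- replicate(nsim, object$fitted.values + stats::rnorm(length(object$t), 0, s))
    as.data.frame(out)
  })
}

#' Quantify peak, undershoot and integrated areas of a fitted response
#'
#' Evaluates the fitted curve on a dense grid (1-ms default) over
#' `[0, t_max]` seconds post-stimulus. The positive peak is the curve
#' maximum; the undershoot is the minimum after the peak, reported only if
#' the curve actually goes negative. The positive/negative intervals are
#' delimited by the baseline crossings of the fit (sign changes refined by
#' bisection via [stats::uniroot()]), and the integrated areas are trapezoid
#' integrals over those intervals.
#'
#' @param fit an accepted `hrffit`, or an `hrf_params` design (evaluated in
#'   percent, i.e. scaled by 100).
#' @param t_max end of the analysis window, seconds post-stimulus; defaults
#'   to the fitted data span (25 s for a default-protocol waveform).
#' @param dt dense-grid step in seconds.
#' @return object of class `response_metrics`: `peak_amplitude` (%),
#'   `peak_time` (s), `undershoot_amplitude` (%, signed negative or `NA`),
#'   `undershoot_time` (s or `NA`), `positive_interval`,
#'   `negative_interval` (s), `integral_positive` (>= 0),
#'   `integral_negative` (<= 0), both in %*s.
#' @export
quantify_response <- function(fit, t_max = NULL, dt = 0.001) {
  if (inherits(fit, "hrffit")) {
    if (is.null(fit$coefficients)) stop_config("quantify_response: fit failed")
    if (!fit$accepted) warning("quantifying a rejected fit (R-squared below gate)")
    par <- as.list(fit$coefficients)
    if (is.null(t_max)) t_max <- max(fit$t)
    f <- function(t) hrf_eval(par, t)
  } else if (inherits(fit, "hrf_params")) {
    if (is.null(t_max)) t_max <- 25
    f <- function(t) 100 * hrf_eval(fit, t)
  } else stop_config("quantify_response: need an 'hrffit' or 'hrf_params'")

  tg <- seq(0, t_max, by = dt)
  v <- f(tg)
  ip <- which.max(v)
  peak <- v[ip]; t_peak <- tg[ip]
  after <- seq(ip, length(tg))
  iu <- after[which.min(v[after])]
  has_under <- v[iu] < 0
  eps <- 1e-12

  cross <- function(lo, hi) stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  sgn <- sign(v); sgn[abs(v) < eps] <- 0
  flips <- which(diff(sgn != 0 & sgn < 0) != 0 | diff(sgn != 0 & sgn > 0) != 0)

  # positive lobe: starts at 0 (curve rises from zero), ends at the first
  # downward crossing after the peak (or t_max if it never crosses)
  down <- which(v[-1] <= 0 & v[-length(v)] > 0)
  down <- down[down >= ip]
  pos_end <- if (length(down)) cross(tg[down[1]], tg[down[1] + 1]) else t_max
  pos_int <- c(0, pos_end)

  if (has_under) {
    up <- which(v[-1] >= 0 & v[-length(v)] < 0)
    up <- up[up >= iu]
    neg_end <- if (length(up)) cross(tg[up[1]], tg[up[1] + 1]) else t_max
    neg_int <- c(pos_end, neg_end)
    undershoot <- v[iu]; t_under <- tg[iu]
  } else {
    neg_int <- c(NA_real_, NA_real_)
    undershoot <- NA_real_; t_under <- NA_real_
  }

  trap <- function(a, b) {
    ts <- seq(a, b, by = dt)
    if (length(ts) < 2) ts <- c(a, b)
    vs <- f(ts)
    sum((vs[-1] + vs[-length(vs)]) / 2 * diff(ts))
  }
  int_pos <- max(trap(pos_int[1], pos_int[2]), 0)
  int_neg <- if (has_under) min(trap(neg_int[1], neg_int[2]), 0) else 0

  structure(list(peak_amplitude = peak, peak_time = t_peak,
                 undershoot_amplitude = undershoot, undershoot_time = t_under,
                 positive_interval = pos_int, negative_interval = neg_int,
                 integral_positive = int_pos, integral_negative = int_neg),
            class = "response_metrics")
}

#' @export
print.response_metrics <- function(x, ...) {
  cat(sprintf("peak %+.3f%% @ %.2f s", x$peak_amplitude, x$peak_time))
  if (!is.na(x$undershoot_amplitude))
    cat(sprintf("; undershoot %+.3f%% @ %.2f s", x$undershoot_amplitude,
                x$undershoot_time))
  cat(sprintf("; areas %+.2f / %+.2f %%*s\n", x$integral_positive,
              x$integral_negative))
  invisible(x)
}
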