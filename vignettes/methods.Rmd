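---
title: "Dissecting evoked cerebral blood flow by vessel caliber: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting evoked cerebral blood flow by vessel caliber: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaflow)
```

## The problem

Diffuse correlation spectroscopy (DCS) infers cerebral blood flow from the
decay of the scattered-light intensity autocorrelation; it is cheap and
noninvasive but spatially diffuse, and it is widely assumed — not directly
demonstrated — that its signal is dominated by flow in microvasculature.
OCT angiography (OCT-A) resolves flow contrast down to capillary scale and
can therefore arbitrate: if evoked flow responses are extracted from OCT-A
separately for vessels of different calibers, the DCS waveform can be
compared against each caliber class.

`octaflow` implements that computational dissection as a reusable, fully
tested pipeline:

1. **Angiography** — repeated complex B-scans at one lateral location are
   collapsed into a flow-contrast image by the average absolute difference
   of signal magnitudes.
2. **Vessel segmentation** — the angiogram is split by multilevel Otsu
   thresholding; bright connected components are binned by
   equivalent-circle diameter into medium (10–20 µm) and large (> 20 µm)
   classes, and remaining suprathreshold pixels form the
   sub-resolution small (< 10 µm) class.
3. **Response extraction** — masked per-frame sums are normalized to the
   pre-stimulus baseline, giving per-class relative-flow waveforms.
4. **Response modeling** — waveforms are fit with the canonical
   double-gamma hemodynamic response function (HRF) and quantified
   (peak, undershoot, latencies, integrated areas).
5. **Survey and statistics** — an en-face survey video locates the
   activation centroid; group aggregation, normality checks, t-tests and
   DCS/OCT-A Pearson correlations summarize an experiment.

Because the in-vivo recordings behind this design are not public, the
package ships a synthetic acquisition generator with known ground truth;
every stage is validated by recovering what was put in.

## Acquisition model

The protocol object encodes the stimulation acquisition: a 30-s recording
of 65 composite frames at 0.46 s/frame, each composite frame built from 32
repeated B-scans of 250 A-scans; the stimulus is a 4-s train of 12 pulses
at 3 Hz starting 5 s in (composite frames 11–20); the first 9 frames
(≈ first 4 s) are the baseline; a DCS channel is sampled concurrently at
4.4 Hz (132 samples). A trial is one such acquisition; ten stimulus
presentations per condition are averaged; the group size defaults to 11
animals.

```{r}
make_protocol()
```

Frame timestamps are taken at exposure centers, `(i - 1/2) * 0.46` s; the
convention is not dictated by the acquisition and is configurable only by
editing the waveform times.

## The double-gamma response model

Evoked flow is modeled as

$$\mathrm{HRF}(t) = A\left(
\frac{t^{\alpha_1-1}\beta_1^{\alpha_1}e^{-\beta_1 t}}{\Gamma(\alpha_1)}
- c\,\frac{t^{\alpha_2-1}\beta_2^{\alpha_2}e^{-\beta_2 t}}{\Gamma(\alpha_2)}
\right),$$

a difference of two gamma densities: the first lobe is the functional
hyperemia peak, the second the post-stimulus undershoot; `A` sets the
amplitude, `c` the peak-to-undershoot ratio. For shapes above 1 the curve
is zero at stimulus onset and decays to zero, which matches a
baseline-referenced flow change.

`fit_hrf()` is the package's central estimator and returns a classed
`hrffit` object with the standard method suite (`coef`, `predict`,
`residuals`, `plot`, `simulate`, `summary`). Fitting choices, all of which
were genuinely open:

* **Units and axis.** The fit is performed on `(value − 1) × 100`
  (percent change) with time re-referenced to stimulus onset, and only the
  post-onset segment is fit. Fitting the full trace would spend degrees of
  freedom on baseline noise the model is structurally zero over.
* **Optimizer and multi-start.** Levenberg–Marquardt least squares
  (`minpack.lm::nls.lm`). Double-gamma least squares is multimodal, so the
  fit restarts from a small grid (α₁ ∈ {3, 6}, α₂ ∈ {8, 12},
  β₁ = β₂ = 1, c ∈ {0.2, 0.8}, amplitude from the observed maximum) and
  the lowest residual sum of squares wins.
* **Bounds.** `A ≥ 0`, `c ∈ [0, 5]`, `α ∈ (1, 30]`, `β ∈ (0, 10]` keep
  the curve zero at onset, bounded, and identifiable.
* **Acceptance gate.** A fit is accepted when R² > 0.9 over the fitted
  segment (R² = 1 − SS_res/SS_tot); rejected fits are excluded from group
  metrics. The gate is an inclusion criterion, not part of the estimator:
  estimator-bias properties are tested on raw fits.

`quantify_response()` evaluates the fitted curve on a 1-ms grid: the peak
is the maximum, the undershoot the post-peak minimum (reported only if
negative), baseline crossings are refined by bisection, and the
positive/negative areas are trapezoid integrals between crossings. Metrics
change by less than 10⁻⁴ when the grid is refined to 0.1 ms (tested).

`hrf_design()` inverts the model for the generator: given a target peak,
undershoot magnitude and extremum latencies it solves for the six
coefficients (1-D root solve for `c`, exact rescale of `A`, iterative
rate rescaling for the latencies), so synthetic ground truth can be set
directly to published grand-average values. All default ground-truth
curves peak 7.3 s post-stimulus with the undershoot minimum at 15 s.

## The synthetic scene and its forward model

A scene is a static complex speckle field (zero-mean complex Gaussian
parenchyma, so magnitudes are Rayleigh) with embedded vessel
cross-sections drawn as filled disks on the pixel grid (strict
center-in-disk rasterization at 4 µm/px). Every repeat adds fresh complex
detector noise everywhere; pixels inside a vessel additionally fluctuate
in magnitude with standard deviation

$$\sigma_{\mathrm{flow}} = s \cdot b_v \cdot f(t),$$

where `s` is the global contrast scale (0.25), `b_v` the per-vessel
baseline decorrelation (defaults 0.45/0.8/1.0 for small/medium/large —
larger vessels carry faster flow) and `f(t)` the instantaneous relative
flow, `1 + HRF(t − onset)`.

The expected angiogram value at a vessel pixel is then
`(2/√π)·√(σ_flow² + σ_det²)`: **proportional to flow** wherever the flow
contrast dominates detector noise. This linearity is the key design
decision. An autoregressive resampling of the complex field (mixing
coefficient rising with flow) also produces monotone contrast, but its
square-root-shaped response compresses a baseline-normalized fractional
flow change by roughly half, which would make amplitude recovery
structurally biased; baseline normalization does not linearize a
readout. Since the whole point of the generator is that downstream
readouts are faithful relative-flow measures, the magnitude-fluctuation
model is used. With the default detector noise (0.02 vs. small-vessel
σ_flow ≈ 0.11) the residual quadrature compression of a small-vessel
response is ≈ 3%, far below the inter-animal spread.

Vessels are placed on a non-overlapping 8-px cell lattice with the class
assignment shuffled by seed, guaranteeing ≥ 1 background pixel between
footprints so 8-connected components never merge. The default scene is an
80 × 176 px (320 × 704 µm) focal sub-region holding 160 small (8 µm),
24 medium (16 µm) and 14 large (28 µm) cross-sections — capillary-dense,
as a cortical B-scan is. Those counts were fixed once so that the
per-class masked sums have signal-to-noise comparable to the in-vivo
waveforms the R² > 0.9 gate was designed for; with an order of magnitude
fewer vessel pixels per class, the gate would reject most fits of a ~1%
response, which is a statement about the fixture size, not the method.

**What the generator does not emulate:** physical OCT interferometry
(k-space, dispersion, depth roll-off), partial-volume vessel edges,
pulsatility, vessel tortuosity or 3-D geometry, photon-counting DCS
statistics, and any arteriole/venule distinction. Passing recovery tests
therefore show the *pipeline's* correctness and calibration, not that the
simple speckle model captures real-tissue nuisance structure.

## Segmentation choices

* **Multilevel Otsu** is an exhaustive maximization of between-class
  variance over a 256-bin histogram (no installed package provides the
  multi-level variant). Empty histogram gaps make the criterion flat, so
  ties are broken at the plateau midpoint — thresholds land mid-gap
  between intensity clusters rather than at the edge of the lower one.
* **Masks are built once** from the time-averaged baseline angiogram and
  applied to every frame. A per-frame mask would confound the temporal
  response with segmentation jitter; fixed masks are what makes the
  per-class time series meaningful.
* **Component sizing** uses the equivalent-circle diameter
  `2√(area·scale²/π)` of 8-connected components above the upper
  threshold; cross-sections are compact punctae, for which an area-based
  diameter is more stable than a caliper width. Bin edges: small < 10,
  medium [10, 20], large > 20 µm.
* **The small class is a noise-gated remainder**: pixels above the *lower*
  Otsu threshold and outside medium/large components. Sub-resolution
  vessels cannot be individually segmented at ~9 µm resolution, and a
  literal non-zero gate would be saturated by detector noise, so the lower
  Otsu level serves as the noise floor.

## Numerical and statistical conventions

* Baseline normalization divides by the mean over the first 9 frames
  (OCT-A) or the first 4 s (DCS); it is exact (output baseline mean 1
  within 10⁻⁹) and idempotent.
* DCS-to-OCT-A comparison resamples the 4.4-Hz channel onto the 65 frame
  centers by linear interpolation (the coarser grid avoids inventing
  OCT-A samples); Pearson correlation is computed on the full 30-s
  common grid.
* When constructing waveform pairs with a prescribed population
  correlation ρ, the noise SD solves ρ = 1/√(1 + σ²/var(signal)); if the
  noise is added at 4.4 Hz and then interpolated, interpolation shrinks
  its variance by the factor mean[(1−λ)² + λ²] over the target grid, and
  the calibration inflates σ accordingly. Both identities are verified by
  brute-force simulation in the test suite.
* Group summaries report mean ± sample SD (n − 1), a one-sample
  Kolmogorov–Smirnov normality p-value on standardized values, and
  two-tailed Student's t-tests against the lowest stimulus current —
  paired within animals, since every animal is measured at every current;
  an unpaired mode and a Bonferroni option exist but default off (no
  correction is applied by default). Degenerate comparisons (zero
  variance) are flagged rather than tested.
* Undershoot amplitudes are stored signed (negative); tables and group
  summaries report magnitudes.
* All randomness flows through explicit seeds; a master seed derives
  sub-seeds (`sample.int`, < 2³¹) per animal, presentation and frame, so
  an experiment is bit-reproducible from its config.

## Fixture and experiment sizes

The validation experiments simulate the full study design — 11 animals ×
10 presentations × 65 frames × 32 repeats, with 1-mA ground-truth
amplitudes (small 2.19%/0.86%, large 0.92%/1.96%, DCS 3.37%/−3.04%) — on
the 80 × 176 px scene above; the survey check uses the full 250-A-scan,
100-px-deep geometry at 10 lateral locations. Unit tests use smaller
scenes (e.g. 40 × 48 px, a handful of vessels) where only arithmetic, not
group statistics, is at stake. The DCS per-presentation noise SD defaults
to 1.5% relative flow, which after 10-presentation averaging puts
single-animal fits comfortably inside the acceptance gate, mirroring a
study in which all included animals yielded usable fits.

## Known limitations

* The medium-class (10–20 µm) 1-mA ground truth is invented (1.5%/1.5%);
  no published grand average exists for it at that current, and it is not
  used for validation.
* The DCS channel is a relative-flow time series plus Gaussian noise; the
  toy `g2` model (`1 + β e^{−2γτ}`, γ ∝ flow index) exists only to
  exercise a round-trip flow-index extraction and is explicitly not a
  reconstruction of any instrument's correlation processing.
* Axial motion correction estimates one rigid axial shift per repeat from
  laterally averaged profiles (quadratic subpixel peak interpolation);
  it is a simplified offline stand-in for per-A-scan alignment and is off
  by default for synthetic scenes, which simulate no drift.
* Absolute velocity calibration, phase-based Doppler processing, lateral
  motion correction, artery/vein discrimination and biophysical
  (balloon/Windkessel) response modeling are out of scope.
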