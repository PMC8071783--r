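# octaflow

Vessel-diameter-resolved analysis of sensory-evoked cerebral blood flow
from OCT angiography (OCT-A) and diffuse correlation spectroscopy (DCS).

## What this is for

DCS is a diffuse near-infrared technique that infers cerebral blood flow
from the decay of the scattered-light intensity autocorrelation. It is
assumed to be biased toward microvascular flow, but a diffuse measurement
cannot say which vessels it reports on. OCT-A resolves flow contrast at
capillary scale, so evoked responses extracted from OCT-A *per vessel
caliber* can be compared directly against the concurrent DCS waveform.

`octaflow` implements that dissection as a tested pipeline for researchers
working with stimulus-evoked optical recordings (or wanting a validated
synthetic testbed for one):

- **Angiography** — composite flow-contrast frames from repeated complex
  B-scans via the average absolute magnitude difference
  `(1/(N−1)) Σ | |Sᵢ₊₁| − |Sᵢ| |` (all-pairs mode available), with
  optional axial motion correction and depth-ROI cropping.
- **Segmentation** — multilevel Otsu thresholding plus 8-connected
  component sizing splits the angiogram into small (< 10 µm), medium
  (10–20 µm, by equivalent diameter) and large (> 20 µm) vessel classes.
- **Response extraction** — masked per-frame sums, normalized to the
  pre-stimulus baseline, averaged over stimulus presentations.
- **Response modeling** — the canonical double-gamma hemodynamic response

  HRF(t) = A·( t^(α₁−1) β₁^α₁ e^(−β₁t) / Γ(α₁) − c · t^(α₂−1) β₂^α₂ e^(−β₂t) / Γ(α₂) ),

  fit by Levenberg–Marquardt least squares with multi-start, gated at
  R² > 0.9, and quantified (peak, undershoot, latencies, integrated
  areas between baseline crossings).
- **Survey & statistics** — the 65-frame, 25×25-px en-face response
  survey; group means ± SD, Kolmogorov–Smirnov normality checks,
  two-tailed t-tests; DCS-vs-OCT-A Pearson correlation on a common grid.
- **Synthetic acquisitions** — a speckle-scene generator with known
  per-class ground-truth responses (30-s protocol: 65 composite frames ×
  32 repeats, stimulus at 5 s, DCS at 4.4 Hz), so every stage is
  validated by parameter recovery.

See `vignettes/methods.Rmd` for the models, the forward-model design and
its limitations.

## Worked example

Simulate one animal's DCS channel — ten 30-s stimulus presentations whose
ground-truth response peaks at +3.37% with a −3.04% undershoot — then
average, fit and quantify:

```r
library(octaflow)

truth    <- hrf_design(peak = 0.0337, undershoot = 0.0304)  # fractional units
protocol <- make_protocol()
animal   <- run_animal_dcs(protocol, truth, noise_sd = 0.015, seed = 7)
summary(animal$fit)
#> Double-gamma hemodynamic response fit
#>   R-squared: 0.9470 (accepted, gate 0.90)
#>       A       c  alpha1  alpha2   beta1   beta2
#> 53.1715  1.1431  6.7918 12.0495  0.6293  0.8436
#>   peak: +3.464% at 7.19 s post-stimulus
#>   undershoot: -3.080% at 15.00 s
#>   integrated: +16.96 %*s positive, -23.94 %*s negative
```

The fit recovers the generating amplitudes (3.46% vs 3.37% truth, −3.08%
vs −3.04%) and the 7.3-s peak latency from a single simulated animal; the
integrated areas are the %·s areas of the fitted curve above and below
baseline. A full group experiment — n animals × presentations × currents,
OCT-A pipeline plus DCS channel plus correlations — runs through one
driver:

```r
cfg <- experiment_config(n_animals = 11, currents = 1, seed = 101)
res <- run_experiment(cfg, out = "results/run1")   # CSV bundle + config
res$group$peak_small                               # group mean ± SD, tests
```

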