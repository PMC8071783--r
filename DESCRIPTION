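Package: octaflow
Title: Vessel-Diameter-Resolved Analysis of Sensory-Evoked Cerebral Blood
    Flow from OCT Angiography and Diffuse Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting sensory-evoked cerebral blood flow by
    vessel caliber. Computes speckle-decorrelation angiograms from repeated
    complex OCT B-scans (average absolute magnitude difference), segments
    vessel cross-sections into diameter classes by multilevel Otsu
    thresholding and connected-component sizing, extracts baseline-normalized
    relative-flow waveforms per class, fits the canonical double-gamma
    hemodynamic response function by Levenberg-Marquardt least squares, and
    quantifies peak, undershoot, latency and integrated-area metrics.
    Includes an en-face response survey builder, correlation of diffuse
    correlation spectroscopy (DCS) waveforms against depth-resolved flow,
    group-level statistics, and a synthetic acquisition generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
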