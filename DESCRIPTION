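Package: farredplr
Title: Far-Red Smartphone Pupillometry: Simulation, Segmentation and
    PLR Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for far-red (630-700 nm) smartphone
    pupillometry. Provides a synthetic eye-video generator with known
    ground truth that reproduces the wavelength-dependent pupil-iris
    contrast created by iris melanin, a classical pupil detector for
    high-contrast far-red frames, the pupil-iris contrast statistic and
    its percent-increase comparison between spectral conditions, CIELAB
    iris-luminance characterisation, pupillary light reflex (PLR) trace
    processing (downsampling, blink exclusion, percent change from mean,
    lag alignment), and device-agreement statistics (MAE, Pearson
    correlation, Bland-Altman limits of agreement) with cohort summaries.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    graphics,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
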