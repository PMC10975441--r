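Package: hsimoist
Title: Hyperspectral Prediction of Seed Moisture Content
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A chemometrics workflow for predicting moisture content of
    maize seeds from near-infrared hyperspectral images. Provides
    black/white reflectance calibration, trimming of noisy spectral
    extremes, seed segmentation, seven spectral pretreatments (moving
    average, Savitzky-Golay smoothing, baseline, normalization, SNV, MSC,
    detrending), SPXY calibration/prediction partitioning, three
    wavelength-selection algorithms (successive projections, competitive
    adaptive reweighted sampling, uninformative variable elimination),
    PLSR/PCR/SVR calibration models with cross-validated error metrics,
    and pixel-wise pseudo-color moisture maps. A synthetic hyperspectral
    seed-data generator with known ground truth supports end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    e1071,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
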