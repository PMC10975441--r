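# hsimoist

Chemometric calibration of **maize-seed moisture content** from
near-infrared hyperspectral images.

Water absorbs at the O–H first overtone (~1450 nm) and the O–H
combination band (~1940 nm); the depth of those features in a seed's
reflectance spectrum encodes its moisture. `hsimoist` implements the
complete workflow a seed-quality lab would run around that signal, for
anyone building or auditing an NIR moisture calibration:

* **Imaging** — black/white reflectance calibration
  `R = (I_raw − I_dark) / (I_white − I_dark)`, trimming of the
  noise-afflicted spectral extremes (256 bands over 935.5–2539 nm → the
  218 interior bands, ≈1068–2432 nm), Otsu-based seed segmentation, and
  ENVI/CSV I/O.
* **Pretreatment** — moving average, Savitzky–Golay, baseline,
  min–max normalization, SNV, MSC, detrending; one dispatcher, leakage
  free (statistics frozen on the calibration set).
* **SPXY splitting** — Kennard–Stone max–min selection on the joint
  distance `dx/max(dx) + dy/max(dy)`; deterministic.
* **Wavelength selection** — successive projections (SPA), competitive
  adaptive reweighted sampling (CARS), and uninformative variable
  elimination (UVE), each with full diagnostics (RMSE-vs-size traces,
  retained-count and RMSECV traces, stability spectra).
* **Modelling** — PLSR (NIPALS), PCR, and RBF support-vector regression;
  RC²/RMSEC, RCV²/RMSECV (leave-one-out), RP²/RMSEP; component counts by
  cross-validation.
* **Visualization** — pixel-wise moisture prediction over a cube through
  the frozen pipeline, rendered as a pseudo-colour map on a 0–12 % scale.
* **Synthetic data** — a seeded Beer–Lambert-style generator of sample
  spectra and full imaged scenes (raw/white/dark frames, seed masks,
  per-pixel ground truth) so every stage is testable with known answers.

## Worked example

```r
library(hsimoist)

cfg   <- synthetic_config(n_samples = 80, seed = 42)  # 7.38–11.99 % moisture
gen   <- generate_spectra(cfg)
x     <- trim_bands(gen$spectra)                      # 80 x 218
split <- spxy_split(x, gen$moisture, calib_fraction = 0.75)
split
#> <SPXY split> 60 calibration / 20 prediction (fraction 0.75)

xp  <- preprocess(x, preprocess_spec("normalization"))
xc  <- xp[split$calibration_idx, ]
yc  <- gen$moisture[split$calibration_idx]
sel <- spa_select(xc, yc)
sel
#> <SPA selection> 21 of 218 bands (9.6%)

report <- evaluate_grid(xc, yc,
                        xp[split$prediction_idx, ],
                        gen$moisture[split$prediction_idx],
                        selections = list(full = NULL, spa = sel),
                        kinds = c("plsr", "pcr"))
print(report, digits = 3)
#>   selection model bands PCs   RC2  RMSEC  RCV2 RMSECV   RP2 RMSEP
#> 1      full  plsr   218   2 0.995 0.0908 0.994  0.104 0.996 0.114
#> 2      full   pcr   218   8 0.995 0.0911 0.994  0.103 0.995 0.119
#> 3       spa  plsr    21   2 0.992 0.1192 0.989  0.135 0.985 0.197
#> 4       spa   pcr    21  15 0.995 0.0969 0.990  0.130 0.983 0.211
```

Reading the table: `RC2`/`RMSEC` describe the fit on the 60 calibration
samples, `RCV2`/`RMSECV` the leave-one-out cross-validation, and
`RP2`/`RMSEP` the 20 held-out prediction samples (all errors in %
moisture). On this synthetic draw the full-band PLSR predicts held-out
moisture to about 0.11 % moisture; the 21-band SPA subset trades a little
accuracy for a 10× smaller model. `run_full_study()` runs the whole
selection × model grid from one config, and `predict_map()` +
`render_map()` turn a segmented cube into a pseudo-colour moisture image.

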