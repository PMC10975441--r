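---
title: "Calibrating seed moisture from NIR hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating seed moisture from NIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsimoist)
```

## The problem

Moisture content drives the storability and viability of maize seed:
above roughly 13 % wet basis, respiration and mould risk rise sharply.
The reference assay (oven drying) is destructive and slow. Near-infrared
hyperspectral imaging offers a non-destructive alternative: water absorbs
at the O–H first overtone near 1450 nm and the O–H combination band near
1940 nm, so the depth of those features in a seed's reflectance spectrum
carries the moisture signal. `hsimoist` implements the full chemometric
workflow from raw camera frames to a pixel-wise moisture map:

1. black/white reflectance calibration,
   `R = (I_raw - I_dark) / (I_white - I_dark)`;
2. trimming of the noise-afflicted spectral extremes (a 256-band
   935.5–2539 nm axis is cut to its 218 interior bands, about
   1068–2432 nm);
3. seed segmentation (Otsu threshold on a high-contrast band, connected
   components, per-region mean spectra);
4. one of seven spectral pretreatments;
5. SPXY partitioning into calibration and prediction sets;
6. wavelength selection by SPA, CARS or UVE;
7. PLSR, PCR or SVR calibration with cross-validated component choice;
8. pixel-wise prediction and pseudo-colour rendering on a 0–12 % scale.

## The synthetic study

No public hyperspectral seed dataset accompanies this workflow, so the
package ships a generator whose output has the statistical structure the
analysis assumes, with known ground truth. Per sample `i` the model is
Beer–Lambert-like:

* moisture `m_i ~ Uniform(7.377, 11.993)` % — uniform rather than
  Gaussian so that the full range is covered at n = 80, which is what
  range-driven SPXY splitting responds to;
* absorbance `a_i(λ) = baseline(λ) + peak_gain · m_i · Σ_k G(λ; c_k, w_k)`
  with unit-height Gaussian bands at 1450 and 1940 nm;
* reflectance `r_i(λ) = s_i · exp(-a_i(λ)) + o_i + ε_i(λ)`, with
  multiplicative scatter `s_i ~ N(1, 0.05)`, additive offset
  `o_i ~ N(0, 0.02)`, and heteroscedastic noise `ε` (sd 0.005 in the
  interior, inflated five-fold at the spectral extremes), clipped to
  (0, 1.5] so that slightly-above-one calibrated reflectance is not
  hidden.

Parameter defaults and the reasoning behind them:

| parameter | default | why |
|---|---|---|
| `baseline_coeffs` | `c(0.45, 0.4, 0.9)` (absorbance, polynomial in normalised wavelength) | reflectance falls from ≈0.6 at 1100 nm to ≈0.2 at 2430 nm, the shape of real grain spectra; it also places each spectrum's min/max on moisture-independent baseline regions, so min–max normalization anchors on stable bands rather than inside a water band |
| `peak_gain` | 0.06 absorbance / % moisture | gives `log10(1/R)` ≈ 0.9–1.1 at 1940 nm for 7–12 % moisture, typical of grain |
| `peak_widths` | 45, 60 nm (Gaussian sd) | O–H overtone/combination bands have FWHM ≈ 100–150 nm |
| `noise_sd` | 0.005 reflectance | per-band detector/illumination noise on a sample spectrum |
| `edge_noise_factor` | 5 | the first ~8.2 % and last ~6.6 % of bands (≈15 % of the axis in total) carry strongly inflated noise — exactly the sections the default trim excises |
| `scatter_slope_sd`, `scatter_offset_sd` | 0.05, 0.02 | particle-size and surface-geometry scatter; these are what SNV, MSC and normalization exist to remove |

Each artifact type maps onto the pretreatment designed to remove it, which
is what makes the pretreatment comparison meaningfully testable: smoothing
targets `ε`, baseline/detrending target additive trends, and
SNV/MSC/normalization target the affine scatter pair `(s_i, o_i)`.

The scene generator (`generate_scene()`) additionally places
non-overlapping elliptical "seeds" on a dark background, gives every seed
one moisture value (optionally jittered within the seed), and synthesises
raw/white/dark frames by inverting the reflectance correction, so the
imaging stage can be tested end-to-end to numerical precision.

What the generator does *not* emulate: radiometric sensor physics,
seed morphology, embryo-versus-endosperm surface differences,
band-to-band noise correlation, and moisture-dependent band shifts or
broadening. Tests passing on this generator therefore demonstrate that
the algorithms are implemented correctly and recover planted structure;
they do not certify performance on real instruments.

## Pretreatments

All seven methods act per spectrum (row-wise) and preserve the matrix
shape: moving average (window 7, shrinking at the edges rather than
padding, to avoid fabricating reflectance values), Savitzky–Golay
(window 7, order 2; polynomial edge evaluation), baseline (subtract the
line through the two endpoint samples, then shift the minimum to zero —
the simplest standard offset correction; polynomial baselines are
available via detrending), normalization (min–max to [0, 1] by default,
with unit-vector and max variants), SNV, MSC, and detrending (order 2).
"Normalization" and "baseline" have no universally agreed definition; the
variants chosen here are the common defaults in spectral software, and
the alternatives are exposed as flags.

MSC is the one stateful method: its reference spectrum is the
calibration-set mean, frozen by `freeze_preprocess()` and reapplied
unchanged to validation, prediction and pixel data — recomputing it on
test data would leak information.

## Splitting, selection, modelling

**SPXY** ranks samples by the joint distance
`d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)` and applies Kennard–Stone
max–min selection, seeded with the most distant pair. It is fully
deterministic; ties break toward the lowest sample index. The calibration
fraction defaults to 0.75 (60 of 80 samples). A caveat found while
validating the package: with moisture uniform and dense, the sample at a
range extreme has a close neighbour in both X and y, so the calibration
set occasionally misses the global extreme by a hairline (a few per cent
of the range); strict range coverage is a tendency, not a guarantee.

**SPA** builds, from every candidate start band, a forward chain that
repeatedly adds the band with maximal norm after orthogonal projection
away from the span of the chosen ones (computed by successive deflation,
verified against explicit orthogonal-complement projectors). Every
(start, size) prefix is scored by exact leave-one-out RMSE of a multiple
linear regression (hat-matrix identity), and the minimiser wins. Columns
are mean-centered before projection; chains truncate if the residual norm
falls below 1e-12.

**CARS** runs `n_mc = 50` Monte-Carlo iterations: PLS weights from a
random 80 % row subsample, an exponentially decaying retention count
`ceiling(r_i · p)` with `r_i = μ e^{-k i}` calibrated so `r_1 = 1` and
`r_N = 2/p` exactly (floor of 2 bands), then weighted resampling with
replacement whose unique survivors form the next retained set. Each set
is scored by 10-fold RMSECV of a PLS model whose component count is the
internal RMSECV minimiser (cap 10); the minimal-RMSECV set wins. All
randomness sits behind one seed.

**UVE** appends a noise matrix the width of X (uniform, scaled by
`noise_scale = 1e-10` so it defines the cutoff without perturbing the
fit), collects one PLS coefficient vector per left-out sample
(12 latent variables), computes per-band stability `C = mean(b)/sd(b)`,
and keeps real bands with `|C|` above the largest `|C|` among the noise
bands. `|C|` is used on both sides because informative coefficients can
be stably negative. The threshold is an extreme statistic of the noise
block, so bands sitting exactly at the cutoff may flip between noise
seeds even though the stabilities themselves are seed-invariant.

**Models.** PLSR is NIPALS with mean-centering (no variance scaling —
pretreatment owns the scale question); PCR regresses on leading
principal-component scores; both return coefficients for every component
count so cross-validation costs one decomposition per fold, and both
coincide with OLS at full rank (an oracle the tests exploit). SVR is
ε-insensitive RBF regression via `e1071::svm` with a seeded 5-fold grid
search (C ∈ {1, 10, 100}, γ around the 1/(p·var) heuristic ×{0.1, 1, 10},
ε ∈ {0.01, 0.1}). Component counts are chosen by leave-one-out RMSECV,
capped at 15. The reported "validation" statistics (RCV², RMSECV) are
cross-validation on the calibration set, not a third partition.

R² is the squared Pearson correlation between measured and predicted —
the conventional RC²/RP² of calibration reports, bounded in [0, 1]. An
alternative additive-denominator form sometimes printed in the applied
literature (cross-product divided by the *sum* of the two sums of
squares) is available behind `r_squared(..., literal = TRUE)` for
comparison; it tops out at 0.5 for perfect agreement and is not used
anywhere in the pipeline.

## Numerical choices and degenerate inputs

* Reflectance correction refuses any pixel/band where white ≤ dark —
  no epsilon clamping, because silent clamping hides acquisition faults.
* SNV and min–max normalization error on constant spectra, naming the
  row; during pixel-wise map prediction such pixels are flagged invalid
  and counted instead of aborting the map (a single dead pixel should not
  kill a scene).
* The default trim window is defined by band index (drop the first 21 and
  last 17 of 256) rather than by wavelength, so it reproduces a 218-band
  analysis axis exactly on the nominal grid; wavelength-interval trimming
  is the general API.
* Distance ties in SPXY and norm ties in SPA break toward the lowest
  index, making both deterministic across platforms.
* CARS' retention count uses `ceiling(r_i · p)` with a 1e-9 guard so the
  exact endpoint `r_N · p = 2` does not round up to 3.

## Stage order

The full study runs trim → pretreatment → SPXY → selection → modelling.
The package splits on raw trimmed spectra by default (leakage-free:
pretreatment statistics are then frozen on the calibration set), but the
headline recovery analysis in the test-suite pretreats before splitting,
which is safe for the stateless normalization and gives SPXY scatter-free
distances. Both orders are available; `run_full_study()` logs its choice.

## Problem sizes

The shipped validation suite works at the study's own scale where that is
cheap (80 samples × 218 bands for splitting, selection and modelling;
10 replicate seeds for the recovery study; 20 seeds for selector
sensitivity and pretreatment comparisons) and at reduced scale
(64-band spectra, 32–64 px scenes) for the imaging and visualization
stages, where the algorithms are resolution-independent.

## Known limitations

* On this generator, wavelength-subset models (SPA/CARS/UVE + PLSR)
  carry a higher noise floor than full-band models: the moisture signal
  enters every band through the same latent factor, so a small subset
  must approximate the exponential moisture response with large opposing
  coefficients, which amplifies independent per-band noise. Full-band
  PLS averages that noise across hundreds of bands. Real per-variety
  spectra, being means over thousands of seed pixels, have far lower
  band noise and do not show this gap; the generator's single-spectrum
  noise model is the pessimistic case.
* SVR hyperparameter search is a small fixed grid; serious SVR use would
  widen it.
* The ENVI reader covers the common cases (BIL/BSQ/BIP, types 1/2/4/5/12,
  wavelength lists) and no more.
* Segmentation assumes bright seeds on a dark background with no
  touching kernels; there is no watershed splitting.
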