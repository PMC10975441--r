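#' Construct a hyperspectral cube
#'
#' @param data 3-D numeric array, rows x cols x bands; raw detector counts
#'   or dimensionless reflectance.
#' @param wavelengths numeric vector (nm), strictly increasing, one per band.
#' @param kind `"raw"` or `"reflectance"`.
#' @return object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3)
    stop_hsi("cube data must be a 3-D array", class = "hsimoist_contract_error")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3])
    stop_hsi("wavelength count does not match band axis",
             class = "hsimoist_contract_error")
  if (any(diff(wavelengths) <= 0))
    stop_hsi("wavelengths must be strictly increasing",
             class = "hsimoist_contract_error")
  if (kind == "reflectance" && any(!is.finite(data)))
    stop_hsi("reflectance cube contains non-finite values",
             class = "hsimoist_contract_error")
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  invisible(x)
}

conform_frame <- function(frame, dims, what) {
  if (is.null(dim(frame))) frame <- array(frame, dims)
  fd <- dim(frame)
  if (length(fd) == 3 && all(fd == dims)) return(frame)
  # 2-D frame (pixels-of-one-scanline x bands) replicated across rows
  if (length(fd) == 2 && fd[1] == dims[2] && fd[2] == dims[3])
    return(aperm(array(frame, c(fd, dims[1])), c(3, 1, 2)))
  stop_hsi(what, " frame shape does not conform to the cube",
           class = "hsimoist_contract_error")
}

#' Black/white reflectance correction
#'
#' Converts raw intensities to reflectance with the standard two-point
#' calibration `R = (I_raw - I_dark) / (I_white - I_dark)`, removing dark
#' current and illumination non-uniformity.
#'
#' @param raw a raw-kind [hypercube()].
#' @param white,dark reference frames: 3-D arrays matching the cube, or
#'   2-D (cols x bands) scanline references replicated across rows.
#' @return a reflectance-kind [hypercube()].
#' @export
reflectance_correct <- function(raw, white, dark) {
  stopifnot(inherits(raw, "hypercube"))
  dims <- dim(raw$data)
  white <- conform_frame(white, dims, "white")
  dark <- conform_frame(dark, dims, "dark")
  denom <- white - dark
  nbad <- sum(denom <= 0)
  if (nbad > 0)
    stop_hsi("white - dark is non-positive at ", nbad,
             " (pixel, band) elements", class = "hsimoist_calibration_error")
  hypercube((raw$data - dark) / denom, raw$wavelengths, kind = "reflectance")
}

#' Trim noisy spectral extremes
#'
#' Retains the contiguous block of bands whose wavelengths fall in
#' `[wl_lo, wl_hi]`. With both limits `NULL` and a 256-band axis, applies
#' the package default window: drop the first 21 and last 17 band indices,
#' retaining 218 interior bands (about 1068-2432 nm on the nominal grid) —
#' the spectral extremes of InGaAs/MCT line-scan acquisitions carry
#' strongly inflated noise.
#'
#' @param x a [hypercube()] or spectra matrix.
#' @param wl_lo,wl_hi retention window in nm (closed interval).
#' @return same type as `x`, band axis subset.
#' @export
trim_bands <- function(x, wl_lo = NULL, wl_hi = NULL) {
  wl <- wavelengths(x)
  if (is.null(wl_lo) && is.null(wl_hi)) {
    if (length(wl) != 256)
      stop_hsi("default trim window is defined for a 256-band axis; ",
               "pass wl_lo / wl_hi explicitly",
               class = "hsimoist_range_error")
    keep <- 22:239
  } else {
    if (is.null(wl_lo)) wl_lo <- min(wl)
    if (is.null(wl_hi)) wl_hi <- max(wl)
    if (wl_lo >= wl_hi)
      stop_hsi("wl_lo must be < wl_hi", class = "hsimoist_range_error")
    keep <- which(wl >= wl_lo & wl <= wl_hi)
    if (!length(keep))
      stop_hsi("no bands inside [", wl_lo, ", ", wl_hi, "] nm",
               class = "hsimoist_range_error")
  }
  if (inherits(x, "hypercube"))
    hypercube(x$data[, , keep, drop = FALSE], wl[keep], kind = x$kind)
  else
    spectra_matrix(x[, keep, drop = FALSE], wl[keep],
                   sample_ids = rownames(x))
}

#' Segment seeds and extract per-seed mean spectra
#'
#' Thresholds the band image nearest `contrast_wl` (Otsu by default),
#' labels connected foreground components, discards regions below
#' `min_area`, and averages the pixel spectra of each surviving region.
#'
#' @param cube a reflectance-kind [hypercube()].
#' @param contrast_wl wavelength (nm) of the contrast band; default 1100 nm
#'   (strong seed/background contrast, outside the deep water bands).
#' @param threshold `"otsu"` or a numeric reflectance cutoff.
#' @param min_area minimum region size in pixels (default 20).
#' @return `list(mask, spectra)`: integer label matrix (0 = background) and
#'   a spectra matrix with one mean spectrum per label.
#' @export
segment_seeds <- function(cube, contrast_wl = 1100, threshold = "otsu",
                          min_area = 20) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance")
    stop_hsi("segmentation requires a reflectance cube",
             class = "hsimoist_contract_error")
  b <- which.min(abs(cube$wavelengths - contrast_wl))
  img <- cube$data[, , b]
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (diff(rng) < .Machine$double.eps) {
      thr <- rng[1] + 1  # flat image: nothing above threshold
    } else {
      scaled <- (img - rng[1]) / diff(rng)
      thr <- rng[1] + diff(rng) * EBImage::otsu(EBImage::Image(scaled))
    }
  } else {
    thr <- as.numeric(threshold)
  }
  fgmask <- img > thr
  lab <- EBImage::bwlabel(EBImage::Image(fgmask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  if (!length(keep))
    stop_hsi("no seed regions found (threshold = ", signif(thr, 4), ")",
             class = "hsimoist_segmentation_error")
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  mask <- matrix(0L, nrow(img), ncol(img))
  mask[lab > 0L] <- relab[lab[lab > 0L]]
  flat <- matrix(cube$data, nrow(img) * ncol(img), dim(cube$data)[3])
  means <- t(vapply(seq_along(keep), function(s)
    colMeans(flat[which(mask == s), , drop = FALSE]),
    numeric(dim(cube$data)[3])))
  list(mask = mask,
       spectra = spectra_matrix(means, cube$wavelengths,
                                sample_ids = paste0("seed", seq_along(keep))))
}
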