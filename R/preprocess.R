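#' Specify a spectral pretreatment
#'
#' One dispatcher covers the seven pretreatments commonly compared for NIR
#' calibration transfer plus a pass-through: moving average and
#' Savitzky-Golay smoothing (noise), baseline and detrending (additive
#' trends), min-max normalization, SNV and MSC (multiplicative/additive
#' scatter).
#'
#' @param method one of `"none"`, `"moving_average"`, `"savitzky_golay"`,
#'   `"baseline"`, `"normalization"`, `"snv"`, `"msc"`, `"detrending"`.
#' @param window odd smoothing window length (default 7).
#' @param poly_order polynomial order for Savitzky-Golay and detrending
#'   (default 2).
#' @param msc_reference optional reference spectrum for MSC; when `NULL`
#'   the mean spectrum of the data being fitted is used (see
#'   [freeze_preprocess()] for leakage-free reuse on test data).
#' @param norm_variant `"minmax"` (default), `"unit"` (unit vector) or
#'   `"max"` normalization.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("none", "moving_average",
                                       "savitzky_golay", "baseline",
                                       "normalization", "snv", "msc",
                                       "detrending"),
                            window = 7, poly_order = 2,
                            msc_reference = NULL,
                            norm_variant = c("minmax", "unit", "max")) {
  method <- match.arg(method)
  norm_variant <- match.arg(norm_variant)
  if (method %in% c("moving_average", "savitzky_golay")) {
    if (window < 3 || window %% 2 == 0)
      stop_hsi("smoothing window must be odd and >= 3",
               class = "hsimoist_config_error")
  }
  if (method == "savitzky_golay" && poly_order >= window)
    stop_hsi("poly_order must be < window", class = "hsimoist_config_error")
  structure(list(method = method, window = as.integer(window),
                 poly_order = as.integer(poly_order),
                 msc_reference = msc_reference,
                 norm_variant = norm_variant),
            class = "preprocess_spec")
}

#' Freeze calibration-set statistics into a pretreatment spec
#'
#' MSC corrects each spectrum against a reference; that reference must be
#' learned on the calibration set only and reapplied unchanged to
#' validation, prediction and pixel spectra. This returns a copy of `spec`
#' with the calibration-set mean spectrum stored as the frozen reference
#' (a no-op for stateless methods).
#'
#' @param spec a [preprocess_spec()].
#' @param xcal calibration spectra matrix.
#' @return the frozen `preprocess_spec`.
#' @export
freeze_preprocess <- function(spec, xcal) {
  if (spec$method == "msc" && is.null(spec$msc_reference))
    spec$msc_reference <- colMeans(xcal)
  spec
}

#' Apply a spectral pretreatment
#'
#' All methods operate row-wise (per spectrum) and preserve the matrix
#' shape and wavelength axis.
#'
#' @param x spectra matrix.
#' @param spec a [preprocess_spec()].
#' @return pretreated spectra matrix.
#' @export
preprocess <- function(x, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  wl <- wavelengths(x)
  out <- switch(spec$method,
    none = x,
    moving_average = pp_moving_average(x, spec$window),
    savitzky_golay = t(apply(x, 1, function(r)
      signal::sgolayfilt(r, p = spec$poly_order, n = spec$window))),
    baseline = pp_baseline(x, wl),
    normalization = pp_normalize(x, spec$norm_variant),
    snv = pp_snv(x),
    msc = pp_msc(x, spec$msc_reference),
    detrending = pp_detrend(x, wl, spec$poly_order)
  )
  spectra_matrix(out, wl, sample_ids = rownames(x))
}

# centered window mean with window shrinkage at the edges
pp_moving_average <- function(x, window) {
  p <- ncol(x); h <- (window - 1L) %/% 2L
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  out <- x
  for (j in seq_len(p)) {
    lo <- max(1L, j - h); hi <- min(p, j + h)
    out[, j] <- (cs[, hi + 1L] - cs[, lo]) / (hi - lo + 1L)
  }
  out
}

# subtract the line through the two endpoint samples, then shift to min 0
pp_baseline <- function(x, wl) {
  p <- ncol(x)
  frac <- (wl - wl[1]) / (wl[p] - wl[1])
  line <- x[, 1] %o% (1 - frac) + x[, p] %o% frac
  out <- x - line
  out - apply(out, 1, min)
}

pp_normalize <- function(x, variant) {
  switch(variant,
    minmax = {
      lo <- apply(x, 1, min); hi <- apply(x, 1, max)
      if (any(hi - lo < 1e-12))
        stop_hsi("constant spectrum in row ",
                 which(hi - lo < 1e-12)[1], ": min-max scaling undefined",
                 class = "hsimoist_degenerate_error")
      (x - lo) / (hi - lo)
    },
    unit = x / sqrt(rowSums(x^2)),
    max = x / apply(x, 1, max)
  )
}

pp_snv <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  if (any(sdv < 1e-12))
    stop_hsi("zero spectral sd in row ", which(sdv < 1e-12)[1],
             ": SNV undefined", class = "hsimoist_degenerate_error")
  (x - mu) / sdv
}

pp_msc <- function(x, ref) {
  if (is.null(ref)) ref <- colMeans(x)
  rc <- ref - mean(ref)
  denom <- sum(rc^2)
  xc <- x - rowMeans(x)
  b <- as.numeric(xc %*% rc) / denom
  a <- rowMeans(x) - b * mean(ref)
  if (any(abs(b) < 1e-12))
    stop_hsi("degenerate MSC slope in row ", which(abs(b) < 1e-12)[1],
             class = "hsimoist_degenerate_error")
  (x - a) / b
}

pp_detrend <- function(x, wl, order) {
  basis <- cbind(1, stats::poly(wl, degree = order))
  # residuals of each spectrum regressed on the polynomial basis
  qrb <- qr(basis)
  t(apply(x, 1, function(r) qr.resid(qrb, r)))
}
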