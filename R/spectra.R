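#' Construct a spectra matrix
#'
#' The workhorse container of the package: a plain numeric matrix with one
#' row per sample and one column per spectral band. Wavelengths (nm) are
#' stored as column names so they survive subsetting; sample identifiers are
#' row names. All chemometric operations (preprocessing, SPXY splitting,
#' wavelength selection, model fitting) act on this representation.
#'
#' @param values numeric matrix, samples x bands.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per column.
#' @param sample_ids optional character vector of row labels.
#' @return a numeric matrix with wavelength column names.
#' @export
spectra_matrix <- function(values, wavelengths, sample_ids = NULL) {
  values <- as.matrix(values)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != ncol(values))
    stop_hsi("wavelength count (", length(wavelengths),
             ") does not match band count (", ncol(values), ")",
             class = "hsimoist_contract_error")
  if (any(diff(wavelengths) <= 0))
    stop_hsi("wavelengths must be strictly increasing",
             class = "hsimoist_contract_error")
  if (any(!is.finite(values)))
    stop_hsi("spectra contain non-finite values",
             class = "hsimoist_contract_error")
  if (is.null(sample_ids)) {
    if (is.null(rownames(values)))
      sample_ids <- paste0("s", seq_len(nrow(values)))
    else sample_ids <- rownames(values)
  }
  dimnames(values) <- list(sample_ids, as.character(wavelengths))
  values
}

#' Wavelength axis of a spectra matrix or hypercube
#'
#' @param x a spectra matrix (wavelengths in column names) or a
#'   [hypercube()].
#' @return numeric vector of wavelengths in nm.
#' @export
wavelengths <- function(x) {
  if (inherits(x, "hypercube")) return(x$wavelengths)
  wl <- suppressWarnings(as.numeric(colnames(x)))
  if (is.null(colnames(x)) || any(is.na(wl)))
    stop_hsi("object carries no numeric wavelength axis",
             class = "hsimoist_contract_error")
  wl
}

#' Write / read per-sample spectra as CSV
#'
#' Layout: first column `sample_id`, second column `moisture_pct`, remaining
#' columns named by wavelength in nm with one decimal.
#'
#' @param x spectra matrix.
#' @param moisture numeric vector of reference moisture (% wet basis).
#' @param path file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns `list(spectra, moisture)`.
#' @export
write_spectra_csv <- function(x, moisture, path) {
  stopifnot(length(moisture) == nrow(x))
  df <- data.frame(
    sample_id = rownames(x),
    moisture_pct = moisture,
    x, check.names = FALSE
  )
  colnames(df)[-(1:2)] <- sprintf("%.1f", wavelengths(x))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl <- as.numeric(colnames(df)[-(1:2)])
  x <- spectra_matrix(as.matrix(df[, -(1:2), drop = FALSE]), wl,
                      sample_ids = as.character(df$sample_id))
  list(spectra = x, moisture = as.numeric(df$moisture_pct))
}
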