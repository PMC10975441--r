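# Minimal ENVI header/binary reader-writer. The header is a plain-text
# "key = value" file; the binary holds IEEE floats/ints in BSQ, BIL or BIP
# interleave. Only the fields needed for reflectance cubes are handled.

envi_dtype <- function(code) {
  switch(as.character(code),
         "1" = list(what = "integer", size = 1, signed = FALSE),
         "2" = list(what = "integer", size = 2, signed = TRUE),
         "4" = list(what = "double", size = 4),
         "5" = list(what = "double", size = 8),
         "12" = list(what = "integer", size = 2, signed = FALSE),
         stop_hsi("unsupported ENVI data type ", code,
                  class = "hsimoist_io_error"))
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("^\\s*ENVI", txt))
    stop_hsi("not an ENVI header: ", path, class = "hsimoist_io_error")
  # join brace-delimited multi-line values, then split into key = value
  txt <- gsub("\\{([^}]*)\\}", "\\{\\1\\}", txt)
  lines <- strsplit(txt, "\n")[[1]][-1]
  joined <- character(0); buf <- ""
  for (ln in lines) {
    buf <- if (nzchar(buf)) paste(buf, ln) else ln
    nopen <- lengths(regmatches(buf, gregexpr("\\{", buf)))
    nclose <- lengths(regmatches(buf, gregexpr("\\}", buf)))
    if (nopen == nclose) { joined <- c(joined, buf); buf <- "" }
  }
  out <- list()
  for (ln in joined) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub("[{}]", "", val)
    out[[key]] <- trimws(val)
  }
  out
}

#' Read / write hyperspectral cubes in ENVI format
#'
#' `read_envi` expects `path` plus a header at `<path>.hdr` (or the path of
#' the header itself with the binary alongside). When the header lacks a
#' per-band `wavelength` list but gives nothing else, a linear grid between
#' `wl_start`/`wl_end` is assumed.
#'
#' @param path path to the binary file (header at `<path>.hdr`).
#' @param kind cube kind flag, `"reflectance"` (default) or `"raw"`.
#' @param wl_start,wl_end fallback wavelength grid endpoints (nm) when the
#'   header lists none.
#' @return a [hypercube()].
#' @export
read_envi <- function(path, kind = "reflectance",
                      wl_start = NULL, wl_end = NULL) {
  hdr_path <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  bin_path <- sub("\\.hdr$", "", path)
  hdr <- parse_envi_header(hdr_path)
  ns <- as.integer(hdr$samples); nl <- as.integer(hdr$lines)
  nb <- as.integer(hdr$bands)
  dt <- envi_dtype(hdr[["data type"]])
  interleave <- tolower(if (is.null(hdr$interleave)) "bsq" else hdr$interleave)
  n <- ns * nl * nb
  con <- file(bin_path, "rb"); on.exit(close(con))
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = if (dt$what == "integer") isTRUE(dt$signed) else TRUE,
                  endian = "little")
  # ENVI order: samples fastest, then (band|line) per interleave
  arr <- switch(interleave,
    bsq = aperm(array(vals, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(vals, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(vals, c(nb, ns, nl)), c(3, 2, 1)),
    stop_hsi("unknown interleave ", interleave, class = "hsimoist_io_error"))
  if (!is.null(hdr$wavelength)) {
    wl <- as.numeric(strsplit(hdr$wavelength, ",")[[1]])
  } else if (!is.null(wl_start) && !is.null(wl_end)) {
    wl <- seq(wl_start, wl_end, length.out = nb)
  } else {
    stop_hsi("header lists no wavelengths and no fallback grid was given",
             class = "hsimoist_io_error")
  }
  hypercube(arr, wl, kind = kind)
}

#' @rdname read_envi
#' @param cube a [hypercube()] to write.
#' @param interleave `"bil"` (default), `"bsq"` or `"bip"`.
#' @return `write_envi` returns `path` invisibly.
#' @export
write_envi <- function(cube, path, interleave = "bil") {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)  # rows(lines) x cols(samples) x bands
  arr <- switch(interleave,
    bsq = aperm(cube$data, c(2, 1, 3)),
    bil = aperm(cube$data, c(2, 3, 1)),
    bip = aperm(cube$data, c(3, 2, 1)),
    stop_hsi("unknown interleave ", interleave, class = "hsimoist_io_error"))
  con <- file(path, "wb")
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = {hsimoist cube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE),
                                   collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Write a label mask as a PNG image
#'
#' Labels are rendered as evenly spaced grey levels (background black).
#'
#' @param mask integer label matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  k <- max(mask)
  img <- if (k > 0) mask / k else mask
  png::writePNG(img, path)
  invisible(path)
}
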