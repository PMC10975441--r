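#' Pixel-wise moisture prediction over a hypercube
#'
#' Runs every foreground pixel spectrum through the same frozen pipeline as
#' the calibration spectra — pretreatment (with calibration-set statistics,
#' e.g. the MSC reference), restriction to the selected bands, model
#' prediction — and assembles a per-pixel moisture map. Pixels whose
#' spectrum is degenerate under the pretreatment (e.g. constant, so SNV or
#' min-max scaling is undefined) are flagged invalid rather than aborting
#' the map.
#'
#' @param cube a reflectance-kind [hypercube()] already trimmed to the band
#'   axis the pretreatment was trained on.
#' @param model an [fit_model()] result.
#' @param spec the frozen [preprocess_spec()] used for calibration.
#' @param selection a `selection_result`, band index vector, or `NULL` for
#'   the full axis.
#' @param mask logical or integer matrix marking foreground pixels;
#'   `NULL` segments nothing and treats every pixel as foreground.
#' @return object of class `moisture_map`: list with `values` (moisture %,
#'   NA on background/invalid), `mask`, `color_range` (default 0-12 %),
#'   and `n_invalid`.
#' @export
predict_map <- function(cube, model, spec, selection = NULL, mask = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "hsi_model"))
  if (cube$kind != "reflectance")
    stop_hsi("predict_map requires a reflectance cube",
             class = "hsimoist_contract_error")
  d <- dim(cube$data)
  idx <- if (is.null(selection)) seq_along(cube$wavelengths)
         else if (inherits(selection, "selection_result")) selection$selected_idx
         else as.integer(selection)
  if (max(idx) > length(cube$wavelengths) ||
      length(model$wavelengths) != length(idx) ||
      any(abs(cube$wavelengths[idx] - model$wavelengths) > 1e-3))
    stop_hsi("cube band axis does not match the model's training wavelengths",
             class = "hsimoist_contract_error")

  fg <- if (is.null(mask)) matrix(TRUE, d[1], d[2]) else mask > 0
  vals <- matrix(NA_real_, d[1], d[2])
  n_invalid <- 0L
  pix <- which(fg)
  if (length(pix)) {
    flat <- matrix(cube$data, d[1] * d[2], d[3])[pix, , drop = FALSE]
    flat <- spectra_matrix(flat, cube$wavelengths)
    ok <- rep(TRUE, nrow(flat))
    pp <- tryCatch(preprocess(flat, spec), error = function(e) NULL)
    if (is.null(pp)) {
      # at least one degenerate pixel: fall back to row-wise application
      pp <- matrix(NA_real_, nrow(flat), ncol(flat))
      for (i in seq_len(nrow(flat))) {
        row_pp <- tryCatch(
          preprocess(flat[i, , drop = FALSE], spec),
          error = function(e) NULL)
        if (is.null(row_pp)) ok[i] <- FALSE else pp[i, ] <- row_pp
      }
      colnames(pp) <- colnames(flat)
      n_invalid <- sum(!ok)
    }
    if (any(ok)) {
      sub <- pp[ok, idx, drop = FALSE]
      vals[pix[ok]] <- predict(model, sub)
    }
  } else {
    warning("moisture map has zero foreground pixels")
  }
  structure(list(values = vals, mask = fg, color_range = c(0, 12),
                 n_invalid = n_invalid),
            class = "moisture_map")
}

#' @export
print.moisture_map <- function(x, ...) {
  cat(sprintf("<moisture map> %d x %d px, %d predicted (%d invalid), range %.2f-%.2f%%\n",
              nrow(x$values), ncol(x$values), sum(!is.na(x$values)),
              x$n_invalid,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

# continuous jet-like ramp used for pseudo-colour rendering
hsi_colormaps <- list(
  jet = c("#00007F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
          "#FFFF00", "#FF7F00", "#FF0000", "#7F0000"),
  viridis = c("#440154", "#46327E", "#365C8D", "#277F8E", "#1FA187",
              "#4AC16D", "#A0DA39", "#FDE725")
)

#' Position of moisture values on the colour axis
#'
#' Linear map of `values` from `color_range` onto `[0, 1]`, clamped.
#'
#' @param values moisture values (%).
#' @param color_range c(lo, hi) rendering range (%).
#' @return positions in `[0, 1]`.
#' @export
color_position <- function(values, color_range = c(0, 12)) {
  pmin(1, pmax(0, (values - color_range[1]) / diff(color_range)))
}

#' Render a moisture map as a pseudo-colour RGB image
#'
#' Values are mapped linearly from `map$color_range` onto the colormap
#' (out-of-range pixels clamped and counted); background pixels render as
#' neutral grey.
#'
#' @param map a [predict_map()] result.
#' @param colormap `"jet"` (default) or `"viridis"`.
#' @param file optional PNG output path; a vertical colour bar annotated in
#'   % moisture is appended on the right.
#' @return object of class `rendered_map`: list with `rgb` (rows x cols x
#'   3 array in `[0, 1]`), `n_clamped`, and the `color_range`.
#' @export
render_map <- function(map, colormap = "jet", file = NULL) {
  stopifnot(inherits(map, "moisture_map"))
  pal <- hsi_colormaps[[colormap]]
  if (is.null(pal)) stop_hsi("unknown colormap ", colormap,
                             class = "hsimoist_config_error")
  ramp <- colorRamp(pal)
  d <- dim(map$values)
  rgb_arr <- array(0.2, dim = c(d, 3))  # neutral background
  fg <- which(!is.na(map$values))
  lo <- map$color_range[1]; hi <- map$color_range[2]
  n_clamped <- sum(map$values[fg] < lo | map$values[fg] > hi)
  if (length(fg)) {
    pos <- color_position(map$values[fg], map$color_range)
    cols <- ramp(pos) / 255
    for (ch in 1:3) {
      plane <- rgb_arr[, , ch]
      plane[fg] <- cols[, ch]
      rgb_arr[, , ch] <- plane
    }
  }
  out <- structure(list(rgb = rgb_arr, n_clamped = n_clamped,
                        color_range = map$color_range,
                        colormap = colormap),
                   class = "rendered_map")
  if (!is.null(file)) {
    bar <- render_colorbar(ramp, d[1], width = max(6L, d[2] %/% 10))
    png::writePNG(abind3(rgb_arr, bar), file)
  }
  out
}

# simple vertical colour bar (high values at the top)
render_colorbar <- function(ramp, height, width) {
  pos <- seq(1, 0, length.out = height)
  cols <- ramp(pos) / 255
  bar <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) bar[, , ch] <- matrix(cols[, ch], height, width)
  # one-pixel white separator
  bar[, 1, ] <- 1
  bar
}

abind3 <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1], dim(a)[2] + dim(b)[2], 3))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}

#' Export a moisture map as a single-band ENVI file
#'
#' @param map a [predict_map()] result.
#' @param path output path (background pixels written as -1).
#' @return `path`, invisibly.
#' @export
write_map_envi <- function(map, path) {
  vals <- map$values
  vals[is.na(vals)] <- -1
  cube <- hypercube(array(vals, dim = c(dim(vals), 1)), 1, kind = "raw")
  write_envi(cube, path, interleave = "bsq")
  invisible(path)
}
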