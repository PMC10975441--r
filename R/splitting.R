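#' SPXY calibration/prediction sample partitioning
#'
#' Kennard-Stone selection on the joint X-Y distance
#' `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)`, where `dx` is the
#' Euclidean distance between spectra and `dy` the absolute moisture
#' difference. The two most distant samples seed the calibration set; the
#' sample whose minimum distance to the selected set is largest is then
#' added repeatedly until `round(calib_fraction * n)` samples are chosen.
#' Deterministic — no RNG; distance ties are broken toward the lowest
#' sample index.
#'
#' @param x spectra matrix (samples x bands).
#' @param y moisture vector, one value per sample.
#' @param calib_fraction fraction of samples assigned to the calibration
#'   set (default 0.75, i.e. 60 of 80).
#' @return object of class `split_result`: list with sorted
#'   `calibration_idx`, `prediction_idx`, the selection `order`, and
#'   `ratio`.
#' @export
spxy_split <- function(x, y, calib_fraction = 0.75) {
  n <- nrow(x)
  if (n < 3) stop_hsi("need at least 3 samples", class = "hsimoist_contract_error")
  if (length(y) != n)
    stop_hsi("y length does not match sample count",
             class = "hsimoist_contract_error")
  if (calib_fraction <= 0 || calib_fraction >= 1)
    stop_hsi("calib_fraction must be in (0, 1)",
             class = "hsimoist_contract_error")
  dx <- as.matrix(dist(x))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0)
    stop_hsi("all samples identical in X and y: SPXY undefined",
             class = "hsimoist_degenerate_error")
  d <- (if (mx > 0) dx / mx else 0) + (if (my > 0) dy / my else 0)

  ncal <- round(calib_fraction * n)
  ncal <- max(2L, min(n - 1L, as.integer(ncal)))
  # seed pair: maximal joint distance, lowest linear index on ties
  sel <- integer(ncal)
  seedlin <- which.max(d)  # column-major first maximum
  sel[1:2] <- sort(c((seedlin - 1L) %% n + 1L, (seedlin - 1L) %/% n + 1L))
  mind <- pmin(d[, sel[1]], d[, sel[2]])
  mind[sel[1:2]] <- -Inf
  k <- 2L
  while (k < ncal) {
    k <- k + 1L
    nxt <- which.max(mind)  # lowest index on ties
    sel[k] <- nxt
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  structure(list(
    calibration_idx = sort(sel),
    prediction_idx = setdiff(seq_len(n), sel),
    order = sel,
    ratio = calib_fraction
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<SPXY split> %d calibration / %d prediction (fraction %.2f)\n",
              length(x$calibration_idx), length(x$prediction_idx), x$ratio))
  invisible(x)
}

#' Write a sample split as CSV
#'
#' @param split a [spxy_split()] result.
#' @param sample_ids character vector of sample labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, sample_ids, path) {
  n <- length(split$calibration_idx) + length(split$prediction_idx)
  subset <- rep("prediction", n)
  subset[split$calibration_idx] <- "calibration"
  write.csv(data.frame(sample_id = sample_ids, subset = subset),
            path, row.names = FALSE)
  invisible(path)
}
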