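#' Configuration for the synthetic seed-spectra generator
#'
#' Defines the generative model used throughout the package's validation
#' suite: Beer-Lambert style reflectance with Gaussian water-absorption
#' features near 1450 nm (O-H first overtone) and 1940 nm (O-H combination
#' band) whose depth scales linearly with moisture, a smooth polynomial
#' absorbance baseline, per-sample multiplicative/additive scatter, and
#' heteroscedastic detector noise inflated at the spectral extremes.
#'
#' Defaults mirror the acquisition geometry the package targets: 256 bands
#' on a linear grid over 935.5-2539 nm and reference moisture spanning
#' 7.377-11.993 % wet basis.
#'
#' @param n_samples number of samples (seed varieties) to generate.
#' @param n_bands number of spectral bands (default 256).
#' @param wl_start,wl_end wavelength grid endpoints in nm.
#' @param moisture_min,moisture_max moisture range, % wet basis.
#' @param peak_centers water absorption band centres, nm.
#' @param peak_widths Gaussian widths (sd) of the absorption bands, nm.
#' @param peak_gain absorbance added per % moisture at a peak centre.
#' @param baseline_coeffs polynomial coefficients (increasing order) of the
#'   absorbance baseline in the normalised wavelength u = (wl - wl_start) /
#'   (wl_end - wl_start).
#' @param scatter_slope_sd sd of the per-sample multiplicative scatter
#'   factor (mean 1).
#' @param scatter_offset_sd sd of the per-sample additive offset (mean 0).
#' @param noise_sd sd of additive reflectance noise in the interior bands.
#' @param edge_noise_factor multiplier (>= 1) applied to noise_sd in the
#'   noise-afflicted spectral extremes (first and last ~7.5% of bands,
#'   about 15% of the axis in total).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 80,
                             n_bands = 256,
                             wl_start = 935.5, wl_end = 2539,
                             moisture_min = 7.377, moisture_max = 11.993,
                             peak_centers = c(1450, 1940),
                             peak_widths = c(45, 60),
                             peak_gain = 0.06,
                             baseline_coeffs = c(0.45, 0.4, 0.9),
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             noise_sd = 0.005,
                             edge_noise_factor = 5,
                             seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_bands = as.integer(n_bands),
    wl_start = wl_start, wl_end = wl_end,
    moisture_min = moisture_min, moisture_max = moisture_max,
    peak_centers = peak_centers, peak_widths = peak_widths,
    peak_gain = peak_gain, baseline_coeffs = baseline_coeffs,
    scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd,
    noise_sd = noise_sd, edge_noise_factor = edge_noise_factor,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  bad <- function(field, why)
    stop_hsi("invalid synthetic config field `", field, "`: ", why,
             class = "hsimoist_config_error")
  if (cfg$n_samples < 1) bad("n_samples", "must be >= 1")
  if (cfg$n_bands < 2) bad("n_bands", "must be >= 2")
  if (!(cfg$wl_start < cfg$wl_end)) bad("wl_start", "wl_start must be < wl_end")
  if (!(cfg$moisture_min < cfg$moisture_max))
    bad("moisture_min", "moisture_min must be < moisture_max")
  if (length(cfg$peak_centers) != length(cfg$peak_widths))
    bad("peak_widths", "one width per peak centre required")
  if (any(cfg$peak_centers < cfg$wl_start | cfg$peak_centers > cfg$wl_end))
    bad("peak_centers", "all peak centres must lie inside [wl_start, wl_end]")
  if (any(cfg$peak_widths <= 0)) bad("peak_widths", "must be positive")
  if (cfg$edge_noise_factor < 1) bad("edge_noise_factor", "must be >= 1")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be >= 0")
  invisible(cfg)
}

#' Read a synthetic configuration from YAML
#'
#' @param path path to a YAML file whose keys match the arguments of
#'   [synthetic_config()].
#' @return object of class `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  do.call(synthetic_config, yaml::read_yaml(path))
}

wavelength_grid <- function(cfg) {
  seq(cfg$wl_start, cfg$wl_end, length.out = cfg$n_bands)
}

# Noiseless absorbance for moisture m (vector) on wavelength grid wl:
# baseline polynomial plus moisture-scaled sum of unit-height Gaussians.
synthetic_absorbance <- function(cfg, m, wl = wavelength_grid(cfg)) {
  u <- (wl - cfg$wl_start) / (cfg$wl_end - cfg$wl_start)
  base <- rep(0, length(wl))
  for (j in seq_along(cfg$baseline_coeffs))
    base <- base + cfg$baseline_coeffs[j] * u^(j - 1)
  pk <- rep(0, length(wl))
  for (k in seq_along(cfg$peak_centers))
    pk <- pk + exp(-0.5 * ((wl - cfg$peak_centers[k]) / cfg$peak_widths[k])^2)
  outer(rep(1, length(m)), base) + cfg$peak_gain * outer(m, pk)
}

# Noise-inflated spectral extremes: ~15% of the axis in total, split as
# the first ~8.2% and last ~6.6% of bands — exactly the sections the
# default trim window excises on a 256-band axis (21 head / 17 tail).
edge_band_mask <- function(n_bands, head_frac = 21 / 256,
                           tail_frac = 17 / 256) {
  kh <- floor(head_frac * n_bands)
  kt <- floor(tail_frac * n_bands)
  mask <- rep(FALSE, n_bands)
  if (kh > 0) mask[seq_len(kh)] <- TRUE
  if (kt > 0) mask[n_bands - seq_len(kt) + 1] <- TRUE
  mask
}

#' Generate synthetic seed spectra with reference moisture
#'
#' Draws moisture uniformly over the configured range, builds noiseless
#' absorbance via the Beer-Lambert model of [synthetic_config()], converts
#' to reflectance `slope_i * exp(-a) + offset_i + noise`, and clips to
#' (0, 1.5]. Deterministic for a given config (seed included).
#'
#' @param config a [synthetic_config()].
#' @return `list(spectra, moisture)`: a spectra matrix (samples x bands)
#'   and the moisture vector (% wet basis).
#' @export
generate_spectra <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_bands
    wl <- wavelength_grid(config)
    m <- runif(n, config$moisture_min, config$moisture_max)
    a <- synthetic_absorbance(config, m, wl)
    slope <- rnorm(n, 1, config$scatter_slope_sd)
    offset <- rnorm(n, 0, config$scatter_offset_sd)
    eps <- matrix(rnorm(n * p, 0, config$noise_sd), n, p)
    edge <- edge_band_mask(p)
    eps[, edge] <- eps[, edge] * config$edge_noise_factor
    r <- slope * exp(-a) + offset + eps
    r <- pmin(pmax(r, 1e-6), 1.5)
    list(spectra = spectra_matrix(r, wl), moisture = m)
  })
}

#' Generate a small synthetic hyperspectral scene of seeds
#'
#' Places `n_seeds` non-overlapping elliptical seed regions on a dark
#' background, assigns each region one moisture value (optionally jittered
#' within the seed), generates per-pixel reflectance spectra with the same
#' model as [generate_spectra()], and synthesises raw/white/dark frames so
#' that [reflectance_correct()] recovers the reflectance cube exactly.
#'
#' @param config a [synthetic_config()]; `n_samples` is ignored.
#' @param n_seeds number of seed regions.
#' @param image_shape integer c(rows, cols).
#' @param within_seed_sd sd of optional per-pixel moisture jitter inside a
#'   seed (default 0: uniform seeds).
#' @return object of class `synthetic_scene`: list with `cube` (reflectance
#'   [hypercube()]), `raw`, `white_frame`, `dark_frame` (raw-intensity
#'   arrays), `seed_mask` (integer labels, 0 = background), `truth_map`
#'   (per-pixel moisture, NA on background) and `seed_moisture`.
#' @export
generate_scene <- function(config, n_seeds, image_shape = c(64, 64),
                           within_seed_sd = 0) {
  validate_synthetic_config(config)
  nr <- image_shape[1]; nc <- image_shape[2]
  with_seed(config$seed, {
    wl <- wavelength_grid(config)
    p <- config$n_bands

    # place non-overlapping ellipses with bounded retries
    mask <- matrix(0L, nr, nc)
    centers <- matrix(NA_real_, n_seeds, 2)
    placed <- 0L; tries <- 0L
    a_ax <- max(3, round(nr / 10)); b_ax <- max(2, round(nc / 14))
    rowg <- matrix(seq_len(nr), nr, nc)
    colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    while (placed < n_seeds && tries < 500L) {
      tries <- tries + 1L
      cy <- runif(1, a_ax + 1, nr - a_ax)
      cx <- runif(1, b_ax + 1, nc - b_ax)
      ell <- ((rowg - cy) / a_ax)^2 + ((colg - cx) / b_ax)^2 <= 1
      if (any(mask[ell] != 0L)) next
      # one-pixel moat so components stay separable
      moat <- ((rowg - cy) / (a_ax + 1.5))^2 + ((colg - cx) / (b_ax + 1.5))^2 <= 1
      if (any(mask[moat & !ell] != 0L)) next
      placed <- placed + 1L
      mask[ell] <- placed
      centers[placed, ] <- c(cy, cx)
    }
    if (placed < n_seeds)
      stop_hsi("could not place ", n_seeds, " non-overlapping seeds on a ",
               nr, "x", nc, " grid", class = "hsimoist_capacity_error")

    seed_m <- runif(n_seeds, config$moisture_min, config$moisture_max)
    truth <- matrix(NA_real_, nr, nc)
    for (s in seq_len(n_seeds)) {
      idx <- which(mask == s)
      mm <- rep(seed_m[s], length(idx))
      if (within_seed_sd > 0) {
        mm <- mm + rnorm(length(idx), 0, within_seed_sd)
        mm <- pmin(pmax(mm, config$moisture_min), config$moisture_max)
      }
      truth[idx] <- mm
    }

    # per-pixel reflectance: seeds via the generative model, background dark
    cube_data <- array(0, dim = c(nr, nc, p))
    fg <- which(!is.na(truth))
    if (length(fg)) {
      a <- synthetic_absorbance(config, truth[fg], wl)
      slope <- rnorm(length(fg), 1, config$scatter_slope_sd)
      offset <- rnorm(length(fg), 0, config$scatter_offset_sd)
      eps <- matrix(rnorm(length(fg) * p, 0, config$noise_sd), length(fg), p)
      edge <- edge_band_mask(p)
      eps[, edge] <- eps[, edge] * config$edge_noise_factor
      rfl <- pmin(pmax(slope * exp(-a) + offset + eps, 1e-6), 1.5)
    }
    bg <- which(is.na(truth))
    bg_r <- matrix(pmin(pmax(
      0.03 + rnorm(length(bg) * p, 0, config$noise_sd), 1e-6), 1.5),
      length(bg), p)
    flat <- matrix(0, nr * nc, p)
    if (length(fg)) flat[fg, ] <- rfl
    flat[bg, ] <- bg_r
    cube_data[] <- flat

    # invert the black/white correction with a smooth illumination model
    white_shape <- 3000 + 1000 * sin(seq(0.3, 2.6, length.out = p))
    white <- array(rep(white_shape, each = nr * nc), dim = c(nr, nc, p))
    dark <- array(100, dim = c(nr, nc, p))
    raw_data <- dark + cube_data * (white - dark)

    cube <- hypercube(cube_data, wl, kind = "reflectance")
    list2scene <- structure(list(
      cube = cube,
      raw = hypercube(raw_data, wl, kind = "raw"),
      white_frame = white, dark_frame = dark,
      seed_mask = mask, truth_map = truth,
      seed_moisture = seed_m
    ), class = "synthetic_scene")
    list2scene
  })
}
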