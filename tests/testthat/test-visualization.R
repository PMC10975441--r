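# End-to-end fixtures: a trained pipeline matched to a synthetic scene.
train_pipeline <- function(cfg, method = "normalization", n_train = 60,
                           use_spa = TRUE) {
  tcfg <- cfg; tcfg$n_samples <- as.integer(n_train)
  g <- generate_spectra(tcfg)
  spec <- freeze_preprocess(preprocess_spec(method), g$spectra)
  xp <- preprocess(g$spectra, spec)
  sel <- if (use_spa) spa_select(xp, g$moisture, n_max = 10) else NULL
  idx <- if (is.null(sel)) seq_len(ncol(xp)) else sel$selected_idx
  cv <- cross_validate("plsr", xp[, idx], g$moisture,
                       components_grid = 1:8)
  model <- fit_model("plsr", xp[, idx], g$moisture, ncomp = cv$best_ncomp)
  list(model = model, spec = spec, selection = sel)
}

test_that("a uniform noiseless seed maps to a constant moisture value", {
  cfg <- fast_config(seed = 31, noise_sd = 0, scatter_slope_sd = 0,
                     scatter_offset_sd = 0)
  tp <- train_pipeline(cfg, use_spa = FALSE)
  sc <- generate_scene(cfg, n_seeds = 1, image_shape = c(32, 32))
  map <- predict_map(sc$cube, tp$model, tp$spec, mask = sc$seed_mask)
  vals <- map$values[sc$seed_mask == 1]
  expect_lt(diff(range(vals)), 1e-6)
  expect_true(all(is.na(map$values[sc$seed_mask == 0])))
})

test_that("per-seed mean predictions recover ground truth on a noiseless scene", {
  cfg <- fast_config(seed = 32, noise_sd = 0)
  tp <- train_pipeline(cfg)
  sc <- generate_scene(cfg, n_seeds = 4, image_shape = c(64, 64))
  map <- predict_map(sc$cube, tp$model, tp$spec, selection = tp$selection,
                     mask = sc$seed_mask)
  for (s in 1:4) {
    est <- mean(map$values[sc$seed_mask == s])
    expect_lt(abs(est - sc$seed_moisture[s]), 0.3)
  }
})

test_that("a constant cube returns the model's prediction at every pixel", {
  cfg <- fast_config(seed = 33)
  tp <- train_pipeline(cfg, use_spa = FALSE)
  g <- generate_spectra(fast_config(seed = 99, n_samples = 2))
  row1 <- g$spectra[1, ]
  cube <- hypercube(array(rep(row1, each = 12 * 10), dim = c(12, 10, 64)),
                    wavelengths(g$spectra), kind = "reflectance")
  map <- predict_map(cube, tp$model, tp$spec)
  direct <- predict(tp$model, preprocess(g$spectra[1, , drop = FALSE],
                                         tp$spec))
  expect_lt(max(abs(map$values - direct)), 1e-8)
})

test_that("an all-background mask yields an empty map with a warning", {
  cfg <- fast_config(seed = 34)
  tp <- train_pipeline(cfg, use_spa = FALSE)
  sc <- generate_scene(cfg, n_seeds = 1, image_shape = c(32, 32))
  expect_warning(
    map <- predict_map(sc$cube, tp$model, tp$spec,
                       mask = matrix(0L, 32, 32)),
    "zero foreground")
  expect_equal(sum(!is.na(map$values)), 0L)
})

test_that("a mismatched band axis is a contract error", {
  cfg <- fast_config(seed = 35)
  tp <- train_pipeline(cfg, use_spa = FALSE)
  sc <- generate_scene(cfg, n_seeds = 1, image_shape = c(32, 32))
  shifted <- hypercube(sc$cube$data, sc$cube$wavelengths + 5,
                       kind = "reflectance")
  expect_error(predict_map(shifted, tp$model, tp$spec),
               class = "hsimoist_contract_error")
})

fake_map <- function(vals, lo = 0, hi = 12) {
  structure(list(values = vals, mask = !is.na(vals),
                 color_range = c(lo, hi), n_invalid = 0L),
            class = "moisture_map")
}

test_that("rendering endpoints hit the first and last colormap entries", {
  m <- fake_map(matrix(c(0, 12, NA), 1, 3))
  r <- render_map(m, "jet")
  pal <- hsimoist:::hsi_colormaps$jet
  first <- grDevices::col2rgb(pal[1]) / 255
  last <- grDevices::col2rgb(pal[length(pal)]) / 255
  expect_equal(as.numeric(r$rgb[1, 1, ]), as.numeric(first), tolerance = 1e-6)
  expect_equal(as.numeric(r$rgb[1, 2, ]), as.numeric(last), tolerance = 1e-6)
  expect_equal(as.numeric(r$rgb[1, 3, ]), rep(0.2, 3))  # background neutral
})

test_that("the colour-axis position is monotone in moisture", {
  vals <- seq(-1, 13, by = 0.5)
  pos <- color_position(vals)
  expect_true(all(diff(pos) >= 0))
  expect_equal(pos[1], 0)       # clamped below
  expect_equal(pos[length(pos)], 1)  # clamped above
})

test_that("seeds at 7.45% and 11.53% moisture render clearly apart", {
  pos <- color_position(c(7.45, 11.53), c(0, 12))
  expect_gt(abs(diff(pos)), 0.25)
})

test_that("out-of-range pixels are clamped and counted", {
  m <- fake_map(matrix(c(-2, 5, 13, 8), 2, 2))
  r <- render_map(m)
  expect_equal(r$n_clamped, 2L)
  path <- withr::local_tempfile(fileext = ".png")
  render_map(m, file = path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_equal(dim(img)[1], 2L)
})
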