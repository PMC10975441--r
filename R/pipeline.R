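#' Pipeline configuration
#'
#' Bundles every stage parameter of the full calibration study. All
#' randomness is behind explicit seeds; rerunning an identical config
#' reproduces every output bit for bit.
#'
#' @param synthetic a [synthetic_config()] (the study's data source), or
#'   `NULL` when `spectra`/`moisture` are supplied directly.
#' @param spectra,moisture pre-loaded data, used when `synthetic` is NULL.
#' @param trim `"default"` (256 -> 218 interior bands), `NULL` (no trim) or
#'   c(wl_lo, wl_hi) in nm.
#' @param preprocess_method `"auto"` (pick the pretreatment-comparison
#'   winner by RMSECV) or a method name accepted by [preprocess_spec()].
#' @param split_fraction SPXY calibration fraction (default 0.75).
#' @param selection_methods subset of `c("spa", "cars", "uve")`; the full
#'   band axis is always evaluated alongside.
#' @param model_kinds subset of `c("plsr", "pcr", "svmr")`.
#' @param cv scheme for component choice, `"loo"` (default) or `"kfold"`.
#' @param max_comp latent-variable cap (default 15).
#' @param seed master seed for the stochastic stages (CARS, UVE noise,
#'   SVR tuning).
#' @param out_dir optional directory; when set, tables, selections, the
#'   split and a stage log are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            spectra = NULL, moisture = NULL,
                            trim = "default",
                            preprocess_method = "normalization",
                            split_fraction = 0.75,
                            selection_methods = c("spa", "cars", "uve"),
                            model_kinds = c("plsr", "pcr", "svmr"),
                            cv = "loo", max_comp = 15,
                            seed = 1L, out_dir = NULL) {
  if (is.null(synthetic) && (is.null(spectra) || is.null(moisture)))
    stop_hsi("either a synthetic config or spectra + moisture are required",
             class = "hsimoist_config_error")
  if (!length(model_kinds))
    stop_hsi("at least one model kind is required",
             class = "hsimoist_config_error")
  structure(list(synthetic = synthetic, spectra = spectra,
                 moisture = moisture, trim = trim,
                 preprocess_method = preprocess_method,
                 split_fraction = split_fraction,
                 selection_methods = selection_methods,
                 model_kinds = model_kinds, cv = cv,
                 max_comp = max_comp, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_data <- function(config) {
  if (!is.null(config$synthetic)) {
    gen <- generate_spectra(config$synthetic)
    x <- gen$spectra; y <- gen$moisture
  } else {
    x <- config$spectra; y <- config$moisture
  }
  if (is.character(config$trim) && identical(config$trim, "default")) {
    x <- trim_bands(x)
  } else if (is.numeric(config$trim)) {
    x <- trim_bands(x, config$trim[1], config$trim[2])
  }
  list(x = x, y = y)
}

#' Compare spectral pretreatments under a PLSR model
#'
#' Fits a PLSR model after each of the seven pretreatments plus
#' no-pretreatment, choosing the latent-variable count by leave-one-out
#' cross-validation, and reports calibration and cross-validation
#' statistics. The winner (minimal RMSECV) is recorded in the
#' `"winner"` attribute.
#'
#' @param x calibration spectra matrix (trimmed).
#' @param y moisture vector.
#' @param methods pretreatments to compare (default: all seven + none).
#' @param max_comp latent-variable cap (default 15).
#' @return data.frame with columns `method`, `PCs`, `RC2`, `RMSEC`,
#'   `RCV2`, `RMSECV`; attribute `winner` holds the minimal-RMSECV method.
#' @export
run_preprocess_comparison <- function(x, y,
                                      methods = c("none", "moving_average",
                                                  "savitzky_golay",
                                                  "normalization", "baseline",
                                                  "snv", "msc", "detrending"),
                                      max_comp = 15) {
  rows <- lapply(methods, function(m) {
    spec <- freeze_preprocess(preprocess_spec(m), x)
    xp <- preprocess(x, spec)
    cv <- cross_validate("plsr", xp, y, scheme = "loo",
                         components_grid =
                           seq_len(min(max_comp, ncol(xp), nrow(xp) - 2L)))
    model <- fit_model("plsr", xp, y, ncomp = cv$best_ncomp)
    fitted <- predict(model, xp)
    data.frame(method = m, PCs = cv$best_ncomp,
               RC2 = r_squared(y, fitted), RMSEC = rmse(y, fitted),
               RCV2 = cv$rcv2, RMSECV = cv$rmsecv)
  })
  out <- do.call(rbind, rows)
  attr(out, "winner") <- out$method[which.min(out$RMSECV)]
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Run the full calibration study
#'
#' Orchestrates trim -> pretreatment (configured, or the
#' pretreatment-comparison winner) -> SPXY split -> wavelength selection
#' (full axis plus the configured selectors) x model kinds ->
#' evaluation report. Stage parameters and durations are logged; with an
#' `out_dir`, tables, selections and the split are written to disk.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return list with `report` (the selection x model [evaluate_grid()]
#'   table), `preprocess_table` (when `preprocess_method = "auto"`),
#'   `split`, `selections`, `preprocess_spec`, `models` (the per-cell
#'   fitted models of the best row), and `data`.
#' @export
run_full_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  dat <- pipeline_data(config)
  say("data: %d samples x %d bands", nrow(dat$x), ncol(dat$x))

  pp_table <- NULL
  method <- config$preprocess_method
  if (identical(method, "auto")) {
    pp_table <- run_preprocess_comparison(dat$x, dat$y,
                                          max_comp = config$max_comp)
    method <- attr(pp_table, "winner")
    say("pretreatment winner by RMSECV: %s", method)
  }

  split <- spxy_split(dat$x, dat$y, config$split_fraction)
  say("SPXY split: %d calibration / %d prediction",
      length(split$calibration_idx), length(split$prediction_idx))

  spec <- freeze_preprocess(preprocess_spec(method),
                            dat$x[split$calibration_idx, , drop = FALSE])
  xall <- preprocess(dat$x, spec)
  xcal <- xall[split$calibration_idx, , drop = FALSE]
  ycal <- dat$y[split$calibration_idx]
  xpred <- xall[split$prediction_idx, , drop = FALSE]
  ypred <- dat$y[split$prediction_idx]

  selections <- list(full = NULL)
  for (m in config$selection_methods) {
    sel <- switch(m,
      spa = spa_select(xcal, ycal),
      cars = cars_select(xcal, ycal, seed = config$seed),
      uve = uve_select(xcal, ycal,
                       n_latent = min(12L, nrow(xcal) - 2L),
                       seed = config$seed),
      stop_hsi("unknown selection method ", m,
               class = "hsimoist_config_error"))
    selections[[m]] <- sel
    say("%s selected %d of %d bands (%.1f%%)", m,
        length(sel$selected_idx), ncol(xcal),
        selected_fraction(length(sel$selected_idx), ncol(xcal)))
  }

  report <- evaluate_grid(xcal, ycal, xpred, ypred,
                          selections = selections,
                          kinds = config$model_kinds,
                          scheme = config$cv, max_comp = config$max_comp,
                          seed = config$seed)
  best_row <- report[which.min(report$RMSEP), ]
  say("best cell by RMSEP: %s-%s (RMSEP %.4f)", best_row$selection,
      best_row$model, best_row$RMSEP)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(config$out_dir, "model_grid.csv"))
    write_report(report, file.path(config$out_dir, "model_grid.md"),
                 format = "markdown")
    if (!is.null(pp_table))
      write_report(pp_table, file.path(config$out_dir, "preprocess_table.csv"))
    write_split_csv(split, rownames(dat$x),
                    file.path(config$out_dir, "split.csv"))
    for (m in names(selections)[-1])
      write_selection_json(selections[[m]],
                           file.path(config$out_dir,
                                     paste0("selection_", m, ".json")))
  }
  say("total %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  list(report = report, preprocess_table = pp_table, split = split,
       selections = selections, preprocess_spec = spec,
       best = best_row,
       data = list(xcal = xcal, ycal = ycal, xpred = xpred, ypred = ypred))
}
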