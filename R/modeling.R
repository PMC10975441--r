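#' Fit a calibration model (PLSR, PCR or SVR)
#'
#' PLSR is fitted by NIPALS with mean-centering of X and y; PCR regresses
#' centered y on the leading principal-component scores of centered X; SVR
#' is epsilon-insensitive support-vector regression with an RBF kernel,
#' hyperparameters chosen by an internal seeded 5-fold grid search unless
#' given. No variance scaling is applied — spectral pretreatment is
#' expected to handle scale.
#'
#' @param kind `"plsr"`, `"pcr"` or `"svmr"`.
#' @param x calibration spectra matrix.
#' @param y moisture vector.
#' @param ncomp number of latent variables (PLSR/PCR; ignored for SVR).
#' @param svm_params optional list with `cost`, `gamma`, `epsilon` to skip
#'   the SVR grid search.
#' @param seed RNG seed for the SVR grid search folds.
#' @return object of class `hsi_model`.
#' @export
fit_model <- function(kind = c("plsr", "pcr", "svmr"), x, y, ncomp = 10,
                      svm_params = NULL, seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (any(!is.finite(y)))
    stop_hsi("y contains non-finite values", class = "hsimoist_contract_error")
  if (kind %in% c("plsr", "pcr")) {
    if (ncomp >= nrow(x))
      stop_hsi("need more samples than components",
               class = "hsimoist_rank_error")
    core <- if (kind == "plsr") pls_nipals(x, y, ncomp) else pcr_core(x, y, ncomp)
    if (core$ncomp < ncomp && kind == "pcr")
      stop_hsi("requested ", ncomp, " components but X rank supports only ",
               core$ncomp, class = "hsimoist_rank_error")
    fit <- list(core = core, ncomp = min(ncomp, core$ncomp))
  } else {
    if (is.null(svm_params)) svm_params <- tune_svm(x, y, seed = seed)
    sv <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                     cost = svm_params$cost, gamma = svm_params$gamma,
                     epsilon = svm_params$epsilon, scale = TRUE)
    fit <- list(svm = sv, svm_params = svm_params, ncomp = NA_integer_)
  }
  structure(c(fit, list(kind = kind, wavelengths = axis_of(x))),
            class = "hsi_model")
}

# internal grid search: RBF gamma around the 1/(p * var) heuristic
tune_svm <- function(x, y, seed = 1L, folds = 5L) {
  g0 <- 1 / (ncol(x) * max(var(as.vector(x)), 1e-12))
  grid <- expand.grid(cost = c(1, 10, 100),
                      gamma = g0 * c(0.1, 1, 10),
                      epsilon = c(0.01, 0.1))
  n <- nrow(x)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  best <- NULL; best_rmse <- Inf
  for (i in seq_len(nrow(grid))) {
    pr <- numeric(n)
    for (f in seq_len(folds)) {
      te <- fold == f
      sv <- e1071::svm(x[!te, , drop = FALSE], y[!te],
                       type = "eps-regression", kernel = "radial",
                       cost = grid$cost[i], gamma = grid$gamma[i],
                       epsilon = grid$epsilon[i], scale = TRUE)
      pr[te] <- predict(sv, x[te, , drop = FALSE])
    }
    rm_i <- rmse(y, pr)
    if (rm_i < best_rmse) { best_rmse <- rm_i; best <- grid[i, ] }
  }
  as.list(best)
}

#' @export
predict.hsi_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  wl <- axis_of(newdata)
  if (length(wl) != length(object$wavelengths) ||
      any(abs(wl - object$wavelengths) > 1e-6))
    stop_hsi("band axis of new data does not match training wavelengths",
             class = "hsimoist_contract_error")
  if (object$kind == "svmr")
    as.numeric(predict(object$svm, newdata))
  else
    linear_predict(object$core, newdata, object$ncomp)
}

#' @export
print.hsi_model <- function(x, ...) {
  cat(sprintf("<%s model> %d bands%s\n", toupper(x$kind),
              length(x$wavelengths),
              if (is.na(x$ncomp)) "" else sprintf(", %d components", x$ncomp)))
  invisible(x)
}

#' Coefficient of determination between measured and predicted values
#'
#' The default is the squared Pearson correlation — the conventional
#' RC2/RP2 of chemometric calibration reports, bounded in `[0, 1]` and
#' equal to 1 for perfect predictions. `literal = TRUE` instead evaluates
#' the alternative printed form
#' `sum((x-xbar)*(y-ybar)) / (sum((x-xbar)^2) + sum((y-ybar)^2))`, kept for
#' comparison; note it reaches at most 0.5 for identical vectors and is not
#' a standard R-squared.
#'
#' @param actual measured values.
#' @param predicted predicted values.
#' @param literal evaluate the non-standard additive-denominator form.
#' @return scalar; in `[0, 1]` for the default form.
#' @export
r_squared <- function(actual, predicted, literal = FALSE) {
  if (length(actual) != length(predicted) || length(actual) < 2)
    stop_hsi("need two equal-length vectors of length >= 2",
             class = "hsimoist_contract_error")
  if (sd(actual) == 0)
    stop_hsi("R^2 undefined for constant measured values",
             class = "hsimoist_degenerate_error")
  xc <- actual - mean(actual); yc <- predicted - mean(predicted)
  if (literal)
    return(sum(xc * yc) / (sum(xc^2) + sum(yc^2)))
  if (sd(predicted) == 0) return(0)
  (sum(xc * yc))^2 / (sum(xc^2) * sum(yc^2))
}

#' Root mean square error
#'
#' @param actual measured values.
#' @param predicted predicted values.
#' @return `sqrt(mean((actual - predicted)^2))`, same units as `actual`.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop_hsi("length mismatch", class = "hsimoist_contract_error")
  sqrt(mean((actual - predicted)^2))
}

#' Cross-validate a calibration model over a component grid
#'
#' Assembles out-of-fold predictions for every candidate component count
#' (leave-one-out by default, or seeded k-fold), computes RMSECV on them,
#' and returns the count minimising RMSECV. For SVR the component grid is
#' ignored and a single out-of-fold prediction set is produced.
#'
#' @param kind `"plsr"`, `"pcr"` or `"svmr"`.
#' @param x,y calibration spectra and moisture.
#' @param scheme `"loo"` or `"kfold"`.
#' @param k number of folds for `"kfold"`.
#' @param components_grid candidate latent-variable counts.
#' @param svm_params,seed passed through to [fit_model()]; `seed` also
#'   fixes the k-fold assignment.
#' @return list with `best_ncomp`, `rmsecv`, `rcv2`, `rmsecv_trace`,
#'   and the out-of-fold `predictions` at the best count.
#' @export
cross_validate <- function(kind = c("plsr", "pcr", "svmr"), x, y,
                           scheme = c("loo", "kfold"), k = 10,
                           components_grid = NULL, svm_params = NULL,
                           seed = 1L) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  x <- as.matrix(x); n <- nrow(x)
  fold <- if (scheme == "loo") seq_len(n)
          else with_seed(seed, sample(rep_len(seq_len(k), n)))
  nf <- max(fold)
  if (any(tabulate(fold, nf) > n - 2))
    stop_hsi("a fold leaves fewer than 2 training samples",
             class = "hsimoist_scheme_error")

  if (kind == "svmr") {
    if (is.null(svm_params)) svm_params <- tune_svm(x, y, seed = seed)
    pr <- numeric(n)
    for (f in seq_len(nf)) {
      te <- fold == f
      m <- fit_model("svmr", x[!te, , drop = FALSE], y[!te],
                     svm_params = svm_params, seed = seed)
      pr[te] <- predict(m, x[te, , drop = FALSE])
    }
    return(list(best_ncomp = NA_integer_, rmsecv = rmse(y, pr),
                rcv2 = r_squared(y, pr), rmsecv_trace = NULL,
                predictions = pr, svm_params = svm_params))
  }

  maxc <- if (is.null(components_grid))
    min(15L, ncol(x), n - 2L) else max(components_grid)
  grid <- if (is.null(components_grid))
    seq_len(maxc) else sort(unique(as.integer(components_grid)))
  preds <- matrix(NA_real_, n, max(grid))
  for (f in seq_len(nf)) {
    te <- fold == f
    core <- if (kind == "plsr")
      pls_nipals(x[!te, , drop = FALSE], y[!te], max(grid))
    else pcr_core(x[!te, , drop = FALSE], y[!te], max(grid))
    for (a in grid) {
      k_eff <- min(a, core$ncomp)
      preds[te, a] <- linear_predict(core, x[te, , drop = FALSE], k_eff)
    }
  }
  trace <- vapply(grid, function(a) rmse(y, preds[, a]), numeric(1))
  best <- grid[which.min(trace)]
  list(best_ncomp = best, rmsecv = min(trace),
       rcv2 = r_squared(y, preds[, best]),
       rmsecv_trace = stats::setNames(trace, grid),
       predictions = preds[, best])
}

#' Evaluate a grid of wavelength selections and model kinds
#'
#' The model-comparison table of a calibration study: for every
#' (selection x model-kind) cell, bands are restricted to the selection,
#' the latent-variable count is chosen by cross-validation on the
#' calibration set, the model is refitted on the full calibration set, and
#' calibration (RC2/RMSEC), cross-validation (RCV2/RMSECV) and prediction
#' (RP2/RMSEP) statistics are reported.
#'
#' @param xcal,ycal calibration spectra and moisture.
#' @param xpred,ypred held-out prediction spectra and moisture.
#' @param selections named list; each element a `selection_result` or a
#'   vector of band indices, or `NULL` for the full band axis.
#' @param kinds model kinds to fit.
#' @param scheme,k cross-validation scheme (see [cross_validate()]).
#' @param max_comp latent-variable cap (default 15).
#' @param seed RNG seed (SVR tuning, k-fold assignment).
#' @return data.frame of class `evaluation_report` with columns
#'   `selection`, `model`, `bands`, `PCs`, `RC2`, `RMSEC`, `RCV2`,
#'   `RMSECV`, `RP2`, `RMSEP`.
#' @export
evaluate_grid <- function(xcal, ycal, xpred, ypred,
                          selections = list(full = NULL),
                          kinds = c("plsr", "pcr", "svmr"),
                          scheme = "loo", k = 10, max_comp = 15,
                          seed = 1L) {
  if (is.null(names(selections)))
    names(selections) <- paste0("sel", seq_along(selections))
  rows <- list()
  for (sname in names(selections)) {
    sel <- selections[[sname]]
    idx <- if (is.null(sel)) seq_len(ncol(xcal))
           else if (inherits(sel, "selection_result")) sel$selected_idx
           else as.integer(sel)
    xc <- xcal[, idx, drop = FALSE]
    xp <- xpred[, idx, drop = FALSE]
    for (kind in kinds) {
      cv <- cross_validate(kind, xc, ycal, scheme = scheme, k = k,
                           components_grid =
                             if (kind == "svmr") NULL
                             else seq_len(min(max_comp, length(idx),
                                              nrow(xc) - 2L)),
                           seed = seed)
      model <- fit_model(kind, xc, ycal,
                         ncomp = if (kind == "svmr") NULL else cv$best_ncomp,
                         svm_params = cv$svm_params, seed = seed)
      fitted_cal <- predict(model, xc)
      fitted_pred <- predict(model, xp)
      rows[[length(rows) + 1L]] <- data.frame(
        selection = sname, model = kind, bands = length(idx),
        PCs = cv$best_ncomp,
        RC2 = r_squared(ycal, fitted_cal), RMSEC = rmse(ycal, fitted_cal),
        RCV2 = cv$rcv2, RMSECV = cv$rmsecv,
        RP2 = r_squared(ypred, fitted_pred),
        RMSEP = rmse(ypred, fitted_pred))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Write an evaluation report as CSV or Markdown
#'
#' @param report an [evaluate_grid()] result.
#' @param path output path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(report, path, row.names = FALSE)
  } else {
    num <- vapply(report, is.numeric, logical(1))
    fmt <- report
    fmt[num] <- lapply(report[num], function(v) sprintf("%.4f", v))
    header <- paste0("| ", paste(names(fmt), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|")
    body <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(header, sep, body), path)
  }
  invisible(path)
}
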