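# Wavelength selection: SPA (successive projections), CARS (competitive
# adaptive reweighted sampling) and UVE (uninformative variable
# elimination). All three operate on the calibration set only and return a
# `selection_result` with per-method diagnostics.

new_selection_result <- function(method, idx, wl, diagnostics) {
  idx <- sort(unique(as.integer(idx)))
  structure(list(method = method, selected_idx = idx,
                 selected_wl = wl[idx], n_bands = length(wl),
                 diagnostics = diagnostics),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<%s selection> %d of %d bands (%s%%)\n", toupper(x$method),
              length(x$selected_idx), x$n_bands,
              selected_fraction(length(x$selected_idx), x$n_bands)))
  invisible(x)
}

#' Selected fraction of the band axis, as a percentage
#'
#' @param n_selected number of selected bands.
#' @param n_bands total bands on the axis.
#' @param digits decimals to round to (default 1).
#' @return percentage, rounded.
#' @export
selected_fraction <- function(n_selected, n_bands, digits = 1) {
  round(100 * n_selected / n_bands, digits)
}

# Exact leave-one-out RMSE of an intercept-included multiple linear
# regression, via the hat-matrix identity e_(-i) = e_i / (1 - h_i).
loocv_rmse_mlr <- function(X, y) {
  Xi <- cbind(1, X)
  if (nrow(Xi) <= ncol(Xi)) return(Inf)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) return(Inf)
  h <- rowSums(qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-10)) return(Inf)
  e <- qr.resid(qrx, y)
  sqrt(mean((e / (1 - h))^2))
}

#' Successive projections algorithm (SPA) wavelength selection
#'
#' Builds, from every candidate initial band, a forward chain in which each
#' step adds the band whose column has maximal norm after orthogonal
#' projection away from the span of the bands already chosen — minimising
#' collinearity among the selected bands. Every (initial band, subset
#' size) candidate is then scored by the leave-one-out RMSE of a multiple
#' linear regression on the calibration set, and the minimiser is
#' returned.
#'
#' @param xcal calibration spectra matrix (columns are mean-centered
#'   internally before projection).
#' @param ycal moisture vector.
#' @param n_min,n_max smallest/largest subset size considered; `n_max`
#'   defaults to `min(25, bands, samples - 2)`.
#' @return a `selection_result`; diagnostics carry `rmse_by_size` (best
#'   LOO RMSE at each subset size), the winning chain and its start.
#' @export
spa_select <- function(xcal, ycal, n_min = 1, n_max = NULL) {
  x <- as.matrix(xcal)
  n <- nrow(x); p <- ncol(x)
  if (is.null(n_max)) n_max <- min(25L, p, n - 2L)
  n_max <- min(n_max, p, n - 2L)
  if (n_min < 1 || n_min > n_max)
    stop_hsi("need 1 <= n_min <= n_max", class = "hsimoist_contract_error")
  xc <- sweep(x, 2, colMeans(x))

  chains <- spa_chains(xc, n_max)
  rmse_grid <- matrix(Inf, p, n_max)  # start x size
  for (s in seq_len(p)) {
    ch <- chains[[s]]
    for (sz in n_min:min(n_max, length(ch)))
      rmse_grid[s, sz] <- loocv_rmse_mlr(x[, ch[1:sz], drop = FALSE], ycal)
  }
  best <- arrayInd(which.min(rmse_grid), dim(rmse_grid))
  chain <- chains[[best[1]]][seq_len(best[2])]
  rmse_by_size <- apply(rmse_grid[, n_min:n_max, drop = FALSE], 2, min)
  new_selection_result("spa", chain, axis_of(x), list(
    rmse_by_size = stats::setNames(rmse_by_size, n_min:n_max),
    best_size = best[2], best_start = chains[[best[1]]][1],
    chain = chain, min_rmse = min(rmse_grid)))
}

# All projection chains of length <= n_max, one per starting column.
# Successive deflation: after choosing column k, every remaining column is
# replaced by its component orthogonal to it, so norms measure information
# not yet spanned. Chains truncate when the largest remaining norm falls
# below tol (rank exhausted).
spa_chains <- function(xc, n_max, tol = 1e-12) {
  p <- ncol(xc)
  lapply(seq_len(p), function(start) {
    xw <- xc
    chain <- integer(n_max)
    chain[1] <- start
    for (step in seq_len(n_max - 1L)) {
      last <- chain[step]
      v <- xw[, last]
      nv <- sum(v^2)
      if (nv < tol^2) { chain <- chain[seq_len(step)]; break }
      xw <- xw - v %*% (crossprod(v, xw) / nv)
      norms <- colSums(xw^2)
      norms[chain[seq_len(step)]] <- -1
      nxt <- which.max(norms)  # ties: lowest index
      if (norms[nxt] < tol) { chain <- chain[seq_len(step)]; break }
      chain[step + 1L] <- nxt
    }
    chain[chain > 0L]
  })
}

# Exponential decay function of CARS: fraction of bands retained at
# Monte-Carlo iteration i of N, starting from p bands. r_1 = 1 and
# r_N = 2/p by construction of the constants.
cars_edf <- function(i, p, N) {
  mu <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  mu * exp(-k * i)
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Monte-Carlo selection over `n_mc` iterations. Each iteration fits a PLS
#' model on a random 80% row subsample restricted to the currently
#' retained bands; bands are weighted by their absolute PLS regression
#' coefficients, cut to the exponentially decaying retention count
#' (`ceiling(r_i * p)`, floor 2), and then resampled with replacement with
#' probability proportional to weight (adaptive reweighted sampling); the
#' unique resampled bands survive. Each surviving set is scored by k-fold
#' RMSECV of a PLS model on the full calibration set (latent variables by
#' internal minimum RMSECV, capped at `max_comp`); the set with minimal
#' RMSECV wins.
#'
#' @param xcal,ycal calibration spectra and moisture.
#' @param n_mc Monte-Carlo iterations (default 50).
#' @param folds folds of the scoring cross-validation (default 10).
#' @param seed RNG seed (subsampling, ARS draws, fold assignment).
#' @param max_comp latent-variable cap inside the selector (default 10).
#' @return a `selection_result`; diagnostics carry the retained-count
#'   trace, RMSECV trace, EDF counts and coefficient paths.
#' @export
cars_select <- function(xcal, ycal, n_mc = 50, folds = 10, seed = 1L,
                        max_comp = 10) {
  x <- as.matrix(xcal)
  n <- nrow(x); p <- ncol(x)
  if (n_mc < 2) stop_hsi("n_mc must be >= 2", class = "hsimoist_contract_error")
  with_seed(seed, {
    retained <- seq_len(p)
    sets <- vector("list", n_mc)
    rmsecv <- rep(NA_real_, n_mc)
    ncomps <- rep(NA_integer_, n_mc)
    counts <- integer(n_mc)
    # epsilon guards the exact endpoint r_N * p = 2 against upward rounding
    edf_counts <- pmax(2L, pmin(p, as.integer(
      ceiling(cars_edf(seq_len(n_mc), p, n_mc) * p - 1e-9))))
    coef_paths <- matrix(0, n_mc, p)
    truncated <- FALSE
    for (i in seq_len(n_mc)) {
      if (length(retained) < 2L) { truncated <- TRUE; break }
      # score current retained set by k-fold RMSECV on the calibration set
      cv <- cross_validate("plsr", x[, retained, drop = FALSE], ycal,
                           scheme = "kfold", k = folds,
                           components_grid =
                             seq_len(min(max_comp, length(retained), n - 2L)),
                           seed = NULL)
      sets[[i]] <- retained
      rmsecv[i] <- cv$rmsecv
      ncomps[i] <- cv$best_ncomp
      counts[i] <- length(retained)
      # PLS weights from an 80% row subsample
      rows <- sample(n, max(2L, round(0.8 * n)))
      core <- pls_nipals(x[rows, retained, drop = FALSE], ycal[rows],
                         min(cv$best_ncomp, length(retained)))
      b <- abs(core$coef[, core$ncomp])
      coef_paths[i, retained] <- core$coef[, core$ncomp]
      w <- b / sum(b)
      # EDF cut: keep the strongest ceiling(r_i * p) bands
      keep_n <- min(edf_counts[i], length(retained))
      ord <- order(w, decreasing = TRUE)
      top <- retained[ord[seq_len(keep_n)]]
      w_top <- w[ord[seq_len(keep_n)]]
      # ARS: weighted resampling with replacement, unique survivors
      if (sum(w_top) <= 0) { truncated <- TRUE; break }
      drawn <- sample(top, size = keep_n, replace = TRUE, prob = w_top)
      retained <- sort(unique(drawn))
    }
    done <- which(!is.na(rmsecv))
    if (!length(done))
      stop_hsi("CARS made no complete iteration", class = "hsimoist_rank_error")
    best <- done[which.min(rmsecv[done])]
    new_selection_result("cars", sets[[best]], axis_of(x), list(
      rmsecv = rmsecv[done], retained_count = counts[done],
      edf_counts = edf_counts, ncomp = ncomps[done],
      coef_paths = coef_paths[done, , drop = FALSE],
      best_iter = best, truncated = truncated))
  })
}

#' Uninformative variable elimination (UVE) wavelength selection
#'
#' Appends a matrix of artificial noise variables (same width as X,
#' uniform on `[0, noise_scale]`), fits one PLS model per left-out sample
#' on the augmented matrix, and measures each variable's stability
#' `C = mean(b) / sd(b)` across the leave-one-out coefficient vectors.
#' Real bands whose `|C|` exceeds the largest `|C|` among the noise bands
#' are selected — anything less stable than pure noise is discarded.
#'
#' @param xcal,ycal calibration spectra and moisture.
#' @param n_latent PLS latent variables (default 12).
#' @param noise_scale amplitude of the appended noise (default 1e-10, so
#'   the noise defines the cutoff without perturbing the fit).
#' @param seed RNG seed for the noise matrix.
#' @return a `selection_result`; diagnostics carry the stability vector
#'   over real and noise bands, the threshold `c_max`, and a flag for any
#'   zero-variance coefficients.
#' @export
uve_select <- function(xcal, ycal, n_latent = 12, noise_scale = 1e-10,
                       seed = 1L) {
  x <- as.matrix(xcal)
  n <- nrow(x); p <- ncol(x)
  if (n_latent > n - 2L)
    stop_hsi("n_latent must be <= samples - 2", class = "hsimoist_contract_error")
  with_seed(seed, {
    G <- matrix(runif(n * p), n, p) * noise_scale
    XG <- cbind(x, G)
    B <- matrix(NA_real_, n, 2L * p)
    for (i in seq_len(n)) {
      core <- pls_nipals(XG[-i, , drop = FALSE], ycal[-i], n_latent)
      B[i, ] <- core$coef[, core$ncomp]
    }
    mu <- colMeans(B)
    sdv <- apply(B, 2, sd)
    zero_sd <- sdv == 0
    C <- mu / sdv
    C[zero_sd] <- Inf * sign(mu[zero_sd] + (mu[zero_sd] == 0))
    c_max <- max(abs(C[(p + 1L):(2L * p)]))
    selected <- which(abs(C[seq_len(p)]) > c_max)
    if (!length(selected))
      stop_hsi("UVE rejected every band (threshold ", signif(c_max, 4), ")",
               class = "hsimoist_degenerate_error")
    new_selection_result("uve", selected, axis_of(x), list(
      stability = C, c_max = c_max, n_latent = n_latent,
      zero_sd_flag = any(zero_sd)))
  })
}

#' Serialize a selection result to JSON
#'
#' @param sel a `selection_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(sel, path) {
  payload <- list(method = sel$method, selected_idx = sel$selected_idx,
                  selected_wl = sel$selected_wl, n_bands = sel$n_bands,
                  diagnostics = sel$diagnostics[
                    !vapply(sel$diagnostics, is.matrix, logical(1))])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
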