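# NIPALS PLS1 and PCR cores. Both mean-center X and y and return
# regression coefficients for every component count 1..ncomp, so
# cross-validation over a component grid costs one decomposition per fold.

pls_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  xmean <- colMeans(X); ymean <- mean(y)
  Xc <- sweep(X, 2, xmean); yc <- y - ymean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  a <- 0L
  while (a < ncomp) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # residual X carries no covariance with y
    a <- a + 1L
    w <- w / nw
    tt <- Xc %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-24) { a <- a - 1L; break }
    pp <- crossprod(Xc, tt) / t2
    qq <- sum(yc * tt) / t2
    Xc <- Xc - tt %*% t(pp)
    yc <- yc - qq * tt
    W[, a] <- w; P[, a] <- pp; Q[a] <- qq
  }
  if (a == 0L)
    stop_hsi("X carries no covariance with y: PLS rank 0",
             class = "hsimoist_rank_error")
  # coefficients for each cumulative component count
  B <- matrix(0, p, a)
  for (k in seq_len(a)) {
    Wk <- W[, 1:k, drop = FALSE]
    Pk <- P[, 1:k, drop = FALSE]
    B[, k] <- Wk %*% solve(crossprod(Pk, Wk), Q[1:k])
  }
  list(coef = B, intercept = ymean - drop(crossprod(xmean, B)),
       xmean = xmean, ymean = ymean, ncomp = a)
}

pcr_core <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xmean <- colMeans(X); ymean <- mean(y)
  Xc <- sweep(X, 2, xmean)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d[1], 1) * 1e-12
  r <- min(sum(pos), ncomp, n - 1L, p)
  if (r == 0L)
    stop_hsi("X has rank 0", class = "hsimoist_rank_error")
  # scores are orthogonal: per-component regression weights are independent
  gamma <- crossprod(sv$u[, 1:r, drop = FALSE], y - ymean) / sv$d[1:r]
  B <- matrix(0, p, r)
  acc <- rep(0, p)
  for (k in seq_len(r)) {
    acc <- acc + sv$v[, k] * gamma[k]
    B[, k] <- acc
  }
  list(coef = B, intercept = ymean - drop(crossprod(xmean, B)),
       xmean = xmean, ymean = ymean, ncomp = r)
}

linear_predict <- function(core, newx, k = core$ncomp) {
  drop(as.matrix(newx) %*% core$coef[, k] + core$intercept[k])
}
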