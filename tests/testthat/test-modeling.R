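linear_data <- function(n = 20, p = 5, seed = 1, noise = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- seq_len(p) / p
  list(x = x, y = drop(x %*% beta) + 5 + rnorm(n, 0, noise))
}

test_that("PLSR at full rank recovers an exact linear relationship", {
  d <- linear_data()
  m <- fit_model("plsr", d$x, d$y, ncomp = 5)
  expect_lt(max(abs(predict(m, d$x) - d$y)), 1e-8)
})

test_that("PLSR and PCR coincide with ordinary least squares at full rank", {
  d <- linear_data(n = 25, p = 6, noise = 0.3)
  ols <- lm.fit(cbind(1, d$x), d$y)$coefficients
  for (kind in c("plsr", "pcr")) {
    m <- fit_model(kind, d$x, d$y, ncomp = 6)
    pred <- predict(m, d$x)
    expect_lt(max(abs(pred - cbind(1, d$x) %*% ols)), 1e-8)
  }
})

test_that("one-component PLSR on a single column is simple regression", {
  set.seed(7)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 + 3 * x[, 1] + rnorm(30, 0, 0.1)
  m <- fit_model("plsr", x, y, ncomp = 1)
  sl <- coef(lm(y ~ x[, 1]))
  expect_equal(m$core$coef[1, 1], unname(sl[2]), tolerance = 1e-10)
  expect_equal(m$core$intercept[1], unname(sl[1]), tolerance = 1e-10)
})

test_that("models refuse data on a mismatched band axis", {
  d <- linear_data()
  x <- spectra_matrix(d$x, seq(1000, 1400, length.out = 5))
  m <- fit_model("plsr", x, d$y, ncomp = 3)
  wrong <- spectra_matrix(d$x, seq(1100, 1500, length.out = 5))
  expect_error(predict(m, wrong), class = "hsimoist_contract_error")
})

test_that("r_squared matches a direct Pearson oracle and its edge cases", {
  a <- c(1, 2, 3, 4); p <- c(1.1, 1.9, 3.2, 3.8)
  oracle <- (sum((a - mean(a)) * (p - mean(p))))^2 /
    (sum((a - mean(a))^2) * sum((p - mean(p))^2))
  expect_equal(r_squared(a, p), oracle, tolerance = 1e-12)
  expect_equal(r_squared(a, a), 1)
  expect_equal(r_squared(a, -a + 10), 1)  # sign-blind by design
  expect_error(r_squared(rep(2, 4), p), class = "hsimoist_degenerate_error")
  # literal additive-denominator form tops out at 0.5 for identical vectors
  expect_equal(r_squared(a, a, literal = TRUE), 0.5)
})

test_that("rmse follows its definition", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(2, 4, 6), c(3, 5, 7)), 1)
  expect_equal(rmse(c(0, 0, 0, 0), c(1, 1, 1, 3)), sqrt(3))
  expect_error(rmse(1:3, 1:4), class = "hsimoist_contract_error")
})

test_that("leave-one-out cross-validation equals a naive refit loop", {
  d <- linear_data(n = 15, p = 4, noise = 0.5)
  for (kind in c("plsr", "pcr")) {
    cv <- cross_validate(kind, d$x, d$y, scheme = "loo",
                         components_grid = 1:3)
    expect_length(cv$predictions, 15L)
    for (a in 1:3) {
      naive <- vapply(1:15, function(i) {
        m <- fit_model(kind, d$x[-i, ], d$y[-i], ncomp = a)
        predict(m, d$x[i, , drop = FALSE])
      }, numeric(1))
      expect_equal(unname(cv$rmsecv_trace[as.character(a)]),
                   rmse(d$y, naive), tolerance = 1e-10)
    }
  }
})

test_that("RMSECV on noiseless linear data flattens at the true rank", {
  set.seed(12)
  x <- matrix(rnorm(30 * 4), 30, 4) %*% matrix(rnorm(4 * 8), 4, 8)
  y <- drop(x %*% rnorm(8)) + 5  # exact linear, X of rank 4
  cv <- cross_validate("plsr", x, y, components_grid = 1:6)
  tr <- cv$rmsecv_trace
  # once the rank is reached the out-of-fold error is numerically zero
  expect_lt(tr["4"], 1e-7)
  expect_lt(tr["6"], 1e-7)
  expect_gt(tr["1"], tr["2"])
})

test_that("fitting error does not exceed cross-validated error on average", {
  delta <- vapply(1:20, function(s) {
    cfg <- fast_config(seed = 400 + s, n_samples = 25)
    g <- generate_spectra(cfg)
    cv <- cross_validate("plsr", g$spectra, g$moisture, components_grid = 1:6)
    m <- fit_model("plsr", g$spectra, g$moisture, ncomp = cv$best_ncomp)
    rmse(g$moisture, predict(m, g$spectra)) - cv$rmsecv
  }, numeric(1))
  expect_lt(mean(delta), 0)
})

test_that("SVR fits and cross-validates with seeded reproducibility", {
  d <- linear_data(n = 40, p = 4, noise = 0.2)
  m1 <- fit_model("svmr", d$x, d$y, seed = 3)
  m2 <- fit_model("svmr", d$x, d$y, seed = 3)
  expect_equal(predict(m1, d$x), predict(m2, d$x))
  cv <- cross_validate("svmr", d$x, d$y, scheme = "kfold", k = 5, seed = 3)
  expect_true(is.finite(cv$rmsecv))
  expect_true(is.na(cv$best_ncomp))
})

test_that("the evaluation grid has one row per selection-model cell", {
  cfg <- fast_config(seed = 42, n_samples = 40)
  g <- generate_spectra(cfg)
  sp <- spxy_split(g$spectra, g$moisture, 0.75)
  xc <- g$spectra[sp$calibration_idx, ]; yc <- g$moisture[sp$calibration_idx]
  xp <- g$spectra[sp$prediction_idx, ]; yp <- g$moisture[sp$prediction_idx]
  rep6 <- evaluate_grid(xc, yc, xp, yp,
                        selections = list(full = NULL, manual = c(5, 20, 40)),
                        kinds = c("plsr", "pcr", "svmr"))
  expect_equal(nrow(rep6), 6L)
  expect_true(all(c("PCs", "RC2", "RMSEC", "RCV2", "RMSECV", "RP2", "RMSEP")
                  %in% names(rep6)))
  expect_true(all(rep6$RC2 >= 0 & rep6$RC2 <= 1))
  expect_true(all(rep6[, c("RMSEC", "RMSECV", "RMSEP")] >= 0))
  rep2 <- evaluate_grid(xc, yc, xp, yp, selections = list(full = NULL),
                        kinds = c("plsr", "pcr"))
  expect_equal(nrow(rep2), 2L)
})
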