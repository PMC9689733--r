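test_that("single-predictor PLSR equals the simple regression slope", {
  set.seed(20)
  x <- rnorm(15)
  y <- 2.5 * x + rnorm(15, 0, 0.1)
  m <- fit_plsr(matrix(x, ncol = 1), y, k = 1)
  slope <- cov(x, y) / var(x)
  expect_equal(unname(m$coefficients), slope, tolerance = 1e-10)
  expect_equal(m$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
})

test_that("full-rank PLSR reaches the least-squares fit and matches a loop-wise NIPALS", {
  set.seed(21)
  X <- matrix(rnorm(18), 6, 3)
  y <- rnorm(6)
  m <- fit_plsr(X, y, k = 3)
  ols <- lm(y ~ X)
  expect_equal(plsr_predict(m, X), unname(fitted(ols)), tolerance = 1e-8)

  X2 <- matrix(rnorm(30 * 8), 30, 8)
  y2 <- X2 %*% rnorm(8) + rnorm(30, 0, 0.2)
  m2 <- fit_plsr(X2, drop(y2), k = 4)
  oracle <- naive_pls1_coef(X2, drop(y2), 4)
  expect_equal(unname(m2$coefficients), oracle$coef, tolerance = 1e-8)
  expect_equal(m2$intercept, unname(oracle$intercept), tolerance = 1e-8)
})

test_that("centring identity: the mean spectrum predicts the mean response", {
  set.seed(22)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rnorm(20)
  for (k in c(1, 3)) {
    m <- fit_plsr(X, y, k)
    expect_equal(plsr_predict(m, m$x_mean), mean(y), tolerance = 1e-10)
  }
})

test_that("score vectors are mutually orthogonal", {
  set.seed(23)
  X <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  m <- fit_plsr(X, y, k = 6)
  Xc <- sweep(X, 2, m$x_mean)
  Tm <- Xc %*% m$weights %*% solve(crossprod(m$loadings, m$weights))
  G <- crossprod(Tm)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  # prediction agrees with explicit score-space reconstruction
  recon <- drop(Tm %*% m$y_loadings) + m$y_mean
  expect_equal(plsr_predict(m, X), recon, tolerance = 1e-8)
})

test_that("fit and predict enforce their contracts", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_plsr(X, rep(1, 5), 2), "zero variance")
  expect_error(fit_plsr(X, rnorm(5), 0), "k")
  expect_error(fit_plsr(X, rnorm(5), 5), "k")
  m <- fit_plsr(X, rnorm(5), 2)
  expect_error(plsr_predict(m, matrix(1, 2, 3)), "Wavelength count")
  expect_equal(plsr_predict(m, X[2, ]), plsr_predict(m, X)[2])
})

test_that("component selection finds a planted low-rank structure", {
  set.seed(24)
  n <- 40; p <- 60
  S <- matrix(rnorm(n * 2), n, 2)
  FL <- matrix(rnorm(2 * p), 2, p)
  X <- S %*% FL
  y <- drop(S %*% c(1.5, -2))
  k <- select_components(X, y, k_max = 5, folds = 5, seed = 7)
  expect_lte(k, 3)
  cv <- pearnir:::cv_rmse_plsr(X, y, 5, folds = 5, seed = 7)
  expect_lt(cv[k], 1e-6)
  expect_identical(k, select_components(X, y, k_max = 5, folds = 5, seed = 7))
  expect_equal(select_components(X, y, k_max = 1, folds = 5, seed = 7), 1L)
})

test_that("tidiers summarise PLSR fits", {
  set.seed(25)
  X <- matrix(rnorm(30), 10, 3)
  m <- fit_plsr(X, rnorm(10), 2)
  td <- tidy(m)
  expect_equal(nrow(td), 4)
  expect_equal(td$estimate[1], m$intercept)
  gl <- glance(m)
  expect_equal(gl$n_components, 2L)
  expect_equal(gl$n_wavelengths, 3L)
})
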