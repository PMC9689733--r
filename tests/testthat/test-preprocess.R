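grid <- make_grid()
h <- grid_spacing(grid)

test_that("black/white calibration maps counts to the expected reflectance", {
  p <- 10
  W <- rep(3000, p); B <- rep(500, p)
  mk <- function(Irow) list(white_counts = W, dark_counts = B,
                            sample_counts = matrix(rep(Irow, 5), 5,
                                                   byrow = TRUE))
  expect_equal(reflectance(mk(B)), matrix(0, 5, p))
  expect_equal(reflectance(mk(W)), matrix(1, 5, p))
  expect_equal(reflectance(mk((W + B) / 2)), matrix(0.5, 5, p))
  bad <- mk(W); bad$white_counts[3] <- bad$dark_counts[3]
  expect_error(reflectance(bad), "Degenerate calibration")
})

test_that("scan averaging is an order-invariant per-wavelength mean", {
  set.seed(4)
  R <- matrix(rnorm(5 * 12), 5, 12)
  expect_equal(average_scans(R), naive_mean_rows(R))
  expect_equal(average_scans(R[c(3, 1, 5, 2, 4), ]), average_scans(R))
  one <- matrix(rep(R[1, ], 5), 5, byrow = TRUE)
  expect_equal(average_scans(one), R[1, ])
  expect_error(average_scans(R[1:4, ]), "5 scan rows")
})

test_that("Savitzky-Golay smoothing reproduces low-degree polynomials and matches the local-regression oracle", {
  pos <- 1:40
  quad <- 2 + 0.3 * pos - 0.01 * pos^2
  expect_lt(max(abs(sg_smooth(quad, 11, 2) - quad)), 1e-10)
  const <- rep(3.2, 40)
  expect_equal(sg_smooth(const, 7, 2), const)
  set.seed(8)
  X <- matrix(rnorm(5 * 40), 5, 40)
  sm <- sg_smooth(X, 7, 2)
  for (i in 1:5) expect_equal(sm[i, ], naive_sg_row(X[i, ], 7, 2),
                              tolerance = 1e-10)
  # smoothing shrinks white-noise variance in the interior
  expect_lt(var(as.vector(sm[, 10:30])), var(as.vector(X[, 10:30])))
  expect_error(sg_smooth(X, 8, 2), "odd")
  expect_error(sg_smooth(X, 7, 7), "polyorder")
})

test_that("finite-difference derivatives match the loop oracle", {
  x <- as.numeric(grid)
  lin <- 1 + 0.002 * x
  quad <- 3 - 0.001 * x + 2e-6 * x^2
  expect_equal(derivative(rep(5, 228), 1, h), numeric(228))
  d1 <- derivative(lin, 1, h)
  expect_equal(d1[2:227], rep(0.002, 226))
  d2 <- derivative(quad, 2, h)
  expect_equal(d2, naive_derivative_row(quad, 2, h))
  set.seed(9)
  X <- matrix(rnorm(3 * 30), 3, 30)
  for (ord in 1:2) {
    D <- derivative(X, ord, 2.5)
    for (i in 1:3) expect_equal(D[i, ], naive_derivative_row(X[i, ], ord, 2.5),
                                tolerance = 1e-12)
  }
  expect_error(derivative(matrix(1, 2, 2), 1, h), "at least 3")
})

test_that("the MSC reference is the training mean and correction inverts affine distortion", {
  set.seed(10)
  X <- matrix(runif(6 * 30, 0.2, 0.8), 6, 30)
  ref <- msc_fit(X)
  expect_equal(ref, naive_mean_rows(X))
  expect_equal(msc_fit(rbind(X[1, ], X[1, ])), X[1, ])
  expect_equal(msc_fit(rbind(X[1, ], 3 * X[1, ])), 2 * X[1, ])
  expect_error(msc_fit(X[1, , drop = FALSE]), "at least 2")

  expect_equal(msc_apply(matrix(ref, 1), ref)[1, ], ref)
  expect_equal(msc_apply(matrix(2 * ref + 5, 1), ref)[1, ], ref)
  corr <- msc_apply(X, ref)
  for (i in 1:6) expect_equal(corr[i, ], unname(naive_msc_row(X[i, ], ref)),
                              tolerance = 1e-10)
  flat <- matrix(rep(mean(ref), 30), 1)  # zero-slope row against the reference
  expect_error(msc_apply(flat, ref), "degenerate row")
})

test_that("MSC maps scatter-corrupted and clean spectra to the same point", {
  co <- generate_cohort(20, seed = 21, scatter_sd = 0.1, baseline_sd = 0)
  latent <- co$truth$latent_reflectance
  ref <- msc_fit(co$reflectance)
  # correcting the corrupted spectra and the latent truth with the same
  # reference must make them coincide: the affine distortion is removed
  corrected <- msc_apply(co$reflectance, ref)
  latent_c <- msc_apply(latent, ref)
  expect_lt(mean((corrected - latent_c)^2), mean((co$reflectance - latent)^2))
  expect_lt(sqrt(mean((corrected - latent_c)^2)), 0.005)
})

test_that("SNV standardises every spectrum", {
  set.seed(11)
  X <- matrix(runif(5 * 25, 0.1, 0.9), 5, 25)
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
  expect_equal(snv(Z), Z)  # idempotent on standardised rows
  for (i in 1:5) expect_equal(Z[i, ], naive_snv_row(X[i, ]), tolerance = 1e-12)
  expect_error(snv(matrix(1, 2, 5)), "constant")
})

test_that("the log transform is pseudo-absorbance with an exact round trip", {
  expect_equal(log_transform(matrix(1, 1, 3))[1, ], c(0, 0, 0))
  expect_equal(log_transform(matrix(0.1, 1, 3))[1, ], c(1, 1, 1))
  set.seed(12)
  X <- matrix(runif(40, 0.05, 1), 4, 10)
  expect_equal(10^(-log_transform(X)), X, tolerance = 1e-12)
  expect_equal(log_transform(X, inverse = FALSE), log10(X))
  expect_error(log_transform(matrix(c(1, -1), 1)), "positive")
})

test_that("named methods compose left-to-right and all thirteen run", {
  set.seed(13)
  X <- matrix(runif(10 * 228, 0.2, 0.8), 10, 228)
  expect_equal(apply_named_method("Raw", X)$train, X)
  expect_equal(apply_named_method("SG+SNV", X)$train, snv(sg_smooth(X, 11, 2)))
  ref <- msc_fit(sg_smooth(X, 11, 2))
  expect_equal(
    apply_named_method("SG+MSC+FD", X)$train,
    derivative(msc_apply(sg_smooth(X, 11, 2), ref), 1, 800 / 227)
  )
  for (m in preprocess_methods()) {
    out <- apply_named_method(m, X, X[1:3, ])
    expect_equal(dim(out$train), dim(X))      # shape preserved
    expect_equal(dim(out$test), c(3, 228))
    expect_equal(!is.null(out$msc_reference), grepl("MSC", m))
  }
  expect_error(apply_named_method("OSC", X), "Unknown")
})

test_that("test-set transforms use training statistics only", {
  set.seed(14)
  X_train <- matrix(runif(8 * 50, 0.2, 0.8), 8, 50)
  probe <- matrix(runif(50, 0.2, 0.8), 1, 50)
  batch_a <- rbind(probe, matrix(runif(3 * 50, 0.2, 0.8), 3, 50))
  batch_b <- rbind(probe, matrix(runif(5 * 50, 0.2, 0.8), 5, 50))
  for (m in c("MSC", "SG+MSC", "SNV", "SG+SNV+FD")) {
    out_a <- apply_named_method(m, X_train, batch_a)$test[1, ]
    out_b <- apply_named_method(m, X_train, batch_b)$test[1, ]
    expect_identical(out_a, out_b)
  }
  # and preprocess_apply reproduces the stored transform
  fp <- apply_named_method("SG+MSC", X_train, batch_a)
  expect_equal(preprocess_apply(fp, batch_a), fp$test)
})

test_that("SNV and MSC bring scatter-corrupted spectra closer to the latent truth", {
  for (seed in 1:2) {
    co <- generate_cohort(25, seed = seed, scatter_sd = 0.1)
    latent <- co$truth$latent_reflectance
    # distances are measured between identically transformed corrupted and
    # latent spectra, normalised by the latent signal variance in that space
    rel_msd <- function(A, B) mean((A - B)^2) / mean((B - mean(B))^2)
    ref <- msc_fit(co$reflectance)
    raw_d <- rel_msd(co$reflectance, latent)
    msc_d <- rel_msd(msc_apply(co$reflectance, ref), msc_apply(latent, ref))
    snv_d <- rel_msd(snv(co$reflectance), snv(latent))
    expect_lt(msc_d, raw_d)
    expect_lt(snv_d, raw_d)
  }
})
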