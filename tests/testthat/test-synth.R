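specs <- default_analyte_specs()
grid <- make_grid()

test_that("sampled concentrations respect their configured ranges", {
  tbl <- sample_concentrations(specs, n = 500, seed = 11)
  expect_equal(nrow(tbl), 500)
  for (s in specs) {
    v <- tbl[[paste0(s$element, "_", s$tissue, "_mgkg")]]
    expect_true(all(v >= s$min_mgkg & v <= s$max_mgkg))
  }
  # pulp calcium specifically sits inside its cohort range
  expect_true(all(tbl$ca_pulp_mgkg >= 14 & tbl$ca_pulp_mgkg <= 40.5))
  expect_equal(nrow(sample_concentrations(specs, n = 0, seed = 1)), 0)
})

test_that("large-cohort analyte means match their calibrated targets", {
  tbl <- sample_concentrations(specs, n = 10000, seed = 202)
  for (s in specs) {
    v <- tbl[[paste0(s$element, "_", s$tissue, "_mgkg")]]
    se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - s$mean_mgkg), 3 * se)
  }
})

test_that("same-element tissues are positively correlated, draws deterministic", {
  tbl <- sample_concentrations(specs, n = 2000, seed = 5)
  expect_gt(cor(tbl$ca_pulp_mgkg, tbl$ca_peel_mgkg), 0.3)
  expect_identical(tbl, sample_concentrations(specs, n = 2000, seed = 5))
})

test_that("absorptivity profiles are Gaussian band sums", {
  one <- analyte_spec("ca", "pulp", 10, 20, 30,
                      band_centers_nm = 1450, band_widths_nm = 30,
                      band_strengths = 0.01)
  eps <- build_absorptivity(one, grid)
  expect_true(all(eps >= 0))
  expect_equal(which.max(eps), which.min(abs(grid - 1450)))

  zero <- analyte_spec("ca", "pulp", 10, 20, 30,
                       band_centers_nm = 1450, band_widths_nm = 30,
                       band_strengths = 0)
  expect_equal(build_absorptivity(zero, grid), numeric(length(grid)))

  two <- analyte_spec("b", "peel", 1, 2, 3,
                      band_centers_nm = c(1000, 1600),
                      band_widths_nm = c(20, 40),
                      band_strengths = c(0.01, 0.02))
  parts <- lapply(1:2, function(j) {
    build_absorptivity(
      analyte_spec("b", "peel", 1, 2, 3,
                   band_centers_nm = two$band_centers_nm[j],
                   band_widths_nm = two$band_widths_nm[j],
                   band_strengths = two$band_strengths[j]),
      grid
    )
  })
  expect_equal(build_absorptivity(two, grid), parts[[1]] + parts[[2]])
})

test_that("analyte specs reject inconsistent parameters", {
  expect_error(analyte_spec("ca", "pulp", 30, 20, 10, 1450, 30), "min_mgkg")
  expect_error(analyte_spec("ca", "pulp", 10, 20, 30, 800, 30), "inside")
  expect_error(analyte_spec("ca", "pulp", 10, 20, 30, 1450, -1), "positive")
})

test_that("frames invert exactly through the black/white calibration", {
  conc <- sample_concentrations(specs, 1, seed = 3)
  fr <- simulate_frames(conc, specs, grid, scatter_sd = 0, noise_snr = Inf,
                        seed = 9)
  R <- reflectance(fr)
  # no per-scan randomness: all five scans identical
  for (s in 2:5) expect_equal(R[s, ], R[1, ])
  rel <- abs(average_scans(R) - fr$latent_reflectance) / fr$latent_reflectance
  expect_lt(max(rel), 1e-12)
})

test_that("scan-averaged reflectance tracks the latent spectrum at the rated SNR", {
  conc <- sample_concentrations(specs, 1, seed = 31)
  fr <- simulate_frames(conc, specs, grid, scatter_sd = 0, noise_snr = 5000,
                        seed = 71)
  avg <- average_scans(reflectance(fr))
  rel <- abs(avg - fr$latent_reflectance) / fr$latent_reflectance
  expect_lt(max(rel), 3 / 5000)
  # residual scale of a single scan is about latent/SNR
  resid <- reflectance(fr)[1, ] - fr$latent_reflectance
  expect_lt(sd(resid / fr$latent_reflectance), 3 / 5000)
  expect_gt(sd(resid / fr$latent_reflectance), 1 / (3 * 5000))
})

test_that("cohorts have the study geometry, bounded reflectance, and are reproducible", {
  co <- generate_cohort(65, seed = 12)
  expect_equal(dim(co$reflectance), c(65, 228))
  expect_equal(ncol(co$reference), 7) # sample_id + six analytes
  expect_true(all(co$reflectance > 0 & co$reflectance <= 1.05))
  co2 <- generate_cohort(65, seed = 12)
  expect_identical(co$reflectance, co2$reflectance)
  expect_identical(co$reference, co2$reference)
  expect_error(generate_cohort(0, seed = 1), "at least 1")
})

test_that("regression of pseudo-absorbance on concentrations recovers band strengths", {
  co <- generate_cohort(300, seed = 44, scatter_sd = 0, noise_snr = Inf,
                        baseline_sd = 0, interferent_sd = 0)
  A <- log_transform(co$reflectance)
  conc <- as.matrix(co$reference[, -1])
  for (key in c("ca_pulp", "k_peel")) {
    s <- specs[[key]]
    j <- which.min(abs(grid - s$band_centers_nm[1]))
    fit <- lm(A[, j] ~ conc)
    est <- coef(fit)[paste0("conc", key, "_mgkg")]
    truth <- build_absorptivity(s, grid)[j]
    expect_equal(unname(est), truth, tolerance = 1e-6)
  }
})

test_that("planted bands carry more analyte signal than off-band wavelengths", {
  co <- generate_cohort(500, seed = 77)
  A <- log_transform(co$reflectance)
  s <- specs$ca_pulp
  y <- co$reference$ca_pulp_mgkg
  others <- as.matrix(co$reference[, setdiff(names(co$reference),
                                             c("sample_id", "ca_pulp_mgkg"))])
  ry <- resid(lm(y ~ others))
  pcor <- vapply(seq_along(grid), function(j) {
    abs(cor(resid(lm(A[, j] ~ others)), ry))
  }, numeric(1))
  on_band <- vapply(s$band_centers_nm,
                    function(c) which.min(abs(grid - c)), integer(1))
  off_band <- which(!planted_wavelengths(s, grid, mult = 3))
  set.seed(1)
  off_sample <- sample(off_band, 50)
  expect_gt(min(pcor[on_band]), median(pcor[off_sample]))
})

test_that("cohort tables round-trip through CSV and the truth sidecar is valid JSON", {
  co <- generate_cohort(6, seed = 2)
  d <- withr::local_tempdir()
  sp <- file.path(d, "spectra.csv"); rp <- file.path(d, "ref.csv")
  tp <- file.path(d, "truth.json")
  write_spectra_csv(co, sp); write_reference_csv(co, rp); write_truth_json(co, tp)
  spec_back <- read_spectra_csv(sp)
  expect_equal(spectra_matrix(spec_back), co$reflectance,
               tolerance = 1e-12, ignore_attr = TRUE)
  # headers print the wavelength at 2 decimals, so reread at that precision
  expect_equal(as.numeric(attr(spec_back, "grid")),
               round(as.numeric(make_grid()), 2))
  ref_back <- read_reference_csv(rp)
  expect_equal(as.data.frame(ref_back), as.data.frame(co$reference),
               tolerance = 1e-12)
  truth <- jsonlite::read_json(tp)
  expect_equal(truth$seed, 2)
  expect_length(truth$bands, 6)
})
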