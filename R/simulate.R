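# Raw-frame simulation and end-to-end cohort generation.
#
# The optical model is Beer-Lambert-like: latent absorbance
#   A(lambda) = baseline(lambda) + sum_analytes c * eps(lambda),
# latent reflectance R = 10^(-A). Each of the 5 scans distorts R by an affine
# scatter term (multiplicative gain, additive offset) plus detector noise at
# the instrument's signal-to-noise ratio, and is then re-expressed as raw
# counts I between a dark frame B and a white-reference frame W so that the
# standard calibration R = (I - B)/(W - B) inverts the distortion-free case
# exactly.

# Fixed matrix/background absorbance of pear tissue: water bands at 980 and
# 1450 nm, a C-H band near 1660 nm, a weak trough near 1200 nm, and a flat
# pedestal that keeps reflectance comfortably below 1.
matrix_baseline <- function(grid) {
  g <- function(c, w) exp(-((grid - c)^2) / (2 * w^2))
  0.15 + 0.12 * g(980, 35) + 0.25 * g(1450, 45) +
    0.08 * g(1660, 25) + 0.05 * g(1200, 40)
}

# Per-fruit nuisance chemistry: a smooth quadratic absorbance perturbation.
fruit_baseline <- function(grid, coefs) {
  t <- (grid - mean(range(grid))) / (diff(range(grid)) / 2)
  coefs[1] + coefs[2] * t + coefs[3] * t^2
}

# Per-fruit interfering compounds (sugars, phenolics, ...): a few Gaussian
# absorbance bands at random positions with random signed amplitudes. Unlike
# the quadratic baseline this background is high-rank across a cohort, which
# is what makes full-spectrum calibration on small n genuinely hard.
fruit_interferents <- function(grid, centers, widths, amps) {
  A <- numeric(length(grid))
  for (j in seq_along(centers)) {
    A <- A + amps[j] * exp(-((grid - centers[j])^2) / (2 * widths[j]^2))
  }
  A
}

latent_absorbance <- function(concs, specs, grid, baseline_coefs = c(0, 0, 0),
                              extra_absorbance = 0) {
  A <- matrix_baseline(grid) + fruit_baseline(grid, baseline_coefs) +
    extra_absorbance
  for (s in specs) {
    A <- A + concs[[paste0(analyte_key(s), "_mgkg")]] * build_absorptivity(s, grid)
  }
  pmax(A, 0)
}

#' Simulate the five raw scan frames for one fruit
#'
#' Produces dark counts, white-reference counts and five sample-count rows for
#' a single fruit, from its known concentrations. Each scan applies an affine
#' scatter distortion — gain ~ lognormal(0, `scatter_sd`), offset ~
#' normal(0, `scatter_sd`/10) — and additive noise with per-wavelength
#' amplitude `latent reflectance / noise_snr` to the latent reflectance before
#' converting back to counts.
#'
#' @param concentrations A one-row data frame (or named list) with
#'   `<element>_<tissue>_mgkg` entries covering every spec in `specs`.
#' @param specs List of [analyte_spec()] objects.
#' @param grid Wavelength grid from [make_grid()].
#' @param scatter_sd Log-scale standard deviation of the per-scan gain; 0
#'   disables scatter.
#' @param noise_snr Signal-to-noise ratio of the detector; `Inf` disables
#'   noise. The emulated instrument is rated 5000:1.
#' @param seed Integer seed.
#' @param baseline_coefs Quadratic absorbance perturbation coefficients for
#'   this fruit (constant, slope, curvature on a \[-1, 1\] wavelength scale).
#' @param extra_absorbance Additional per-fruit absorbance profile (length of
#'   `grid`), e.g. interfering-compound bands; defaults to none.
#'
#' @return A list of class `scan_set`: `white_counts` (W), `dark_counts` (B),
#'   `sample_counts` (I, 5 x p matrix), plus the `latent_reflectance` truth and
#'   the `grid`.
#' @export
simulate_frames <- function(concentrations, specs, grid, scatter_sd = 0.04,
                            noise_snr = 5000, seed = 1L,
                            baseline_coefs = c(0, 0, 0),
                            extra_absorbance = 0) {
  if (noise_snr <= 0) abort("`noise_snr` must be positive (use Inf for none).")
  if (scatter_sd < 0) abort("`scatter_sd` must be non-negative.")
  A <- latent_absorbance(concentrations, specs, grid, baseline_coefs,
                         extra_absorbance)
  r_latent <- 10^(-A)
  p <- length(grid)
  W <- 30000 + 10000 * exp(-((grid - 1300)^2) / (2 * 400^2))
  B <- rep(2000, p)
  I <- matrix(NA_real_, 5, p)
  with_seed(seed, {
    for (s in 1:5) {
      gain <- rlnorm(1, 0, scatter_sd)
      offset <- rnorm(1, 0, scatter_sd / 10)
      noise <- if (is.finite(noise_snr)) rnorm(p, 0, r_latent / noise_snr) else 0
      r_scan <- gain * r_latent + offset + noise
      I[s, ] <- B + r_scan * (W - B)
    }
  })
  structure(
    list(white_counts = W, dark_counts = B, sample_counts = I,
         latent_reflectance = r_latent, grid = grid),
    class = "scan_set"
  )
}

#' Generate a synthetic pear cohort
#'
#' End-to-end generator: concentrations are drawn with
#' [sample_concentrations()], raw frames simulated with [simulate_frames()],
#' calibrated via `R = (I - B)/(W - B)` and averaged over the five scans. The
#' latent truth (noiseless spectra, band placements, per-fruit baselines) is
#' kept on the object for oracle testing; the modelling pipeline itself never
#' reads it.
#'
#' @param n Number of fruit (>= 1); 65 matches the emulated study cohort.
#' @param specs Analyte specifications; defaults to [default_analyte_specs()].
#' @param grid Wavelength grid; defaults to the 228-point 900-1700 nm grid.
#' @param seed Integer master seed; all randomness derives from it.
#' @param scatter_sd,noise_snr Passed to [simulate_frames()].
#' @param concentration,tissue_cor Passed to [sample_concentrations()].
#' @param baseline_sd Standard deviation of the per-fruit quadratic absorbance
#'   perturbation coefficients; emulates fruit-to-fruit matrix variation.
#' @param n_interferents Number of per-fruit interfering-compound absorbance
#'   bands (random centres in the grid, widths 20-80 nm).
#' @param interferent_sd Standard deviation of the signed interferent band
#'   amplitudes (absorbance units); 0 disables the interfering background.
#' @param keep_frames Keep the raw `scan_set`s on the result (`$frames`).
#'
#' @return A list of class `nir_cohort`: `grid`, `reflectance` (n x p matrix),
#'   `reference` (tibble of concentrations), `sample_ids`, `truth` (latent
#'   reflectance, band geometry, config echo) and optionally `frames`.
#' @examples
#' cohort <- generate_cohort(n = 5, seed = 42)
#' dim(cohort$reflectance)
#' @export
generate_cohort <- function(n, specs = default_analyte_specs(),
                            grid = make_grid(), seed = 1L,
                            scatter_sd = 0.04, noise_snr = 5000,
                            concentration = 4, tissue_cor = 0.5,
                            baseline_sd = 0.01, n_interferents = 8L,
                            interferent_sd = 0.015, keep_frames = FALSE) {
  n <- check_scalar_int(n, "n")
  if (n < 1) abort("`n` must be at least 1.")
  sub <- with_seed(seed, {
    list(
      conc_seed = sample.int(.Machine$integer.max, 1),
      frame_seeds = sample.int(.Machine$integer.max, n),
      baseline_coefs = matrix(rnorm(3 * n, 0, baseline_sd), n, 3),
      interferents = lapply(seq_len(n), function(i) {
        list(centers = runif(n_interferents, min(grid), max(grid)),
             widths = runif(n_interferents, 20, 80),
             amps = rnorm(n_interferents, 0, interferent_sd))
      })
    )
  })
  reference <- sample_concentrations(specs, n, seed = sub$conc_seed,
                                     concentration = concentration,
                                     tissue_cor = tissue_cor)
  p <- length(grid)
  refl <- matrix(NA_real_, n, p)
  latent <- matrix(NA_real_, n, p)
  frames <- if (keep_frames) vector("list", n)
  for (i in seq_len(n)) {
    intf <- sub$interferents[[i]]
    fr <- simulate_frames(reference[i, ], specs, grid,
                          scatter_sd = scatter_sd, noise_snr = noise_snr,
                          seed = sub$frame_seeds[i],
                          baseline_coefs = sub$baseline_coefs[i, ],
                          extra_absorbance = fruit_interferents(
                            grid, intf$centers, intf$widths, intf$amps))
    refl[i, ] <- average_scans(reflectance(fr))
    latent[i, ] <- fr$latent_reflectance
    if (keep_frames) frames[[i]] <- fr
  }
  if (any(refl <= 0) || any(refl > 1.05)) {
    abort("Generated reflectance left (0, 1.05]; lower `scatter_sd` or check specs.")
  }
  dimnames(refl) <- list(reference$sample_id, sprintf("%.2f", as.numeric(grid)))
  out <- list(
    grid = grid,
    reflectance = refl,
    reference = reference,
    sample_ids = reference$sample_id,
    truth = list(
      latent_reflectance = latent,
      baseline_coefs = sub$baseline_coefs,
      interferents = sub$interferents,
      specs = specs,
      seed = seed, scatter_sd = scatter_sd, noise_snr = noise_snr,
      concentration = concentration, tissue_cor = tissue_cor,
      baseline_sd = baseline_sd, n_interferents = n_interferents,
      interferent_sd = interferent_sd
    )
  )
  if (keep_frames) out$frames <- frames
  structure(out, class = "nir_cohort")
}

#' @export
print.nir_cohort <- function(x, ...) {
  cat(sprintf(
    "<nir_cohort> %d fruit x %d wavelengths (%.0f-%.0f nm), %d analytes\n",
    nrow(x$reflectance), ncol(x$reflectance),
    x$grid[1], x$grid[length(x$grid)], ncol(x$reference) - 1
  ))
  invisible(x)
}

#' Tidy accessors and CSV round-trips for cohorts
#'
#' `spectra_tbl()` returns the scan-averaged spectra as a tibble (`sample_id`
#' plus one column per wavelength, named with the wavelength in nm to two
#' decimals); `write_spectra_csv()` / `read_spectra_csv()` and
#' `write_reference_csv()` / `read_reference_csv()` persist the two tables;
#' `write_truth_json()` saves the generator's latent band geometry sidecar.
#'
#' @param cohort An `nir_cohort`.
#' @param path File path.
#' @return `spectra_tbl()` a tibble; readers return tibbles (`read_spectra_csv`
#'   with a `grid` attribute); writers return `path` invisibly.
#' @export
spectra_tbl <- function(cohort) {
  tibble::as_tibble(cohort$reflectance, .name_repair = "minimal") |>
    dplyr::mutate(sample_id = cohort$sample_ids, .before = 1)
}

#' @rdname spectra_tbl
#' @export
write_spectra_csv <- function(cohort, path) {
  utils::write.csv(spectra_tbl(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname spectra_tbl
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  grid <- as.numeric(names(df)[-1])
  if (anyNA(grid)) abort("Spectra CSV must have wavelength column names.")
  out <- tibble::as_tibble(df)
  attr(out, "grid") <- structure(grid, class = "wavelength_grid")
  out
}

#' @rdname spectra_tbl
#' @export
write_reference_csv <- function(cohort, path) {
  utils::write.csv(cohort$reference, path, row.names = FALSE)
  invisible(path)
}

#' @rdname spectra_tbl
#' @export
read_reference_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname spectra_tbl
#' @export
write_truth_json <- function(cohort, path) {
  tr <- cohort$truth
  bands <- purrr::map(tr$specs, function(s) {
    list(centers_nm = s$band_centers_nm, widths_nm = s$band_widths_nm,
         strengths = s$band_strengths)
  })
  jsonlite::write_json(
    list(bands = bands, seed = tr$seed, scatter_sd = tr$scatter_sd,
         noise_snr = tr$noise_snr, concentration = tr$concentration,
         tissue_cor = tr$tissue_cor, baseline_sd = tr$baseline_sd,
         n_interferents = tr$n_interferents,
         interferent_sd = tr$interferent_sd),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# matrix view of a spectra tibble (sample_id first column)
spectra_matrix <- function(tbl) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$sample_id
  m
}
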