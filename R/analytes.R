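# Analyte specifications and the concentration / absorptivity models behind
# the synthetic cohort generator.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Define an analyte for the synthetic cohort generator
#'
#' An analyte specification couples the concentration range observed in a
#' fruit cohort (minimum, mean, maximum, mg/kg) with the near-infrared
#' absorption bands through which that analyte — via the organic compounds it
#' associates with — leaves a signature on the reflectance spectrum. Bands are
#' Gaussian in wavelength; `band_strengths` are molar-absorptivity-like
#' coefficients in absorbance units per mg/kg.
#'
#' @param element One of `"ca"`, `"b"`, `"k"`.
#' @param tissue One of `"pulp"`, `"peel"`.
#' @param min_mgkg,mean_mgkg,max_mgkg Concentration statistics (mg/kg),
#'   `min < mean < max`.
#' @param band_centers_nm Gaussian band centres, inside \[900, 1700\] nm.
#' @param band_widths_nm Gaussian band standard deviations (nm), all positive.
#' @param band_strengths Peak absorbance per mg/kg for each band.
#'
#' @return A list of class `analyte_spec`.
#' @seealso [default_analyte_specs()], [build_absorptivity()]
#' @export
analyte_spec <- function(element, tissue, min_mgkg, mean_mgkg, max_mgkg,
                         band_centers_nm, band_widths_nm,
                         band_strengths = rep(0.12 / (max_mgkg - min_mgkg),
                                              length(band_centers_nm))) {
  element <- match.arg(element, c("ca", "b", "k"))
  tissue <- match.arg(tissue, c("pulp", "peel"))
  if (!(min_mgkg < mean_mgkg && mean_mgkg < max_mgkg)) {
    abort("Need min_mgkg < mean_mgkg < max_mgkg.")
  }
  if (length(band_centers_nm) < 1) abort("At least one absorption band is required.")
  if (any(band_centers_nm < 900 | band_centers_nm > 1700)) {
    abort("Band centres must lie inside [900, 1700] nm.")
  }
  if (length(band_widths_nm) != length(band_centers_nm) ||
      length(band_strengths) != length(band_centers_nm)) {
    abort("Band centres, widths and strengths must have equal length.")
  }
  if (any(band_widths_nm <= 0)) abort("Band widths must be positive.")
  structure(
    list(
      element = element, tissue = tissue,
      min_mgkg = min_mgkg, mean_mgkg = mean_mgkg, max_mgkg = max_mgkg,
      band_centers_nm = band_centers_nm,
      band_widths_nm = band_widths_nm,
      band_strengths = band_strengths
    ),
    class = "analyte_spec"
  )
}

analyte_key <- function(spec) paste(spec$element, spec$tissue, sep = "_")

#' Default analyte specifications for a 'Huangguan' pear cohort
#'
#' Concentration minima, means and maxima follow published reference
#' measurements of calcium, boron and potassium in pear pulp and peel
#' (ICP-determined, mg/kg). Band placements sit inside the wavelength regions
#' where calibration studies report analyte-linked spectral response for each
#' element and tissue; strengths are scaled to each analyte's concentration
#' range so all six leave comparable absorbance signatures.
#'
#' @return Named list of six [analyte_spec()] objects, keyed
#'   `ca_pulp`, `b_pulp`, `k_pulp`, `ca_peel`, `b_peel`, `k_peel`.
#' @export
default_analyte_specs <- function() {
  specs <- list(
    analyte_spec("ca", "pulp", 14, 26.687, 40.5,
                 band_centers_nm = c(1150, 1250, 1480, 1640),
                 band_widths_nm = c(30, 25, 35, 30)),
    analyte_spec("b", "pulp", 2.115, 3.995, 7.865,
                 band_centers_nm = c(1010, 1310, 1590),
                 band_widths_nm = c(30, 35, 30)),
    analyte_spec("k", "pulp", 1365.8, 1783.7, 2308,
                 band_centers_nm = c(1060, 1560),
                 band_widths_nm = c(25, 30)),
    analyte_spec("ca", "peel", 281.15, 653.44, 1324.85,
                 band_centers_nm = c(1040, 1240, 1540),
                 band_widths_nm = c(30, 25, 30)),
    analyte_spec("b", "peel", 6.175, 10.646, 21.675,
                 band_centers_nm = c(960, 1260, 1600),
                 band_widths_nm = c(30, 25, 35)),
    analyte_spec("k", "peel", 2691.85, 5323.39, 10073,
                 band_centers_nm = c(1240, 1470, 1620),
                 band_widths_nm = c(30, 35, 30))
  )
  names(specs) <- vapply(specs, analyte_key, character(1))
  specs
}

# Beta shape parameters matching the unit-interval mean of a spec.
beta_shapes <- function(spec, concentration = 4) {
  m <- (spec$mean_mgkg - spec$min_mgkg) / (spec$max_mgkg - spec$min_mgkg)
  c(alpha = m * concentration, beta = (1 - m) * concentration)
}

#' Draw fruit concentrations from range-respecting Beta laws
#'
#' Each analyte concentration follows a Beta distribution rescaled to its
#' \[min, max\] range, with the Beta mean matched to the configured cohort
#' mean — so hard bounds are respected exactly and expected values are
#' calibrated. Same-element pulp and peel concentrations are coupled through a
#' Gaussian copula with correlation `tissue_cor`, reflecting that a fruit rich
#' in an element tends to be rich in both tissues.
#'
#' @param specs List of [analyte_spec()] objects (default all six).
#' @param n Number of fruit (>= 0).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param concentration Beta concentration parameter (alpha + beta); larger
#'   values give tighter distributions around the mean.
#' @param tissue_cor Latent correlation between same-element pulp and peel
#'   values, in \[0, 1).
#'
#' @return A tibble with `sample_id` and one `<element>_<tissue>_mgkg` column
#'   per spec.
#' @examples
#' sample_concentrations(n = 3, seed = 1)
#' @export
sample_concentrations <- function(specs = default_analyte_specs(), n, seed,
                                  concentration = 4, tissue_cor = 0.5) {
  n <- check_scalar_int(n, "n")
  if (n < 0) abort("`n` must be non-negative.")
  if (!all(vapply(specs, inherits, logical(1), "analyte_spec"))) {
    abort("`specs` must be a list of analyte_spec objects.")
  }
  if (tissue_cor < 0 || tissue_cor >= 1) abort("`tissue_cor` must be in [0, 1).")
  keys <- vapply(specs, analyte_key, character(1))
  cols <- stats::setNames(vector("list", length(specs)), keys)

  with_seed(seed, {
    # one latent uniform per (element, tissue); same-element tissues share a
    # Gaussian factor with loading sqrt(tissue_cor)
    elements <- unique(vapply(specs, function(s) s$element, character(1)))
    shared <- lapply(stats::setNames(elements, elements),
                     function(e) rnorm(n))
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      z <- sqrt(tissue_cor) * shared[[s$element]] +
        sqrt(1 - tissue_cor) * rnorm(n)
      u <- stats::pnorm(z)
      sh <- beta_shapes(s, concentration)
      cols[[i]] <- s$min_mgkg +
        (s$max_mgkg - s$min_mgkg) * qbeta(u, sh["alpha"], sh["beta"])
    }
  })

  out <- tibble::tibble(sample_id = sprintf("pear_%03d", seq_len(n)))
  for (k in keys) out[[paste0(k, "_mgkg")]] <- if (n > 0) cols[[k]] else numeric(0)
  out
}

#' Evaluate an analyte's absorptivity profile on a wavelength grid
#'
#' Sums the spec's Gaussian bands: for band *j* with centre \eqn{c_j}, width
#' \eqn{w_j} and strength \eqn{s_j}, the contribution at wavelength
#' \eqn{\lambda} is \eqn{s_j \exp(-(\lambda - c_j)^2 / (2 w_j^2))}. The result
#' multiplies the analyte concentration in the Beer-Lambert absorbance model.
#'
#' @param spec An [analyte_spec()].
#' @param grid A [make_grid()] wavelength grid.
#' @return Non-negative numeric vector, one value per grid point
#'   (absorbance per mg/kg).
#' @export
build_absorptivity <- function(spec, grid) {
  if (!inherits(spec, "analyte_spec")) abort("`spec` must be an analyte_spec.")
  eps <- numeric(length(grid))
  for (j in seq_along(spec$band_centers_nm)) {
    eps <- eps + spec$band_strengths[j] *
      exp(-((grid - spec$band_centers_nm[j])^2) /
            (2 * spec$band_widths_nm[j]^2))
  }
  eps
}
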