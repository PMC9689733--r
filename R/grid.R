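#' Build a uniform wavelength grid
#'
#' The handheld spectrometer emulated by the synthetic generator records 228
#' bands between 900 and 1700 nm; those are the defaults. The grid is always
#' uniform: `n_points` equally spaced wavelengths with the stated endpoints.
#'
#' @param n_points Number of grid points (>= 2).
#' @param lo_nm,hi_nm First and last wavelength in nanometres, `lo_nm < hi_nm`.
#'
#' @return A numeric vector of class `wavelength_grid`, strictly increasing,
#'   with attributes available via [grid_spacing()].
#' @examples
#' g <- make_grid()
#' length(g)
#' grid_spacing(g)
#' @export
make_grid <- function(n_points = 228L, lo_nm = 900, hi_nm = 1700) {
  n_points <- check_scalar_int(n_points, "n_points")
  if (n_points < 2) abort("`n_points` must be at least 2.")
  if (!is.finite(lo_nm) || !is.finite(hi_nm) || lo_nm >= hi_nm) {
    abort("`lo_nm` must be strictly less than `hi_nm`.")
  }
  structure(seq(lo_nm, hi_nm, length.out = n_points), class = "wavelength_grid")
}

#' @rdname make_grid
#' @param grid A `wavelength_grid` (or any increasing numeric vector).
#' @export
grid_spacing <- function(grid) {
  if (length(grid) < 2) abort("`grid` must have at least 2 points.")
  (grid[length(grid)] - grid[1]) / (length(grid) - 1)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d points, %.1f-%.1f nm (spacing %.4f nm)\n",
    length(x), x[1], x[length(x)], grid_spacing(x)
  ))
  invisible(x)
}
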