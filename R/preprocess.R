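# Reflectance calibration, scan averaging, and the thirteen named spectral
# pretreatments with train/apply semantics.

#' Calibrate raw counts to reflectance
#'
#' Applies the black/white-plate calibration `R = (I - B)/(W - B)` per
#' wavelength to each of the five scan rows.
#'
#' @param scans A `scan_set` from [simulate_frames()], or a list with
#'   `white_counts`, `dark_counts` and a 5-row `sample_counts` matrix.
#' @return A 5 x p reflectance matrix.
#' @export
reflectance <- function(scans) {
  W <- scans$white_counts; B <- scans$dark_counts; I <- scans$sample_counts
  if (any(W <= B)) abort("Degenerate calibration: white counts must exceed dark counts at every wavelength.")
  sweep(sweep(I, 2, B, "-"), 2, W - B, "/")
}

#' Average the five scans of one fruit
#'
#' @param R A 5 x p reflectance matrix.
#' @return Length-p vector of per-wavelength means.
#' @export
average_scans <- function(R) {
  R <- check_matrix(R, "R")
  if (nrow(R) != 5) abort("Expected exactly 5 scan rows.")
  colMeans(R)
}

#' Savitzky-Golay smoothing along the wavelength axis
#'
#' Each spectrum (row) is smoothed by local least-squares polynomial fitting:
#' a degree-`polyorder` polynomial is fit over each sliding window of
#' `window` points and evaluated at the window centre. At the edges the fit of
#' the nearest complete window is evaluated at the edge positions, so
#' polynomials of degree <= `polyorder` pass through unchanged everywhere.
#'
#' @param X Spectra matrix (rows = samples) or a single spectrum vector.
#' @param window Odd window length >= 3, at most the number of wavelengths.
#' @param polyorder Polynomial degree, >= 1 and < `window`.
#' @return Matrix (or vector) of the input shape.
#' @export
sg_smooth <- function(X, window = 11L, polyorder = 2L) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1)
  X <- check_matrix(X)
  window <- check_scalar_int(window, "window")
  polyorder <- check_scalar_int(polyorder, "polyorder")
  if (window %% 2 == 0 || window < 3) abort("`window` must be an odd integer >= 3.")
  if (polyorder < 1 || polyorder >= window) abort("`polyorder` must be in [1, window).")
  if (window > ncol(X)) abort("`window` exceeds the number of wavelengths.")
  # signal::sgolay gives the full projection matrix whose off-centre rows are
  # exactly the edge-window evaluations we need
  FM <- signal::sgolay(p = polyorder, n = window)
  out <- t(apply(X, 1, function(x) signal::sgolayfilt(x, FM)))
  dimnames(out) <- dimnames(X)
  if (vec) out[1, ] else out
}

#' Finite-difference spectral derivatives
#'
#' First or second derivative with respect to wavelength: central differences
#' at interior points, one-sided differences at the two edges, scaled by the
#' grid spacing.
#'
#' @param X Spectra matrix or single spectrum.
#' @param order 1 or 2.
#' @param spacing_nm Wavelength spacing in nm (> 0).
#' @return Matrix (or vector) of the input shape, in units of
#'   reflectance / nm (order 1) or reflectance / nm^2 (order 2).
#' @export
derivative <- function(X, order = 1L, spacing_nm = 800 / 227) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1)
  X <- check_matrix(X)
  if (!order %in% c(1L, 2L)) abort("`order` must be 1 or 2.")
  if (spacing_nm <= 0) abort("`spacing_nm` must be positive.")
  p <- ncol(X)
  if (p < 3) abort("Need at least 3 wavelengths for derivatives.")
  out <- X
  if (order == 1) {
    out[, 2:(p - 1)] <- (X[, 3:p] - X[, 1:(p - 2)]) / (2 * spacing_nm)
    out[, 1] <- (X[, 2] - X[, 1]) / spacing_nm
    out[, p] <- (X[, p] - X[, p - 1]) / spacing_nm
  } else {
    out[, 2:(p - 1)] <- (X[, 3:p] - 2 * X[, 2:(p - 1)] + X[, 1:(p - 2)]) / spacing_nm^2
    # one-sided second differences at the edges
    out[, 1] <- (X[, 3] - 2 * X[, 2] + X[, 1]) / spacing_nm^2
    out[, p] <- (X[, p] - 2 * X[, p - 1] + X[, p - 2]) / spacing_nm^2
  }
  if (vec) out[1, ] else out
}

#' Multiplicative scatter correction
#'
#' `msc_fit()` learns the MSC reference — the column-wise mean spectrum — from
#' training rows only. `msc_apply()` regresses each spectrum on that reference
#' (`x ~ a + b * reference`, least squares over wavelengths) and returns
#' `(x - a)/b`, undoing additive offset and multiplicative gain.
#'
#' @param X_train Training spectra matrix with at least 2 rows.
#' @param X Spectra matrix (or single spectrum) to correct.
#' @param reference Reference spectrum from `msc_fit()`.
#' @param tol Rows whose fitted slope `|b|` falls below `tol` raise a
#'   degenerate-row error.
#' @return `msc_fit()` a length-p vector; `msc_apply()` a matrix of the input
#'   shape.
#' @export
msc_fit <- function(X_train) {
  X_train <- check_matrix(X_train, "X_train")
  if (nrow(X_train) < 2) abort("MSC reference needs at least 2 training rows.")
  colMeans(X_train)
}

#' @rdname msc_fit
#' @export
msc_apply <- function(X, reference, tol = 1e-8) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1)
  X <- check_matrix(X)
  if (length(reference) != ncol(X)) abort("Reference length must match wavelength count.")
  if (sd(reference) == 0) abort("MSC reference must be non-constant.")
  rc <- reference - mean(reference)
  b <- as.vector(X %*% rc - rowMeans(X) * sum(rc)) / sum(rc^2)
  bad <- which(abs(b) < tol)
  if (length(bad)) {
    abort(sprintf("MSC degenerate row(s) with |slope| < %g: %s",
                  tol, paste(bad, collapse = ", ")))
  }
  a <- rowMeans(X) - b * mean(reference)
  out <- (X - a) / b
  dimnames(out) <- dimnames(X)
  if (vec) out[1, ] else out
}

#' Standard normal variate
#'
#' Centres each spectrum to mean 0 and scales it to unit standard deviation
#' (denominator n - 1); a reference-free scatter correction.
#'
#' @param X Spectra matrix or single spectrum.
#' @return Matrix (or vector) of the input shape.
#' @export
snv <- function(X) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1)
  X <- check_matrix(X)
  s <- apply(X, 1, sd)
  if (any(s == 0)) {
    abort(sprintf("SNV degenerate (constant) row(s): %s",
                  paste(which(s == 0), collapse = ", ")))
  }
  out <- (X - rowMeans(X)) / s
  dimnames(out) <- dimnames(X)
  if (vec) out[1, ] else out
}

#' Log transform to pseudo-absorbance
#'
#' Elementwise `log10(1/R)`, linearising concentration-signal relations under
#' a Beer-Lambert model. Set `inverse = FALSE` for plain `log10(R)`.
#'
#' @param X Reflectance matrix or single spectrum, all values > 0.
#' @param inverse Transform `1/R` (default, pseudo-absorbance) or `R`.
#' @return Matrix (or vector) of the input shape.
#' @export
log_transform <- function(X, inverse = TRUE) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1)
  X <- check_matrix(X)
  if (any(X <= 0)) abort("Log transform requires strictly positive reflectance.")
  out <- if (inverse) log10(1 / X) else log10(X)
  dimnames(out) <- dimnames(X)
  if (vec) out[1, ] else out
}

#' The thirteen named pretreatments
#'
#' `preprocess_methods()` lists the supported treatment names: the raw
#' spectrum, six elementary transforms (FD, SD, MSC, SNV, SG, LG) and six
#' compositions (SG+MSC, SG+SNV, SG+MSC+FD, SG+MSC+SD, SG+SNV+FD, SG+SNV+SD),
#' applied left-to-right as written.
#'
#' @return Character vector of the 13 names.
#' @export
preprocess_methods <- function() {
  c("Raw", "FD", "SD", "MSC", "SNV", "SG", "LG",
    "SG+MSC", "SG+SNV", "SG+MSC+FD", "SG+MSC+SD", "SG+SNV+FD", "SG+SNV+SD")
}

#' Apply a named pretreatment with train/apply semantics
#'
#' Elementary steps run left-to-right in the order the name lists them. Any
#' statistic learned from data — only MSC's reference spectrum — is computed
#' from the (already partially transformed) training rows and reused verbatim
#' on the test rows, so no test-set information leaks into the transform.
#'
#' @param method One of [preprocess_methods()].
#' @param X_train Training spectra matrix.
#' @param X_test Optional test spectra matrix with the same wavelength count.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters for the SG step.
#' @param spacing_nm Grid spacing for the derivative steps.
#'
#' @return A list of class `fitted_preprocessor`: `method`, `train` (transformed
#'   training matrix), `test` (transformed test matrix or `NULL`),
#'   `msc_reference` (present iff the method includes MSC), and the parameters.
#' @examples
#' X <- matrix(runif(40, 0.2, 0.8), 4, 10)
#' fp <- apply_named_method("SNV", X)
#' round(rowMeans(fp$train), 12)
#' @export
apply_named_method <- function(method, X_train, X_test = NULL,
                               sg_window = 11L, sg_polyorder = 2L,
                               spacing_nm = 800 / 227) {
  if (!method %in% preprocess_methods()) {
    abort(sprintf("Unknown pretreatment '%s'.", method))
  }
  X_train <- check_matrix(X_train, "X_train")
  if (!is.null(X_test)) {
    X_test <- check_matrix(X_test, "X_test")
    if (ncol(X_test) != ncol(X_train)) abort("Train/test wavelength counts differ.")
  }
  steps <- if (method == "Raw") character(0) else strsplit(method, "+", fixed = TRUE)[[1]]
  msc_reference <- NULL
  for (st in steps) {
    if (st == "MSC") {
      msc_reference <- msc_fit(X_train)
      X_train <- msc_apply(X_train, msc_reference)
      if (!is.null(X_test)) X_test <- msc_apply(X_test, msc_reference)
    } else {
      f <- switch(st,
        FD = function(M) derivative(M, 1L, spacing_nm),
        SD = function(M) derivative(M, 2L, spacing_nm),
        SNV = snv,
        SG = function(M) sg_smooth(M, sg_window, sg_polyorder),
        LG = log_transform,
        abort(sprintf("Unknown pretreatment step '%s'.", st))
      )
      X_train <- f(X_train)
      if (!is.null(X_test)) X_test <- f(X_test)
    }
  }
  structure(
    list(method = method, train = X_train, test = X_test,
         msc_reference = msc_reference,
         sg_window = sg_window, sg_polyorder = sg_polyorder,
         spacing_nm = spacing_nm),
    class = "fitted_preprocessor"
  )
}

#' Re-apply a fitted pretreatment to new spectra
#'
#' Uses the statistics stored at fit time (the MSC reference learned on the
#' training rows), so repeated calls on different batches give identical
#' per-row output.
#'
#' @param fp A `fitted_preprocessor` from [apply_named_method()].
#' @param X New spectra matrix.
#' @return Transformed matrix of the input shape.
#' @export
preprocess_apply <- function(fp, X) {
  if (!inherits(fp, "fitted_preprocessor")) abort("`fp` must be a fitted_preprocessor.")
  X <- check_matrix(X)
  steps <- if (fp$method == "Raw") character(0) else strsplit(fp$method, "+", fixed = TRUE)[[1]]
  for (st in steps) {
    X <- switch(st,
      FD = derivative(X, 1L, fp$spacing_nm),
      SD = derivative(X, 2L, fp$spacing_nm),
      MSC = msc_apply(X, fp$msc_reference),
      SNV = snv(X),
      SG = sg_smooth(X, fp$sg_window, fp$sg_polyorder),
      LG = log_transform(X)
    )
  }
  X
}
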