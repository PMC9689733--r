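#' Tidiers for pearnir result objects
#'
#' broom-style `tidy()` and `glance()` methods. `tidy()` returns the
#' per-element view of an object — coefficients per wavelength for a
#' `plsr_model`, per-tree summaries for a `gbrt_model`, the fitness trace for
#' a `ga_result`, the combined model grid for an `nir_study`. `glance()`
#' returns a one-row summary.
#'
#' @param x A `plsr_model`, `gbrt_model`, `ga_result` or `nir_study`.
#' @param ... Ignored.
#' @return A tibble.
#' @name pearnir-tidiers
NULL
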