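# ggplot2 views of the main result types.

#' Plot a cohort's spectra
#'
#' One reflectance curve per fruit across the wavelength grid.
#'
#' @param object An `nir_cohort`.
#' @param alpha Line transparency.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.nir_cohort <- function(object, alpha = 0.4, ...) {
  spectra_tbl(object) |>
    tidyr::pivot_longer(-"sample_id", names_to = "wavelength_nm",
                        values_to = "reflectance") |>
    dplyr::mutate(wavelength_nm = as.numeric(.data$wavelength_nm)) |>
    ggplot2::ggplot(ggplot2::aes(.data$wavelength_nm, .data$reflectance,
                                 group = .data$sample_id)) +
    ggplot2::geom_line(alpha = alpha, colour = "grey30") +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance") +
    ggplot2::theme_minimal()
}

#' Plot a GA fitness trace
#'
#' Best cross-validated RMSE per generation (non-increasing under elitism).
#'
#' @param object A `ga_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.ga_result <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$generation, .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Generation", y = "Best CV RMSE (mg/kg)") +
    ggplot2::theme_minimal()
}

#' Plot a study's model grid
#'
#' Prediction-set RPD per pretreatment, faceted by model family, with the
#' level-A and level-B grade boundaries marked; GA-refined rows are
#' highlighted.
#'
#' @param object An `nir_study`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.nir_study <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(stage = ifelse(.data$ga_applied, "GA-refined", "full-band")) |>
    ggplot2::ggplot(ggplot2::aes(.data$method, .data$rpd_prediction,
                                 fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(1.4, 2), linetype = "dashed") +
    ggplot2::facet_wrap(~family, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Prediction-set RPD", fill = NULL,
                  title = object$target) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
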