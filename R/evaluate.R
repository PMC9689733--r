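# Sample splitting, calibration metrics (R2, RMSE, RPD) and A/B/C grading.

#' Split a cohort into modelling and prediction sets
#'
#' Seeded shuffle of `0..n-1`-style indices (returned 1-based): the first
#' `floor(ratio * n)` shuffled samples form the modelling (calibration) set,
#' the remainder the prediction (held-out) set. With the study defaults
#' `n = 65, ratio = 0.8` this gives the 52/13 partition.
#'
#' @param n Number of samples (>= 5).
#' @param ratio Modelling-set fraction in (0, 1).
#' @param seed Integer seed.
#' @return A list of class `train_test_split` with integer vectors
#'   `modelling_idx`, `prediction_idx`, and `seed`.
#' @examples
#' sp <- split_dataset(65, seed = 7)
#' lengths(sp[1:2])
#' @export
split_dataset <- function(n, ratio = 0.8, seed = 1L) {
  n <- check_scalar_int(n, "n")
  if (n < 5) abort("`n` must be at least 5.")
  if (ratio <= 0 || ratio >= 1) abort("`ratio` must be in (0, 1).")
  n_model <- floor(ratio * n)
  if (n_model < 1 || n_model >= n) abort("`ratio` leaves an empty set.")
  perm <- with_seed(seed, sample.int(n))
  structure(
    list(modelling_idx = sort(perm[seq_len(n_model)]),
         prediction_idx = sort(perm[(n_model + 1):n]),
         seed = seed),
    class = "train_test_split"
  )
}

#' Grade a model by its RPD
#'
#' The ratio of performance to deviation (RPD) grades a calibration: level A
#' (`rpd >= 2`) supports quantitative prediction, level B (`1.4 <= rpd < 2`)
#' moderate prediction, level C (`rpd < 1.4`) is unusable.
#'
#' @param rpd Positive RPD value(s); `Inf` allowed (a perfect fit).
#' @return Character vector of `"A"`, `"B"` or `"C"`.
#' @examples
#' grade(c(2, 1.4, 1.39))
#' @export
grade <- function(rpd) {
  if (any(is.na(rpd)) || any(rpd <= 0)) abort("`rpd` must be positive.")
  dplyr::case_when(rpd >= 2 ~ "A", rpd >= 1.4 ~ "B", TRUE ~ "C")
}

#' Evaluate predictions on one sample set
#'
#' Computes the three calibration metrics: `r2`, the squared Pearson
#' correlation between measured and predicted values (0 by convention when the
#' predictions are constant); `rmse`, the root mean squared error (mg/kg); and
#' `rpd`, the standard deviation of the measured values (denominator n - 1)
#' over the RMSE, graded A/B/C by [grade()]. An alternative `r2_method =
#' "sse"` gives the 1 - SSE/SST convention, under which (with population sd)
#' `rpd = 1/sqrt(1 - r2)` holds exactly on a single set.
#'
#' @param y_true Measured reference values (length >= 3, non-constant).
#' @param y_pred Predicted values, same length.
#' @param r2_method `"correlation"` (default) or `"sse"`.
#' @return A one-row tibble: `r2`, `rmse`, `rpd`, `level`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred, r2_method = c("correlation", "sse")) {
  r2_method <- match.arg(r2_method)
  if (length(y_true) != length(y_pred)) abort("Lengths differ.")
  if (length(y_true) < 3) abort("Need at least 3 samples.")
  if (sd(y_true) == 0) abort("Degenerate target: `y_true` is constant.")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  r2 <- if (r2_method == "correlation") {
    if (sd(y_pred) == 0) 0 else cor(y_true, y_pred)^2
  } else {
    1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
  }
  rpd <- if (rmse == 0) Inf else sd(y_true) / rmse
  tibble::tibble(r2 = r2, rmse = rmse, rpd = rpd, level = grade(rpd),
                 n = length(y_true))
}

#' Summarise a reference table analyte by analyte
#'
#' Minimum, maximum and mean concentration per analyte column, in the layout
#' of a cohort-description table.
#'
#' @param reference Tibble with `sample_id` plus `<element>_<tissue>_mgkg`
#'   columns (e.g. `cohort$reference`).
#' @return Tibble with one row per analyte: `analyte`, `min_mgkg`, `max_mgkg`,
#'   `mean_mgkg`.
#' @export
summarize_reference <- function(reference) {
  if (nrow(reference) == 0) abort("`reference` must be non-empty.")
  reference |>
    tidyr::pivot_longer(-"sample_id", names_to = "analyte",
                        values_to = "mgkg") |>
    dplyr::mutate(analyte = sub("_mgkg$", "", .data$analyte)) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(min_mgkg = min(.data$mgkg),
                     max_mgkg = max(.data$mgkg),
                     mean_mgkg = mean(.data$mgkg),
                     .groups = "drop")
}
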