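# JSON serialisation of fitted objects (coefficients, trees, config echoes).

#' Serialise fitted objects to JSON
#'
#' Writes a self-contained JSON description of a fitted object: for a
#' `plsr_model` the linear form and component triplets; for a `gbrt_model`
#' the initial prediction, shrinkage and every tree's split/leaf structure;
#' for a `fitted_preprocessor` the method name, parameters and MSC reference;
#' for a `ga_result` the selected wavelengths, fitness trace and config echo.
#'
#' @param x The fitted object.
#' @param path Output file.
#' @param ... Passed on to methods (`grid` for `ga_result`, to express the
#'   mask in nm).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path, ...) UseMethod("write_model_json")

#' @export
write_model_json.plsr_model <- function(x, path, ...) {
  jsonlite::write_json(
    list(type = "plsr", n_components = x$n_components,
         coefficients = unname(x$coefficients), intercept = x$intercept,
         x_mean = unname(x$x_mean), y_mean = x$y_mean, scaled = x$scale),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
write_model_json.gbrt_model <- function(x, path, ...) {
  trees <- purrr::map(x$trees, function(tr) {
    purrr::map(tr, function(nd) {
      list(var = nd$var, threshold = nd$threshold,
           left = nd$left, right = nd$right, value = nd$value)
    })
  })
  jsonlite::write_json(
    list(type = "gbrt", initial_prediction = x$initial_prediction,
         learning_rate = x$learning_rate, n_trees = x$n_trees,
         max_depth = x$max_depth, trees = trees),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
write_model_json.fitted_preprocessor <- function(x, path, ...) {
  jsonlite::write_json(
    list(type = "preprocessor", method = x$method,
         sg_window = x$sg_window, sg_polyorder = x$sg_polyorder,
         spacing_nm = x$spacing_nm,
         msc_reference = if (is.null(x$msc_reference)) NULL else
           unname(x$msc_reference)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
write_model_json.ga_result <- function(x, path, grid = make_grid(), ...) {
  jsonlite::write_json(
    list(type = "ga_result", selected_count = x$selected_count,
         selected_nm = as.numeric(grid)[x$best_mask],
         best_fitness = x$best_fitness,
         fitness_trace = x$best_fitness_per_generation,
         config = unclass(x$config)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
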