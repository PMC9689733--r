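# Orchestration of the four-step study per (element, tissue) target:
# full-band grid over 13 pretreatments x 2 model families, qualification,
# GA refinement of qualifying PLSR models, and best-model selection.

#' Configure a calibration study
#'
#' @param treatments Subset of [preprocess_methods()] to run.
#' @param families Model families, subset of `c("PLSR", "GBRT")`.
#' @param split_ratio Modelling-set fraction (0.8 gives 52/13 at n = 65).
#' @param seed Master seed: the split, all CV fold assignments and the GA runs
#'   derive from it.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param plsr_k_max,plsr_cv_folds Component-selection settings for
#'   [select_components()].
#' @param gbrt_n_trees,gbrt_learning_rate,gbrt_max_depth,gbrt_min_samples_leaf
#'   GBRT hyperparameters (applied uniformly across treatments).
#' @param gbrt_tune Tune GBRT per treatment with [tune_gbrt()] over
#'   `gbrt_grid` instead of using the fixed settings.
#' @param gbrt_grid Grid for [tune_gbrt()] when `gbrt_tune = TRUE`.
#' @param ga A [ga_config()] for the refinement stage (its `seed` is
#'   overridden by a seed derived from the master seed).
#' @param r2_method R-squared convention for [compute_metrics()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(treatments = preprocess_methods(),
                         families = c("PLSR", "GBRT"),
                         split_ratio = 0.8, seed = 1L,
                         sg_window = 11L, sg_polyorder = 2L,
                         plsr_k_max = 20L, plsr_cv_folds = 10L,
                         gbrt_n_trees = 200L, gbrt_learning_rate = 0.05,
                         gbrt_max_depth = 3L, gbrt_min_samples_leaf = 2L,
                         gbrt_tune = FALSE, gbrt_grid = NULL,
                         ga = ga_config(), r2_method = "correlation") {
  if (!all(treatments %in% preprocess_methods())) {
    abort("`treatments` must be among preprocess_methods().")
  }
  families <- match.arg(families, c("PLSR", "GBRT"), several.ok = TRUE)
  structure(
    list(treatments = treatments, families = families,
         split_ratio = split_ratio, seed = as.integer(seed),
         sg_window = sg_window, sg_polyorder = sg_polyorder,
         plsr_k_max = plsr_k_max, plsr_cv_folds = plsr_cv_folds,
         gbrt_n_trees = gbrt_n_trees, gbrt_learning_rate = gbrt_learning_rate,
         gbrt_max_depth = gbrt_max_depth,
         gbrt_min_samples_leaf = gbrt_min_samples_leaf,
         gbrt_tune = gbrt_tune, gbrt_grid = gbrt_grid,
         ga = ga, r2_method = r2_method),
    class = "study_config"
  )
}

study_targets <- function() {
  c("ca_pulp", "b_pulp", "k_pulp", "ca_peel", "b_peel", "k_peel")
}

# deterministic sub-seeds for one study
study_seeds <- function(config, n_treatments) {
  with_seed(config$seed, {
    list(split = sample.int(.Machine$integer.max, 1),
         cv = sample.int(.Machine$integer.max, 1),
         ga = sample.int(.Machine$integer.max, n_treatments))
  })
}

# resolve (X, y) from a cohort-like dataset and a target key
study_data <- function(dataset, target) {
  target <- match.arg(target, study_targets())
  if (inherits(dataset, "nir_cohort")) {
    X <- dataset$reflectance
    reference <- dataset$reference
    spacing <- grid_spacing(dataset$grid)
  } else if (is.list(dataset) && !is.null(dataset$spectra) &&
             !is.null(dataset$reference)) {
    X <- if (is.matrix(dataset$spectra)) dataset$spectra else
      spectra_matrix(dataset$spectra)
    reference <- dataset$reference
    grid <- attr(dataset$spectra, "grid") %||% as.numeric(colnames(X))
    spacing <- if (length(grid) == ncol(X) && !anyNA(grid)) {
      grid_spacing(grid)
    } else 800 / 227
  } else {
    abort("`dataset` must be an nir_cohort or a list(spectra, reference).")
  }
  ycol <- paste0(target, "_mgkg")
  if (!ycol %in% names(reference)) {
    abort(sprintf("Reference table lacks column '%s'.", ycol))
  }
  list(X = X, y = reference[[ycol]], target = target, spacing = spacing)
}

evaluate_fit <- function(predict_fun, Xm, ym, Xp, yp, r2_method) {
  mod <- compute_metrics(ym, predict_fun(Xm), r2_method)
  pred <- compute_metrics(yp, predict_fun(Xp), r2_method)
  tibble::tibble(
    r2_modelling = mod$r2, rmse_modelling = mod$rmse,
    rpd_modelling = mod$rpd, level_modelling = mod$level,
    r2_prediction = pred$r2, rmse_prediction = pred$rmse,
    rpd_prediction = pred$rpd, level_prediction = pred$level
  )
}

#' Run the full-band model grid
#'
#' Splits the cohort once (shared across all rows so rows are comparable),
#' then fits one model per (pretreatment, family) combination: pretreatment
#' statistics are learned on the modelling rows only, PLSR component counts
#' are chosen by cross-validation, GBRT uses the configured hyperparameters.
#' Both sets are scored and graded, and each row is flagged `qualified` when
#' its prediction set reaches level B or better.
#'
#' @param dataset An `nir_cohort`, or a list with `spectra` (tibble or matrix)
#'   and `reference` (tibble).
#' @param target One of `ca_pulp`, `b_pulp`, `k_pulp`, `ca_peel`, `b_peel`,
#'   `k_peel`.
#' @param config A [study_config()].
#' @return A tibble with one row per (treatment, family): metrics for both
#'   sets, `qualified`, `ga_applied = FALSE`, and bookkeeping columns
#'   (`k_components`, `selected_count`, `mask` list-column).
#' @export
run_fullband_grid <- function(dataset, target, config = study_config()) {
  sd_ <- study_data(dataset, target)
  seeds <- study_seeds(config, length(config$treatments))
  sp <- split_dataset(nrow(sd_$X), config$split_ratio, seeds$split)
  Xm_raw <- sd_$X[sp$modelling_idx, , drop = FALSE]
  Xp_raw <- sd_$X[sp$prediction_idx, , drop = FALSE]
  ym <- sd_$y[sp$modelling_idx]
  yp <- sd_$y[sp$prediction_idx]

  rows <- purrr::map(config$treatments, function(tr) {
    fp <- tryCatch(
      apply_named_method(tr, Xm_raw, Xp_raw,
                         sg_window = config$sg_window,
                         sg_polyorder = config$sg_polyorder,
                         spacing_nm = sd_$spacing),
      error = function(e) abort(sprintf("Pretreatment '%s' failed: %s",
                                        tr, conditionMessage(e)))
    )
    purrr::map(config$families, function(fam) {
      if (fam == "PLSR") {
        k <- select_components(fp$train, ym, k_max = config$plsr_k_max,
                               folds = config$plsr_cv_folds, seed = seeds$cv)
        model <- fit_plsr(fp$train, ym, k)
        metrics <- evaluate_fit(function(M) plsr_predict(model, M),
                                fp$train, ym, fp$test, yp, config$r2_method)
        extra <- tibble::tibble(k_components = model$n_components)
      } else {
        pars <- if (isTRUE(config$gbrt_tune)) {
          tuned <- if (is.null(config$gbrt_grid)) {
            tune_gbrt(fp$train, ym, seed = seeds$cv)
          } else {
            tune_gbrt(fp$train, ym, grid = config$gbrt_grid, seed = seeds$cv)
          }
          as.list(tuned[1, ])
        } else {
          list(n_trees = config$gbrt_n_trees,
               learning_rate = config$gbrt_learning_rate,
               max_depth = config$gbrt_max_depth,
               min_samples_leaf = config$gbrt_min_samples_leaf)
        }
        model <- fit_gbrt(fp$train, ym, pars$n_trees, pars$learning_rate,
                          pars$max_depth, pars$min_samples_leaf)
        metrics <- evaluate_fit(function(M) gbrt_predict(model, M),
                                fp$train, ym, fp$test, yp, config$r2_method)
        extra <- tibble::tibble(k_components = NA_integer_)
      }
      dplyr::bind_cols(
        tibble::tibble(target = target, method = tr, family = fam),
        metrics, extra,
        tibble::tibble(
          qualified = metrics$level_prediction %in% c("A", "B"),
          ga_applied = FALSE,
          selected_count = NA_integer_,
          mask = list(NULL)
        )
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Keep the rows that met the prediction standard
#'
#' A model qualifies for GA refinement when its prediction set reaches level B
#' or better (RPD >= 1.4); refinement is applied to the PLSR family only.
#'
#' @param rows Grid tibble from [run_fullband_grid()].
#' @return The qualifying subset (possibly empty).
#' @export
qualify <- function(rows) {
  dplyr::filter(rows, .data$qualified, .data$family == "PLSR")
}

#' GA-refine the qualifying models
#'
#' For each qualifying full-band PLSR row: rebuild the same split and
#' pretreatment, evolve a wavelength mask on the treated modelling set with
#' [ga_select()], refit PLSR on the selected wavelengths (component count
#' re-chosen by CV, capped by mask size) and re-score both sets.
#'
#' @param dataset As in [run_fullband_grid()].
#' @param qualified Output of [qualify()]; must be non-empty.
#' @param config The same [study_config()] used for the full-band grid.
#' @return A tibble like the grid rows with `ga_applied = TRUE`,
#'   `selected_count`, and the mask in the `mask` list-column.
#' @export
run_ga_stage <- function(dataset, qualified, config = study_config()) {
  if (nrow(qualified) == 0) abort("Empty GA stage: no qualifying models.")
  sd_ <- study_data(dataset, qualified$target[1])
  seeds <- study_seeds(config, length(config$treatments))
  sp <- split_dataset(nrow(sd_$X), config$split_ratio, seeds$split)
  Xm_raw <- sd_$X[sp$modelling_idx, , drop = FALSE]
  Xp_raw <- sd_$X[sp$prediction_idx, , drop = FALSE]
  ym <- sd_$y[sp$modelling_idx]
  yp <- sd_$y[sp$prediction_idx]

  rows <- purrr::map(seq_len(nrow(qualified)), function(i) {
    tr <- qualified$method[i]
    fp <- apply_named_method(tr, Xm_raw, Xp_raw,
                             sg_window = config$sg_window,
                             sg_polyorder = config$sg_polyorder,
                             spacing_nm = sd_$spacing)
    ga_cfg <- config$ga
    ga_cfg$seed <- seeds$ga[match(tr, config$treatments)]
    res <- ga_select(fp$train, ym, ga_cfg)
    mask <- res$best_mask
    k <- select_components(fp$train[, mask, drop = FALSE], ym,
                           k_max = min(config$plsr_k_max, sum(mask)),
                           folds = config$plsr_cv_folds, seed = seeds$cv)
    model <- fit_plsr(fp$train[, mask, drop = FALSE], ym, k)
    metrics <- evaluate_fit(
      function(M) plsr_predict(model, M[, mask, drop = FALSE]),
      fp$train, ym, fp$test, yp, config$r2_method
    )
    dplyr::bind_cols(
      tibble::tibble(target = qualified$target[i], method = tr, family = "PLSR"),
      metrics,
      tibble::tibble(
        k_components = model$n_components,
        qualified = metrics$level_prediction %in% c("A", "B"),
        ga_applied = TRUE,
        selected_count = res$selected_count,
        mask = list(mask)
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Select the best model row
#'
#' Maximal prediction-set RPD; ties broken by higher prediction R-squared,
#' then by fewer selected wavelengths (full-band rows count as selecting
#' everything), then by row order.
#'
#' @param rows Grid tibble (full-band and/or GA-stage rows).
#' @return The single best row.
#' @export
select_best <- function(rows) {
  if (nrow(rows) == 0) abort("`rows` must be non-empty.")
  nsel <- ifelse(is.na(rows$selected_count), Inf, rows$selected_count)
  o <- order(-rows$rpd_prediction, -rows$r2_prediction, nsel)
  rows[o[1], ]
}

#' Run one complete calibration study
#'
#' The four-step procedure for a single (element, tissue) target: (1) the
#' full-band grid over all configured pretreatments and model families, (2)
#' qualification (prediction level B or better, PLSR only), (3) GA wavelength
#' refinement of the qualifiers, (4) best-model selection by prediction-set
#' RPD over all rows.
#'
#' @inheritParams run_fullband_grid
#' @return A list of class `nir_study`: `target`, `fullband`, `qualified`,
#'   `ga_stage` (empty tibble when nothing qualified), `best`, `config`, `n`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(65, seed = 11)
#' st <- run_study(cohort, "ca_pulp",
#'                 study_config(treatments = c("Raw", "SNV"),
#'                              families = "PLSR",
#'                              ga = ga_config(population_size = 10,
#'                                             generations = 5)))
#' st$best
#' }
#' @export
run_study <- function(dataset, target, config = study_config()) {
  fullband <- run_fullband_grid(dataset, target, config)
  q <- qualify(fullband)
  ga_stage <- if (nrow(q) > 0) {
    run_ga_stage(dataset, q, config)
  } else {
    fullband[0, ]
  }
  best <- select_best(dplyr::bind_rows(fullband, ga_stage))
  structure(
    list(target = target, fullband = fullband, qualified = q,
         ga_stage = ga_stage, best = best,
         any_qualified = nrow(q) > 0,
         config = config, n = nrow(study_data(dataset, target)$X)),
    class = "nir_study"
  )
}

#' @export
print.nir_study <- function(x, ...) {
  cat(sprintf("<nir_study> target %s: %d full-band rows, %d qualified, %d GA rows\n",
              x$target, nrow(x$fullband), nrow(x$qualified), nrow(x$ga_stage)))
  cat(sprintf("  best: %s-%s%s  prediction R2 = %.3f, RPD = %.3f (level %s)\n",
              x$best$method, if (x$best$ga_applied) "GA-" else "", x$best$family,
              x$best$r2_prediction, x$best$rpd_prediction,
              x$best$level_prediction))
  invisible(x)
}

#' @rdname pearnir-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.nir_study <- function(x, ...) {
  dplyr::bind_rows(x$fullband, x$ga_stage) |>
    dplyr::select(-"mask")
}

#' @rdname pearnir-tidiers
#' @export
#' @exportS3Method generics::glance
glance.nir_study <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n = x$n,
    n_models = nrow(x$fullband) + nrow(x$ga_stage),
    n_qualified = nrow(x$qualified),
    best_method = x$best$method,
    best_ga = x$best$ga_applied,
    best_rpd_prediction = x$best$rpd_prediction,
    best_level = x$best$level_prediction
  )
}

#' Serialise a study report to JSON
#'
#' Writes the full-band and GA-stage tables, the best-model identifier, the
#' selected wavelengths (nm) per GA row, and a config/seed echo.
#'
#' @param study An `nir_study`.
#' @param path Output file.
#' @param grid Optional wavelength grid used to express masks in nm.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(study, path, grid = make_grid()) {
  ga_rows <- study$ga_stage
  ga_list <- purrr::map(seq_len(nrow(ga_rows)), function(i) {
    list(method = ga_rows$method[i],
         selected_count = ga_rows$selected_count[i],
         selected_nm = as.numeric(grid)[ga_rows$mask[[i]]],
         rpd_prediction = ga_rows$rpd_prediction[i])
  })
  jsonlite::write_json(
    list(
      target = study$target,
      n = study$n,
      seed = study$config$seed,
      fullband = dplyr::select(study$fullband, -"mask"),
      ga_stage = ga_list,
      best = as.list(dplyr::select(study$best, -"mask")),
      any_qualified = study$any_qualified
    ),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
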