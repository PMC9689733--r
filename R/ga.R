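# Genetic-algorithm extraction of characteristic wavelengths: binary masks
# over the grid evolved against a cross-validated PLSR fitness.

#' GA configuration for wavelength selection
#'
#' @param population_size Number of masks per generation (>= 2).
#' @param generations Number of generations evolved.
#' @param crossover_prob Probability a mating pair undergoes uniform crossover.
#' @param mutation_prob Per-bit flip probability; default `1/p` at fit time
#'   when `NULL`.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Number of best masks copied unchanged each generation (>= 1).
#' @param init_density Probability a bit starts selected; 0.5 concentrates
#'   initial mask sizes near p/2 (about 114 of 228 wavelengths).
#' @param cv_folds Folds for the PLSR fitness.
#' @param k_max Cap on PLSR components inside the fitness.
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, generations = 60L,
                      crossover_prob = 0.8, mutation_prob = NULL,
                      tournament_size = 3L, elitism = 1L,
                      init_density = 0.5, cv_folds = 5L, k_max = 10L,
                      seed = 1L) {
  if (population_size < 2) abort("`population_size` must be >= 2.")
  if (elitism < 1 || elitism >= population_size) {
    abort("`elitism` must be in [1, population_size).")
  }
  probs <- c(crossover_prob, init_density)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must be in [0, 1].")
  if (init_density <= 0 || init_density >= 1) abort("`init_density` must be in (0, 1).")
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         tournament_size = as.integer(tournament_size),
         elitism = as.integer(elitism), init_density = init_density,
         cv_folds = as.integer(cv_folds), k_max = as.integer(k_max),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Cross-validated fitness of a wavelength mask
#'
#' Restricts the spectra to the selected wavelengths and returns the
#' cross-validated RMSE of a PLSR whose component count is chosen by the same
#' CV (capped by the masked dimension). Lower is better; deterministic given
#' the seed.
#'
#' @param mask Logical vector over wavelengths with at least 2 `TRUE` entries.
#' @param X Spectra matrix.
#' @param y Response vector.
#' @param folds CV folds (>= 2).
#' @param seed Seed for fold assignment.
#' @param k_max Cap on the candidate component count.
#' @return CV RMSE (mg/kg).
#' @export
cv_fitness <- function(mask, X, y, folds = 5L, seed = 1L, k_max = 10L) {
  X <- check_matrix(X)
  if (length(mask) != ncol(X)) abort("`mask` length must match wavelength count.")
  if (sum(mask) < 2) abort("`mask` must select at least 2 wavelengths.")
  min(cv_rmse_plsr(X[, mask, drop = FALSE], y, k_max, folds, seed))
}

# ensure a chromosome keeps >= 2 active bits (repair by random activation)
repair_mask <- function(mask) {
  need <- 2L - sum(mask)
  if (need > 0) mask[sample(which(!mask), need)] <- TRUE
  mask
}

#' Evolve a characteristic-wavelength mask
#'
#' Standard generational GA over binary masks: seeded random initialisation at
#' `init_density`, tournament selection, uniform crossover, per-bit mutation,
#' repair of masks with fewer than two wavelengths, and elitism (so the
#' recorded best fitness never worsens). Fitness is [cv_fitness()].
#'
#' @param X Spectra matrix (modelling set, already pretreated).
#' @param y Response vector.
#' @param config A [ga_config()].
#' @return A list of class `ga_result`: `best_mask` (logical), `best_fitness`
#'   (its CV RMSE), `best_fitness_per_generation` (non-increasing),
#'   `selected_count`, and the `config`.
#' @export
ga_select <- function(X, y, config = ga_config()) {
  X <- check_matrix(X)
  if (sd(y) == 0) abort("Degenerate target: `y` has zero variance.")
  if (nrow(X) < 2 * config$cv_folds) abort("Need n >= 2 * cv_folds samples.")
  p <- ncol(X)
  pmut <- config$mutation_prob %||% (1 / p)
  pop_n <- config$population_size

  with_seed(config$seed, {
    fold_seed <- sample.int(.Machine$integer.max, 1)
    pop <- lapply(seq_len(pop_n), function(i) {
      repair_mask(runif(p) < config$init_density)
    })
    fit <- vapply(pop, function(msk) {
      cv_fitness(msk, X, y, folds = config$cv_folds, seed = fold_seed,
                 k_max = config$k_max)
    }, numeric(1))
    best_trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fit)
      new_pop <- pop[ord[seq_len(config$elitism)]]
      new_fit <- fit[ord[seq_len(config$elitism)]]
      while (length(new_pop) < pop_n) {
        pick <- function() {
          cand <- sample.int(pop_n, config$tournament_size, replace = TRUE)
          pop[[cand[which.min(fit[cand])]]]
        }
        c1 <- pick(); c2 <- pick()
        if (runif(1) < config$crossover_prob) {
          swap <- runif(p) < 0.5
          tmp <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmp
        }
        for (child in list(c1, c2)) {
          if (length(new_pop) >= pop_n) break
          flip <- runif(p) < pmut
          child <- xor(child, flip)
          child <- repair_mask(child)
          new_pop[[length(new_pop) + 1L]] <- child
          new_fit <- c(new_fit, cv_fitness(child, X, y,
                                           folds = config$cv_folds,
                                           seed = fold_seed,
                                           k_max = config$k_max))
        }
      }
      pop <- new_pop
      fit <- new_fit
      best_trace[g] <- min(fit)
    }
    b <- which.min(fit)
    structure(
      list(best_mask = pop[[b]], best_fitness = fit[b],
           best_fitness_per_generation = best_trace,
           selected_count = sum(pop[[b]]),
           config = config),
      class = "ga_result"
    )
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> %d wavelengths selected (CV RMSE %.4g) after %d generations\n",
    x$selected_count, x$best_fitness, length(x$best_fitness_per_generation)
  ))
  invisible(x)
}

#' @rdname pearnir-tidiers
#' @export
#' @exportS3Method generics::tidy
tidy.ga_result <- function(x, ...) {
  tibble::tibble(
    generation = seq_along(x$best_fitness_per_generation),
    best_fitness = x$best_fitness_per_generation
  )
}

#' @rdname pearnir-tidiers
#' @export
#' @exportS3Method generics::glance
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    selected_count = x$selected_count,
    best_fitness = x$best_fitness,
    generations = length(x$best_fitness_per_generation),
    population_size = x$config$population_size
  )
}
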