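make_ga_data <- function(n = 40, seed = 60) {
  co <- generate_cohort(n, seed = seed)
  sp <- split_dataset(n, seed = seed + 1)
  list(X = co$reflectance[sp$modelling_idx, ],
       y = co$reference$ca_pulp_mgkg[sp$modelling_idx],
       spec = default_analyte_specs()$ca_pulp)
}

test_that("mask fitness is consistent, deterministic, and guarded", {
  d <- make_ga_data()
  full <- rep(TRUE, ncol(d$X))
  f_full <- cv_fitness(full, d$X, d$y, folds = 4, seed = 3)
  direct <- min(pearnir:::cv_rmse_plsr(d$X, d$y, 10, folds = 4, seed = 3))
  expect_equal(f_full, direct)
  msk <- rep(c(TRUE, FALSE), length.out = ncol(d$X))
  expect_identical(cv_fitness(msk, d$X, d$y, folds = 4, seed = 3),
                   cv_fitness(msk, d$X, d$y, folds = 4, seed = 3))
  expect_error(cv_fitness(rep(FALSE, ncol(d$X)), d$X, d$y), "at least 2")
})

test_that("the planted-band mask beats random masks of equal size", {
  # single analyte, nuisance off: the planted bands are then the only
  # informative wavelengths, so a band-only mask must score best
  specs1 <- default_analyte_specs()["ca_pulp"]
  co <- generate_cohort(50, specs = specs1, seed = 61,
                        scatter_sd = 0, baseline_sd = 0, interferent_sd = 0)
  sp <- split_dataset(50, seed = 62)
  X <- co$reflectance[sp$modelling_idx, ]
  y <- co$reference$ca_pulp_mgkg[sp$modelling_idx]
  grid <- make_grid()
  planted <- planted_wavelengths(specs1$ca_pulp, grid, mult = 1.5)
  f_planted <- cv_fitness(planted, X, y, folds = 4, seed = 5)
  set.seed(99)
  f_rand <- replicate(50, {
    msk <- rep(FALSE, length(planted))
    msk[sample(length(planted), sum(planted))] <- TRUE
    cv_fitness(msk, X, y, folds = 4, seed = 5)
  })
  expect_lt(f_planted, median(f_rand))
})

test_that("the GA returns a valid, reproducible mask with a non-increasing trace", {
  d <- make_ga_data(n = 40, seed = 62)
  cfg <- ga_config(population_size = 12, generations = 6, cv_folds = 4,
                   k_max = 8, seed = 17)
  res <- ga_select(d$X, d$y, cfg)
  expect_s3_class(res, "ga_result")
  expect_gte(res$selected_count, 2)
  expect_equal(res$selected_count, sum(res$best_mask))
  expect_true(all(diff(res$best_fitness_per_generation) <= 1e-12))
  res2 <- ga_select(d$X, d$y, cfg)
  expect_identical(res$best_mask, res2$best_mask)
  expect_identical(res$best_fitness_per_generation,
                   res2$best_fitness_per_generation)
  # initial density 0.5 keeps selected counts in the central range
  expect_gt(res$selected_count, 228 * 0.25)
  expect_lt(res$selected_count, 228 * 0.75)
  expect_error(ga_select(d$X, rep(1, nrow(d$X)), cfg), "zero variance")
  td <- tidy(res)
  expect_equal(nrow(td), 6)
  expect_equal(glance(res)$selected_count, res$selected_count)
})

test_that("ga_config validates its probabilities and sizes", {
  expect_error(ga_config(population_size = 1), "population_size")
  expect_error(ga_config(crossover_prob = 1.5), "Probabilities")
  expect_error(ga_config(init_density = 0), "init_density")
  expect_error(ga_config(elitism = 50, population_size = 50), "elitism")
})
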