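test_that("optimizer configs validate their invariants", {
  expect_error(optimizer_config(population_size = 5), "even")
  expect_error(optimizer_config(population_size = 2), "even")
  expect_error(optimizer_config(generations = 0), ">= 1")
  expect_error(dosa_config(k_outer = 1), ">= 2")
  d <- dosa_config(main = optimizer_config(population_size = 20,
                                           generations = 10, seed = 4))
  expect_equal(d$tuning$population_size, 10L)
  expect_equal(d$tuning$generations, 5L)
})

test_that("the GA returns a deterministic, self-consistent front", {
  d <- cls_data(n = 30, p = 20, k = 1, sep = 4, seed = 6)
  objs <- cheap_objectives(cap = 20)
  cfg <- optimizer_config(population_size = 6, generations = 2, seed = 12)
  ss1 <- ga_optimize(objs, d, cfg)
  ss2 <- ga_optimize(objs, d, cfg)
  expect_identical(fitness_matrix(ss1), fitness_matrix(ss2))
  expect_identical(lapply(ss1$solutions, `[[`, "features"),
                   lapply(ss2$solutions, `[[`, "features"))
  expect_gte(length(ss1$solutions), 1)
  # front filtering is idempotent
  X <- fitness_matrix(ss1)
  expect_equal(nondominated_front(X), seq_len(nrow(X)))
  # unique feature sets
  keys <- vapply(ss1$solutions, function(s) paste(s$features, collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  # single-objective contract: a front is still returned
  s1 <- ga_optimize(objs[1], d, cfg)
  expect_gte(length(s1$solutions), 1)
})

test_that("evaluation count respects the budget", {
  d <- cls_data(n = 20, p = 15, seed = 2)
  cfg <- optimizer_config(population_size = 4, generations = 1, seed = 5)
  ss <- ga_optimize(cheap_objectives(cap = 15, B = 10), d, cfg)
  expect_lte(ss$meta$n_evaluated, 8)  # parents + offspring
  cfg2 <- optimizer_config(population_size = 6, generations = 3, seed = 5)
  ss2 <- ga_optimize(cheap_objectives(cap = 15, B = 10), d, cfg2)
  expect_lte(ss2$meta$n_evaluated, 6 * 4)
})

test_that("the GA recovers a perfectly separable informative feature", {
  d <- generate_classification(n_samples = 30, n_features = 25,
                               n_informative = 1, separation = 10,
                               noise_sd = 0.1, seed = 9)
  cfg <- optimizer_config(population_size = 10, generations = 5,
                          init_max_features = 5, seed = 21)
  ss <- ga_optimize(cheap_objectives(cap = 25), d, cfg)
  tb <- tidy(ss)
  best <- dplyr::filter(tb, objective == "balanced_accuracy", fitness == 1,
                        n_feat == 1)
  expect_gte(nrow(best), 1)
  expect_true(any(vapply(ss$solutions,
                         function(s) identical(s$features, 1L), logical(1))))
})

test_that("a failing objective aborts the run with its name", {
  d <- cls_data(n = 20, p = 10, seed = 2)
  bad <- objective_parsimony(name = "broken_metric")
  bad$evaluator <- function(fs, data, seed) stop("boom")
  cfg <- optimizer_config(population_size = 4, generations = 1, seed = 1)
  expect_error(ga_optimize(list(bad), d, cfg), "broken_metric")
})

test_that("zero adjustment reproduces the bare GA exactly", {
  d <- cls_data(n = 30, p = 25, seed = 14)
  objs <- cheap_objectives(cap = 25)
  cfg <- optimizer_config(population_size = 6, generations = 2, seed = 31)
  bare <- ga_optimize(objs, d, cfg)
  dz <- dosa_optimize(objs, d, dosa_config(main = cfg, k_outer = 2,
                                           adjuster_kind = "zero", seed = 31))
  expect_identical(fitness_matrix(dz), fitness_matrix(bare))
  expect_identical(sd_matrix(dz), sd_matrix(bare))
  expect_identical(lapply(dz$solutions, `[[`, "features"),
                   lapply(bare$solutions, `[[`, "features"))
})

test_that("a constant overestimation is subtracted from every reported fitness", {
  obj <- const_overest_objective(0.1)
  base_fitness <- attr(obj, "base_fitness")
  d <- cls_data(n = 24, p = 30, seed = 3)
  cfg <- optimizer_config(population_size = 6, generations = 2, seed = 8)
  ds <- dosa_optimize(list(obj, objective_parsimony(cap = 30)), d,
                      dosa_config(main = cfg, k_outer = 2,
                                  adjuster_kind = "dummy", seed = 8))
  for (s in ds$solutions) {
    fs <- feature_set(s$features, 30)
    expect_equal(s$fitness[1], base_fitness(fs) - 0.1, tolerance = 1e-9)
    # parsimony objective (sd = 0, overestimation = 0) is untouched
    expect_equal(s$fitness[2], root_leanness(length(s$features), 30),
                 tolerance = 1e-6)
  }
})

test_that("the dual-stage control flow is traceable and within budget", {
  mo_log_clear()
  d <- cls_data(n = 30, p = 20, seed = 4)
  objs <- cheap_objectives(cap = 20, B = 10)
  cfg <- optimizer_config(population_size = 4, generations = 2, seed = 3)
  dcfg <- dosa_config(main = cfg, k_outer = 2, adjuster_kind = "dummy", seed = 3)
  ds <- dosa_optimize(objs, d, dcfg)
  lg <- mo_log()
  expect_true(any(grepl("created 2 outer folds", lg)))
  expect_true(sum(grepl("fold \\d+ front size", lg)) == 2)
  expect_true(sum(grepl("adjuster\\[dummy\\] for objective", lg)) == 2)
  expect_true(any(grepl("final run with adjusted objectives", lg)))
  # inner-model fits: <= pop * (gens+1) * (k_outer stage-1 runs + final) * k_inner
  k_inner <- 5
  bound <- 4 * (2 + 1) * (2 + 1 + 1) * k_inner
  expect_lte(mo_fit_count(), bound)
})

test_that("holdout evaluation preserves parsimony and stays in [0,1]", {
  d <- cls_data(n = 30, p = 20, seed = 10)
  d2 <- cls_data(n = 30, p = 20, seed = 11)
  objs <- cheap_objectives(cap = 20, B = 10)
  ss <- ga_optimize(objs, d, optimizer_config(4, 1, seed = 2))
  Xt <- evaluate_on_holdout(ss, d, d2)
  expect_equal(dim(Xt), dim(fitness_matrix(ss)))
  expect_true(all(Xt >= 0 & Xt <= 1))
  expect_equal(Xt[, "root_leanness"], fitness_matrix(ss)[, "root_leanness"])
  # in-sample plumbing: holdout = train is well-formed
  Xin <- evaluate_on_holdout(ss, d, d)
  expect_true(all(Xin >= 0 & Xin <= 1))
  # missing outcome errors
  d_nc <- mo_dataset(d2$x)
  expect_error(evaluate_on_holdout(ss, d, d_nc), "lacks the class")
})
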