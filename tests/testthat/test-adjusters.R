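test_that("weighted median minimizes the weighted absolute error", {
  expect_equal(weighted_median(c(0.1, 0.2, 0.3), rep(1, 3)), 0.2)
  expect_equal(weighted_median(c(0.1, 0.2, 0.3), c(0.7, 0.2, 0.1)), 0.1)
  for (case in 1:200) {
    n <- sample(1:12, 1)
    v <- withr::with_seed(case, round(stats::runif(n, -0.2, 0.6), 3))
    w <- withr::with_seed(case + 1, stats::runif(n, 0.01, 1))
    expect_equal(weighted_median(v, w), wmedian_brute(v, w),
                 info = paste("case", case))
  }
})

make_samples <- function(n, f, seed = 1) {
  withr::with_seed(seed, {
    nf <- sample(1:100, n, replace = TRUE)
    fit <- stats::runif(n, 0.4, 1)
    tibble::tibble(
      fold = 1L,
      original_fitness = fit,
      fitness_sd = stats::runif(n, 0, 0.1),
      n_feat = nf,
      overestimation = f(fit, nf) + stats::rnorm(n, 0, 0.01),
      weight = rep(1 / n, n)
    )
  })
}

test_that("zero and dummy adjusters are the documented constants", {
  s <- make_samples(20, function(f, k) 0.15 * f)
  z <- fit_adjuster("zero", s)
  nd <- tibble::tibble(original_fitness = 0.9, fitness_sd = 0.05, n_feat = 40)
  expect_equal(predict_overestimation(z, nd), 0)
  d <- fit_adjuster("dummy", s)
  expect_equal(predict_overestimation(d, nd),
               wmedian_brute(s$overestimation, s$weight))
  expect_equal(predict_overestimation(d, dplyr::bind_rows(nd, nd)),
               rep(wmedian_brute(s$overestimation, s$weight), 2))
  expect_error(fit_adjuster("median", s), "arg")
})

test_that("all adjuster kinds fit deterministically under a seed", {
  s <- make_samples(40, function(f, k) 0.3 * sqrt(k / 100))
  nd <- tibble::tibble(original_fitness = seq(0.4, 0.9, length.out = 7),
                       fitness_sd = 0.05, n_feat = seq(5, 95, length.out = 7))
  for (kind in adjuster_kinds()) {
    p1 <- predict_overestimation(fit_adjuster(kind, s, seed = 9), nd)
    p2 <- predict_overestimation(fit_adjuster(kind, s, seed = 9), nd)
    expect_identical(p1, p2, info = kind)
  }
})

test_that("exactly estimated objectives yield near-zero adjusters", {
  s <- make_samples(30, function(f, k) 0)
  s$overestimation <- 0  # parsimony-like: no noise at all
  nd <- tibble::tibble(original_fitness = c(0.5, 0.8), fitness_sd = 0,
                       n_feat = c(10, 60))
  for (kind in c("zero", "dummy")) {
    expect_lt(max(abs(predict_overestimation(fit_adjuster(kind, s, 1), nd))),
              1e-6)
  }
  for (kind in c("ptree", "rfreg")) {
    expect_lt(max(abs(predict_overestimation(fit_adjuster(kind, s, 1), nd))),
              0.02)
  }
})

test_that("tree and forest recover a monotone overestimation law", {
  truth <- function(f, k) 0.3 * sqrt(k / 100)
  s <- make_samples(150, truth, seed = 5)
  grid <- tibble::tibble(original_fitness = 0.7, fitness_sd = 0.05,
                         n_feat = seq(2, 98, by = 4))
  for (kind in c("ptree", "rfreg")) {
    m <- fit_adjuster(kind, s, seed = 2)
    pred <- predict_overestimation(m, grid)
    expect_gt(stats::cor(pred, truth(0.7, grid$n_feat), method = "spearman"),
              0.9)
    expect_lt(max(abs(pred - truth(0.7, grid$n_feat))), 0.1)
  }
})

test_that("learned regressors beat the constant baseline when a trend exists", {
  truth <- function(f, k) 0.4 * (f - 0.4)
  s <- make_samples(120, truth, seed = 11)
  held <- make_samples(60, truth, seed = 12)
  mae <- function(kind) {
    m <- fit_adjuster(kind, s, seed = 3)
    pred <- predict_overestimation(m, held)
    sum(held$weight * abs(pred - held$overestimation))
  }
  expect_lt(mae("rfreg"), mae("dummy"))
  expect_lt(mae("svr"), mae("dummy"))
  expect_true(is.finite(mae("rsvr")))
})

test_that("adjuster samples carry overestimation and fold-normalized weights", {
  obj <- const_overest_objective(0.2)
  d <- cls_data(n = 24, p = 30, seed = 3)
  cfg <- optimizer_config(population_size = 4, generations = 1, seed = 2)
  dcfg <- dosa_config(main = cfg, k_outer = 2, adjuster_kind = "dummy", seed = 2)
  ds <- dosa_optimize(list(obj, objective_parsimony(cap = 30)), d, dcfg)
  samples <- ds$meta$adjuster_samples
  s1 <- dplyr::filter(samples, objective == 1)
  # per-fold weights each sum to 1, total mass = number of folds
  sums <- as.vector(tapply(s1$weight, s1$fold, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  expect_equal(sum(s1$weight), length(unique(s1$fold)), tolerance = 1e-9)
  # the synthetic objective overestimates by exactly 0.2 everywhere
  expect_equal(s1$overestimation, rep(0.2, nrow(s1)), tolerance = 1e-9)
  # parsimony is exactly estimated
  s2 <- dplyr::filter(samples, objective == 2)
  expect_equal(s2$overestimation, rep(0, nrow(s2)), tolerance = 1e-12)
})

test_that("single-solution fold gives the trivial sample", {
  hof <- structure(list(
    solutions = list(list(features = 1:3, n_total = 10,
                          fitness = c(0.9, 0.5), sd = c(0.04, 0),
                          test_fitness = c(0.7, 0.5))),
    objectives = list(objective_parsimony(name = "m1"),
                      objective_parsimony(name = "m2")),
    meta = list()), class = "mo_solution_set")
  s <- build_adjuster_samples(list(hof), 1)
  expect_equal(nrow(s), 1)
  expect_equal(s$original_fitness, 0.9)
  expect_equal(s$overestimation, 0.2)
  expect_equal(s$weight, 1)
  hof$solutions[[1]]$test_fitness <- NULL
  expect_error(build_adjuster_samples(list(hof), 1), "missing test fitness")
})

test_that("adjuster samples round-trip through CSV", {
  s <- make_samples(10, function(f, k) 0.1 * f, seed = 7)
  s$objective <- 1L
  path <- withr::local_tempfile(fileext = ".csv")
  export_adjuster_samples(s, path)
  s2 <- import_adjuster_samples(path)
  expect_equal(as.data.frame(s2[, names(s2)]),
               as.data.frame(s[, names(s2)]), tolerance = 1e-12)
})
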