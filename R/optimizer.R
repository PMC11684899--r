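#' Optimizer configuration
#'
#' Settings of the reference NSGA-style genetic algorithm used for wrapper
#' feature selection.
#'
#' @param population_size Even integer >= 4.
#' @param generations Number of generations (>= 1).
#' @param crossover_rate Probability that a mating pair undergoes uniform
#'   crossover.
#' @param mutation_strength Expected number of feature activations and of
#'   deactivations per mutation (`alpha`): each active feature is dropped
#'   with probability `alpha / max(1, k)` and each inactive one added with
#'   probability `alpha / (n_total - k)` for a panel of size `k`.
#' @param init_max_features Initial panels draw their size uniformly from
#'   `1..init_max_features`.
#' @param clone_retry_budget How often a duplicated offspring mask is
#'   re-mutated before being dropped.
#' @param seed Integer master seed of the run.
#' @return An object of class `mo_optimizer_config`.
#' @export
optimizer_config <- function(population_size = 20, generations = 10,
                             crossover_rate = 0.9, mutation_strength = 1,
                             init_max_features = 30, clone_retry_budget = 3,
                             seed = 1) {
  population_size <- as.integer(population_size)
  generations <- as.integer(generations)
  if (population_size < 4L || population_size %% 2L != 0L) {
    stop("population_size must be an even integer >= 4", call. = FALSE)
  }
  if (generations < 1L) stop("generations must be >= 1", call. = FALSE)
  structure(
    list(population_size = population_size, generations = generations,
         crossover_rate = crossover_rate,
         mutation_strength = mutation_strength,
         init_max_features = as.integer(init_max_features),
         clone_retry_budget = as.integer(clone_retry_budget),
         seed = as.integer(seed)),
    class = "mo_optimizer_config"
  )
}

#' Dual-stage configuration
#'
#' @param main [optimizer_config()] of the final (stage-3) run.
#' @param tuning Optional [optimizer_config()] of the per-fold stage-1 runs;
#'   defaults to half the population and half the generations of `main`.
#' @param k_outer Stage-1 fold count (>= 2).
#' @param adjuster_kind One of [adjuster_kinds()], or a vector with one
#'   kind per objective.
#' @param seed Master seed of the fold partitioning and adjuster fits.
#' @return An object of class `mo_dosa_config`.
#' @export
dosa_config <- function(main = optimizer_config(), tuning = NULL, k_outer = 3,
                        adjuster_kind = "dummy", seed = main$seed) {
  k_outer <- as.integer(k_outer)
  if (k_outer < 2L) stop("k_outer must be >= 2", call. = FALSE)
  if (is.null(tuning)) {
    half_pop <- max(4L, 2L * (main$population_size %/% 4L))
    tuning <- optimizer_config(
      population_size = half_pop,
      generations = max(1L, main$generations %/% 2L),
      crossover_rate = main$crossover_rate,
      mutation_strength = main$mutation_strength,
      init_max_features = main$init_max_features,
      clone_retry_budget = main$clone_retry_budget,
      seed = main$seed
    )
  }
  stopifnot(all(adjuster_kind %in% adjuster_kinds()))
  structure(
    list(main = main, tuning = tuning, k_outer = k_outer,
         adjuster_kind = adjuster_kind, seed = as.integer(seed)),
    class = "mo_dosa_config"
  )
}

# ---- solution sets --------------------------------------------------------

new_solution_set <- function(solutions, objectives, meta = list()) {
  structure(list(solutions = solutions, objectives = objectives, meta = meta),
            class = "mo_solution_set")
}

#' @export
print.mo_solution_set <- function(x, ...) {
  cat("<mo_solution_set> ", length(x$solutions), " solutions, ",
      length(x$objectives), " objectives (",
      paste(purrr::map_chr(x$objectives, "name"), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Fitness matrices of a solution set
#'
#' `fitness_matrix()` returns the train (inner-CV, possibly adjusted)
#' fitness, `sd_matrix()` the bootstrap SDs, `test_fitness_matrix()` the
#' fitness measured on left-out samples (NA where not computed). Rows are
#' solutions, columns objectives.
#'
#' @param ss An `mo_solution_set`.
#' @return Numeric matrix with one named column per objective.
#' @export
fitness_matrix <- function(ss) {
  extract_matrix(ss, "fitness")
}

#' @rdname fitness_matrix
#' @export
sd_matrix <- function(ss) extract_matrix(ss, "sd")

#' @rdname fitness_matrix
#' @export
test_fitness_matrix <- function(ss) extract_matrix(ss, "test_fitness")

extract_matrix <- function(ss, field) {
  m <- length(ss$objectives)
  out <- matrix(NA_real_, length(ss$solutions), m,
                dimnames = list(NULL, purrr::map_chr(ss$objectives, "name")))
  for (i in seq_along(ss$solutions)) {
    v <- ss$solutions[[i]][[field]]
    if (!is.null(v)) out[i, ] <- v
  }
  out
}

# ---- NSGA-II machinery ----------------------------------------------------

# rank 1 = non-dominated front of what remains, then peel
nds_ranks <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining) > 0) {
    r <- r + 1L
    front <- remaining[nondominated_front(F[remaining, , drop = FALSE])]
    rank[front] <- r
    remaining <- setdiff(remaining, front)
  }
  rank
}

crowding_distance <- function(F) {
  n <- nrow(F)
  d <- rep(0, n)
  if (n <= 2) return(rep(Inf, n))
  for (j in seq_len(ncol(F))) {
    ord <- order(F[, j])
    rng <- F[ord[n], j] - F[ord[1], j]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (F[ord[i + 1], j] - F[ord[i - 1], j]) / rng
      }
    }
  }
  d
}

# environmental selection to mu by (rank, crowding)
nsga_select <- function(F, mu) {
  rank <- nds_ranks(F)
  chosen <- integer(0)
  for (r in sort(unique(rank))) {
    front <- which(rank == r)
    if (length(chosen) + length(front) <= mu) {
      chosen <- c(chosen, front)
    } else {
      cd <- crowding_distance(F[front, , drop = FALSE])
      front <- front[order(-cd, front)]
      chosen <- c(chosen, front[seq_len(mu - length(chosen))])
      break
    }
  }
  sort(chosen)
}

# ---- the reference genetic algorithm --------------------------------------

#' Reference NSGA-style genetic algorithm for wrapper feature selection
#'
#' Generational loop over binary feature masks: uniform crossover, a
#' specialized mutation that removes and adds an expected
#' `mutation_strength` features per offspring, clone handling (duplicated
#' masks are re-mutated, then dropped), and NSGA-II environmental selection
#' (non-dominated sorting with crowding-distance tie-break). Every
#' evaluated solution enters a hall of fame; the returned set is the
#' non-dominated front of all solutions explored, with unique panels.
#'
#' @param objectives List of [objectives] (all maximized, in \[0,1\]).
#' @param data An [mo_dataset()].
#' @param config An [optimizer_config()]; runs are deterministic given its
#'   seed.
#' @return An `mo_solution_set`.
#' @export
ga_optimize <- function(objectives, data, config = optimizer_config()) {
  stopifnot(length(objectives) >= 1, n_samples(data) > 0)
  p <- ncol(data$x)
  mu <- config$population_size
  hof <- new.env(parent = emptyenv())
  hof$order <- character(0)

  evaluate <- function(feats) {
    key <- paste(feats, collapse = ",")
    if (!is.null(hof[[key]])) return(hof[[key]])
    fs <- feature_set(feats, p)
    eval_seed <- (config$seed + 17 * as.numeric(fs_hash(fs))) %% 2147480017
    res <- purrr::map(seq_along(objectives), function(j) {
      out <- tryCatch(
        objectives[[j]]$evaluator(fs, data,
                                  seed = as.integer((eval_seed + j) %% 2147480017)),
        error = function(e) {
          stop("objective '", objectives[[j]]$name, "' failed: ",
               conditionMessage(e), call. = FALSE)
        }
      )
      out
    })
    sol <- list(features = fs$indices, n_total = p,
                fitness = purrr::map_dbl(res, "fitness"),
                sd = purrr::map_dbl(res, "sd"),
                test_fitness = NULL)
    hof[[key]] <- sol
    hof$order <- c(hof$order, key)
    sol
  }

  mutate_mask <- function(feats) {
    k <- length(feats)
    alpha <- config$mutation_strength
    drop <- feats[stats::runif(k) < alpha / max(1, k)]
    inactive <- setdiff(seq_len(p), feats)
    add <- inactive[stats::runif(length(inactive)) < alpha / max(1, p - k)]
    sort(union(setdiff(feats, drop), add))
  }

  withr::with_seed(config$seed, {
    # initialization: panels of uniformly drawn size
    pop <- vector("list", mu)
    for (i in seq_len(mu)) {
      for (try in 1:20) {
        s <- sample.int(min(config$init_max_features, p), 1)
        feats <- sort(sample.int(p, s))
        if (!any(purrr::map_lgl(pop[seq_len(i - 1)],
                                ~ identical(.x, feats)))) break
      }
      pop[[i]] <- feats
    }
    pop_sols <- purrr::map(pop, evaluate)

    for (gen in seq_len(config$generations)) {
      F_pop <- do.call(rbind, purrr::map(pop_sols, "fitness"))
      rank <- nds_ranks(F_pop)
      cd <- crowding_distance(F_pop)
      tournament <- function() {
        c2 <- sample.int(mu, 2)
        a <- c2[1]; b <- c2[2]
        if (rank[a] < rank[b]) a
        else if (rank[b] < rank[a]) b
        else if (cd[a] >= cd[b]) a else b
      }
      keys_current <- unique(purrr::map_chr(pop, paste, collapse = ","))
      offspring <- list()
      for (o in seq_len(mu)) {
        p1 <- pop[[tournament()]]
        p2 <- pop[[tournament()]]
        child <- if (stats::runif(1) < config$crossover_rate) {
          both <- intersect(p1, p2)
          either <- setdiff(union(p1, p2), both)
          sort(c(both, either[stats::runif(length(either)) < 0.5]))
        } else {
          p1
        }
        child <- mutate_mask(child)
        tries <- 0L
        while (paste(child, collapse = ",") %in% keys_current &&
               tries < config$clone_retry_budget) {
          child <- mutate_mask(child)
          tries <- tries + 1L
        }
        if (paste(child, collapse = ",") %in% keys_current) next  # clone dropped
        if (length(child) == 0) child <- sample.int(p, 1)
        offspring[[length(offspring) + 1]] <- child
        keys_current <- c(keys_current, paste(child, collapse = ","))
      }
      off_sols <- purrr::map(offspring, evaluate)
      merged <- c(pop, offspring)
      merged_sols <- c(pop_sols, off_sols)
      F_all <- do.call(rbind, purrr::map(merged_sols, "fitness"))
      keep <- nsga_select(F_all, mu)
      pop <- merged[keep]
      pop_sols <- merged_sols[keep]
    }
  })

  all_sols <- purrr::map(hof$order, ~ hof[[.x]])
  F_hof <- do.call(rbind, purrr::map(all_sols, "fitness"))
  front <- nondominated_front(F_hof)
  log_event("GA done: %d evaluations, front size %d (pop %d, gens %d, seed %d)",
            length(all_sols), length(front), mu, config$generations,
            config$seed)
  new_solution_set(all_sols[front], objectives,
                   meta = list(n_evaluated = length(all_sols),
                               config = config,
                               feature_names = colnames(data$x)))
}

# ---- the dual-stage orchestrator ------------------------------------------

#' Dual-stage overestimation-adjusted optimization
#'
#' Stage 1 partitions the training data into `k_outer` folds, runs the
#' (cheaper) tuning optimizer on each fold's training part and measures the
#' resulting front on the fold's left-out part. Stage 2 turns every
#' solution into a regression sample — (inner-CV fitness, its SD, panel
#' size) predicting the observed overestimation, weighted by the HV partial
#' derivative — and fits one adjuster per objective. Stage 3 re-runs the
#' main optimizer on all training data with each objective replaced by its
#' adjusted version, so model selection itself sees corrected fitness.
#'
#' @param objectives List of [objectives].
#' @param data The full training [mo_dataset()].
#' @param config A [dosa_config()].
#' @return An `mo_solution_set` whose fitness values are the adjusted
#'   expected performances; fold hall-of-fames, adjuster models and
#'   training samples are attached in `$meta`.
#' @export
dosa_optimize <- function(objectives, data, config = dosa_config()) {
  m <- length(objectives)
  kinds <- rep_len(config$adjuster_kind, m)
  folds <- create_folds(data, config$k_outer, seed = config$seed)
  log_event("dosa: created %d outer folds over %d samples (seed %d)",
            config$k_outer, n_samples(data), config$seed)

  fold_hofs <- list()
  for (i in seq_len(config$k_outer)) {
    tr <- fold_train_idx(folds, i)
    te <- fold_test_idx(folds, i)
    tcfg <- config$tuning
    tcfg$seed <- (config$seed + i) %% 2147480017  # per-fold stream
    hof <- ga_optimize(objectives, dataset_subset(data, tr), tcfg)
    if (length(hof$solutions) == 0) {
      warning("fold ", i, " produced an empty front; skipped", call. = FALSE)
      next
    }
    train_part <- dataset_subset(data, tr)
    test_part <- dataset_subset(data, te)
    for (s in seq_along(hof$solutions)) {
      fs <- feature_set(hof$solutions[[s]]$features, ncol(data$x))
      hof$solutions[[s]]$test_fitness <- purrr::map_dbl(
        objectives, ~ .x$holdout_eval(fs, train_part, test_part)
      )
    }
    log_event("dosa: fold %d front size %d (train %d / test %d)",
              i, length(hof$solutions), length(tr), length(te))
    fold_hofs[[length(fold_hofs) + 1]] <- hof
  }
  if (length(fold_hofs) == 0) {
    stop("all stage-1 folds produced empty fronts", call. = FALSE)
  }

  adjusters <- vector("list", m)
  samples_all <- list()
  adjusted <- vector("list", m)
  for (j in seq_len(m)) {
    samples <- build_adjuster_samples(fold_hofs, j)
    samples$objective <- j
    samples_all[[j]] <- samples
    log_event("dosa: adjuster[%s] for objective %d ('%s') on %d samples",
              kinds[j], j, objectives[[j]]$name, nrow(samples))
    adjusters[[j]] <- fit_adjuster(kinds[j], samples,
                                   seed = (config$seed + 1000L + j) %% 2147480017)
    adjusted[[j]] <- make_adjusted_objective(objectives[[j]], adjusters[[j]])
  }

  log_event("dosa: final run with adjusted objectives on all %d samples",
            n_samples(data))
  out <- ga_optimize(adjusted, data, config$main)
  out$objectives <- objectives  # report under the original objective specs
  out$meta$adjusters <- adjusters
  out$meta$adjuster_kind <- kinds
  out$meta$fold_hofs <- fold_hofs
  out$meta$adjuster_samples <- dplyr::bind_rows(samples_all)
  out$meta$dosa_config <- config
  out
}

#' Measure a solution set on held-out data
#'
#' Refits each solution's inner model on the full training data and
#' measures every objective on the holdout samples (parsimony objectives
#' are identical between train and holdout by construction). The result is
#' the test fitness matrix X' paired with the solution set's expected
#' fitness matrix X in [mope()] and [pareto_delta()].
#'
#' @param ss An `mo_solution_set`.
#' @param train_data Training [mo_dataset()] the set was produced from.
#' @param holdout_data Held-out [mo_dataset()] with the same features.
#' @param objectives Objectives to measure; defaults to the set's own.
#' @return Numeric solutions-by-objectives matrix in \[0,1\].
#' @export
evaluate_on_holdout <- function(ss, train_data, holdout_data,
                                objectives = ss$objectives) {
  need_class <- any(purrr::map_lgl(
    objectives, ~ !is.null(.x$learner) && .x$learner$kind == "classification"))
  if (need_class && is.null(holdout_data$class)) {
    stop("holdout data lacks the class outcome", call. = FALSE)
  }
  need_surv <- any(purrr::map_lgl(
    objectives, ~ !is.null(.x$learner) && .x$learner$kind == "survival"))
  if (need_surv && is.null(holdout_data$time)) {
    stop("holdout data lacks the survival outcome", call. = FALSE)
  }
  p <- ncol(train_data$x)
  out <- matrix(NA_real_, length(ss$solutions), length(objectives),
                dimnames = list(NULL, purrr::map_chr(objectives, "name")))
  for (i in seq_along(ss$solutions)) {
    fs <- feature_set(ss$solutions[[i]]$features, p)
    out[i, ] <- purrr::map_dbl(
      objectives, ~ .x$holdout_eval(fs, train_data, holdout_data))
  }
  out
}
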