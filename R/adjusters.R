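#' Weighted median
#'
#' The minimizer of the weighted absolute error `sum(w * |v - c|)` over
#' `c`. When the minimizer is an interval, the lowest sample value among
#' the minimizers is returned, which makes the result deterministic.
#'
#' @param v Numeric values.
#' @param w Non-negative weights, same length.
#' @return Scalar weighted median.
#' @export
weighted_median <- function(v, w) {
  stopifnot(length(v) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(v)
  v <- v[ord]
  w <- w[ord]
  cw <- cumsum(w)
  v[which(cw >= sum(w) / 2)[1]]
}

#' Build overestimation training samples from fold hall-of-fames
#'
#' One regression sample per solution of each fold's front: the inner-CV
#' fitness, its SD and the panel size are the predictors, the
#' overestimation (inner-CV fitness minus the fitness measured on the
#' fold's left-out samples) is the response, and the HV-derivative weight
#' of the solution within its fold (see [assign_weights()]) is the sample
#' weight, so that each fold contributes total weight 1.
#'
#' @param fold_hofs List of per-fold solution sets ([mo_solution_set]
#'   objects) whose solutions carry test fitness.
#' @param obj_index Objective (column) index the samples are built for.
#' @return Tibble with columns `fold`, `original_fitness`, `fitness_sd`,
#'   `n_feat`, `overestimation`, `weight`.
#' @export
build_adjuster_samples <- function(fold_hofs, obj_index) {
  rows <- purrr::imap(fold_hofs, function(hof, f) {
    X <- fitness_matrix(hof)
    Xt <- test_fitness_matrix(hof)
    if (anyNA(Xt)) {
      stop("fold solutions are missing test fitness for objective ", obj_index,
           call. = FALSE)
    }
    w <- assign_weights(X, obj_index)
    tibble::tibble(
      fold = as.integer(f),
      original_fitness = unname(X[, obj_index]),
      fitness_sd = unname(sd_matrix(hof)[, obj_index]),
      n_feat = purrr::map_int(hof$solutions, ~ length(.x$features)),
      overestimation = unname(X[, obj_index] - Xt[, obj_index]),
      weight = unname(w)
    )
  })
  dplyr::bind_rows(rows)
}

#' Export / import adjuster samples
#'
#' Adjuster training samples round-trip through a plain CSV (columns fold,
#' objective, original_fitness, fitness_sd, n_feat, overestimation,
#' weight) for inspection and reuse.
#'
#' @param samples Tibble from [build_adjuster_samples()]; may carry an
#'   `objective` column when several objectives are stacked.
#' @param path File path of the CSV.
#' @return `export_adjuster_samples()` returns `path` invisibly;
#'   `import_adjuster_samples()` the tibble.
#' @export
export_adjuster_samples <- function(samples, path) {
  if (!"objective" %in% names(samples)) samples$objective <- 1L
  readr::write_csv(
    samples[, c("fold", "objective", "original_fitness", "fitness_sd",
                "n_feat", "overestimation", "weight")],
    path
  )
  invisible(path)
}

#' @rdname export_adjuster_samples
#' @export
import_adjuster_samples <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Adjuster kinds
#'
#' Six interchangeable regressors of the overestimation from the
#' meta-feature triple (fitness, SD, panel size):
#' \describe{
#'   \item{zero}{constant 0 — no adjustment, the unadjusted baseline.}
#'   \item{dummy}{the weighted median of the observed overestimations
#'     (constant predictor minimizing the weighted absolute error).}
#'   \item{ptree}{depth-limited regression tree, cost-complexity pruned by
#'     weighted 5-fold CV of the absolute error.}
#'   \item{rfreg}{random forest (500 trees) with the HV weights as case
#'     weights.}
#'   \item{svr}{epsilon-SVR with RBF kernel, C = 1, epsilon = 0.01; the HV
#'     weights enter through deterministic integer replication of rows.}
#'   \item{rsvr}{as svr, with C and epsilon picked by random search (30
#'     draws, log-uniform C in \[1e-2, 1e3\], epsilon in \[1e-3, 1e-1\])
#'     minimizing weighted MAE under 5-fold CV.}
#' }
#'
#' @return `adjuster_kinds()` returns the vector of valid kind names.
#' @export
adjuster_kinds <- function() c("zero", "dummy", "ptree", "rfreg", "svr", "rsvr")

#' Fit an overestimation adjuster
#'
#' @param kind One of [adjuster_kinds()].
#' @param samples Tibble from [build_adjuster_samples()].
#' @param seed Integer seed (tree/forest/search randomness).
#' @return Object of class `mo_adjuster` with a deterministic
#'   [predict_overestimation()] method.
#' @export
fit_adjuster <- function(kind, samples, seed = 1) {
  kind <- match.arg(kind, adjuster_kinds())
  if (kind == "zero") {
    return(new_adjuster("zero", NULL))
  }
  if (nrow(samples) < 1) stop("adjuster needs at least one sample", call. = FALSE)
  w <- samples$weight
  if (sum(w) <= 0) w <- rep(1, nrow(samples))
  y <- samples$overestimation
  df <- data.frame(original_fitness = samples$original_fitness,
                   fitness_sd = samples$fitness_sd,
                   n_feat = as.numeric(samples$n_feat))
  fit <- switch(
    kind,
    dummy = weighted_median(y, w),
    ptree = fit_ptree(df, y, w, seed),
    rfreg = withr::with_seed(seed, ranger::ranger(
      x = df, y = y, num.trees = 500, case.weights = w,
      min.node.size = 5, seed = seed, num.threads = 1
    )),
    svr = fit_svr(df, y, w, cost = 1, epsilon = 0.01),
    rsvr = fit_rsvr(df, y, w, seed)
  )
  new_adjuster(kind, fit)
}

new_adjuster <- function(kind, fit) {
  structure(list(kind = kind, fit = fit), class = "mo_adjuster")
}

#' @export
print.mo_adjuster <- function(x, ...) {
  cat("<mo_adjuster> kind =", x$kind, "\n")
  invisible(x)
}

# tree grown deep-ish, then the cp minimizing weighted CV absolute error wins
fit_ptree <- function(df, y, w, seed) {
  d <- df
  d$.y <- y
  full <- withr::with_seed(seed, rpart::rpart(
    .y ~ ., data = d, weights = w, method = "anova",
    control = rpart::rpart.control(maxdepth = 5, minsplit = 5, minbucket = 2,
                                   cp = 1e-4, xval = 0)
  ))
  cps <- unique(c(full$cptable[, "CP"], 1))
  if (length(cps) == 1 || nrow(d) < 10) {
    return(rpart::prune(full, cp = cps[1]))
  }
  folds <- withr::with_seed(seed + 1L, sample(rep_len(1:5, nrow(d))))
  cv_mae <- vapply(cps, function(cp) {
    err <- 0
    for (f in 1:5) {
      tr <- folds != f
      if (sum(tr) < 4 || !any(!tr)) next
      m <- withr::with_seed(seed + 2L, rpart::rpart(
        .y ~ ., data = d[tr, ], weights = w[tr], method = "anova",
        control = rpart::rpart.control(maxdepth = 5, minsplit = 5,
                                       minbucket = 2, cp = cp, xval = 0)
      ))
      pred <- predict(m, d[!tr, ])
      err <- err + sum(w[!tr] * abs(pred - y[!tr]))
    }
    err
  }, numeric(1))
  rpart::prune(full, cp = cps[which.min(cv_mae)])
}

# quantized importance weighting: replica counts proportional to weight,
# totalling about max(n, 50) rows so uniform weights keep every sample
svr_replicate <- function(w) {
  counts <- round(w / sum(w) * max(length(w), 50))
  if (sum(counts) < 2) {
    counts[order(-w)[1:min(2, length(w))]] <- pmax(counts[order(-w)[1:min(2, length(w))]], 1L)
  }
  rep(seq_along(w), counts)
}

fit_svr <- function(df, y, w, cost, epsilon) {
  idx <- svr_replicate(w)
  m <- suppressWarnings(e1071::svm(
    x = as.matrix(df[idx, , drop = FALSE]), y = y[idx],
    type = "eps-regression", kernel = "radial",
    cost = cost, epsilon = epsilon, scale = apply(df, 2, stats::sd) > 0
  ))
  list(model = m, cost = cost, epsilon = epsilon)
}

fit_rsvr <- function(df, y, w, seed, n_draws = 30) {
  draws <- withr::with_seed(seed, data.frame(
    cost = 10^stats::runif(n_draws, -2, 3),
    epsilon = 10^stats::runif(n_draws, -3, -1)
  ))
  n <- nrow(df)
  folds <- withr::with_seed(seed + 1L, sample(rep_len(1:5, n)))
  score <- vapply(seq_len(n_draws), function(d) {
    err <- 0
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (sum(tr) < 2) next
      m <- tryCatch(
        fit_svr(df[tr, , drop = FALSE], y[tr], w[tr],
                cost = draws$cost[d], epsilon = draws$epsilon[d]),
        error = function(e) NULL
      )
      if (is.null(m)) return(Inf)
      pred <- predict(m$model, as.matrix(df[!tr, , drop = FALSE]))
      err <- err + sum(w[!tr] * abs(pred - y[!tr]))
    }
    err
  }, numeric(1))
  best <- which.min(score)
  fit_svr(df, y, w, cost = draws$cost[best], epsilon = draws$epsilon[best])
}

#' Predict the overestimation for meta-feature triples
#'
#' @param adjuster A fitted `mo_adjuster`.
#' @param newdata Data frame with columns `original_fitness`, `fitness_sd`,
#'   `n_feat`.
#' @return Numeric vector of predicted overestimations (not clipped; the
#'   clipping to \[0,1\] of adjusted fitness lives in
#'   [make_adjusted_objective()]).
#' @export
predict_overestimation <- function(adjuster, newdata) {
  stopifnot(inherits(adjuster, "mo_adjuster"))
  n <- nrow(newdata)
  df <- data.frame(original_fitness = newdata$original_fitness,
                   fitness_sd = newdata$fitness_sd,
                   n_feat = as.numeric(newdata$n_feat))
  switch(
    adjuster$kind,
    zero = rep(0, n),
    dummy = rep(adjuster$fit, n),
    ptree = as.numeric(predict(adjuster$fit, df)),
    rfreg = as.numeric(predict(adjuster$fit, data = df,
                               num.threads = 1)$predictions),
    svr = ,
    rsvr = as.numeric(predict(adjuster$fit$model, as.matrix(df)))
  )
}

#' Train the adjuster for one objective from fold hall-of-fames
#'
#' Composes [build_adjuster_samples()] and [fit_adjuster()].
#'
#' @inheritParams build_adjuster_samples
#' @inheritParams fit_adjuster
#' @return A fitted `mo_adjuster` for this objective only.
#' @export
train_adjuster <- function(kind, fold_hofs, obj_index, seed = 1) {
  samples <- build_adjuster_samples(fold_hofs, obj_index)
  log_event("adjuster[%s] objective %d trained on %d samples from %d folds",
            kind, obj_index, nrow(samples), length(fold_hofs))
  fit_adjuster(kind, samples, seed = seed)
}
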