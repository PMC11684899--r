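#' Balanced accuracy
#'
#' Mean per-class recall. Predicted labels outside the known classes count
#' as errors for their true class.
#'
#' @param y_true Vector of true class labels (factor or coercible).
#' @param y_pred Vector of predicted labels, same length.
#' @return Scalar in \[0,1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  y_true <- factor(y_true)
  v <- balanced_accuracy_(y_true, as.character(y_pred), levels(y_true))
  if (is.na(v)) stop("every true class must be non-empty", call. = FALSE)
  v
}

# NA-returning core used by the bootstrap (undefined when a class is absent)
balanced_accuracy_ <- function(y_true, y_pred, all_classes) {
  y_true <- as.character(y_true)
  recalls <- vapply(all_classes, function(cl) {
    idx <- y_true == cl
    if (!any(idx)) return(NA_real_)
    mean(y_pred[idx] == cl)
  }, numeric(1))
  if (anyNA(recalls)) return(NA_real_)
  mean(recalls)
}

#' Concordance index
#'
#' Harrell-style c-index from brute-force pair enumeration: among pairs
#' where the subject with the strictly earlier time has an observed event,
#' the fraction in which the higher risk score belongs to that subject;
#' risk ties count 0.5.
#'
#' @param time Numeric follow-up times.
#' @param event 0/1 event indicators.
#' @param risk Numeric risk scores (higher = expected earlier event).
#' @return Scalar in \[0,1\]; 0.5 with a warning when no pair is comparable.
#' @export
concordance_index <- function(time, event, risk) {
  stopifnot(length(time) == length(event), length(time) == length(risk))
  v <- concordance_index_(time, event, risk)
  if (is.na(v)) {
    warning("no comparable pairs; returning 0.5", call. = FALSE)
    return(0.5)
  }
  v
}

concordance_index_ <- function(time, event, risk) {
  n <- length(time)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    comp <- which(time > time[i])
    if (length(comp) == 0) next
    den <- den + length(comp)
    num <- num + sum(risk[i] > risk[comp]) + 0.5 * sum(risk[i] == risk[comp])
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Root-leanness parsimony fitness
#'
#' Parsimony objective rewarding small panels on a square-root scale:
#' `max(0, 1 - sqrt(k / cap))` for a panel of `k` features. It is 1 for an
#' empty panel, 0 at the cap, and strictly decreasing in between.
#'
#' @param k Number of selected features (or a [feature_set()]).
#' @param cap Panel size at which the fitness reaches 0 (default 100).
#' @return Scalar in \[0,1\].
#' @export
root_leanness <- function(k, cap = 100) {
  if (inherits(k, "feature_set")) k <- n_features(k)
  stopifnot(cap >= 1, k >= 0)
  pmax(0, 1 - sqrt(k / cap))
}

# ---- learners -------------------------------------------------------------

#' Bundled inner learners
#'
#' Thin adapters around standard fits so the wrapper can treat classifiers
#' and survival models uniformly: `fit(x, data)` trains on the selected
#' feature columns, `predict` returns class labels (classification) or risk
#' scores (survival). A failed fit falls back to the majority class /
#' all-zero risk with a logged warning.
#'
#' @return An object of class `mo_learner`.
#' @name learners
NULL

new_learner <- function(name, kind, fit, predict) {
  structure(list(name = name, kind = kind, fit = fit, predict = predict),
            class = "mo_learner")
}

#' @rdname learners
#' @export
learner_nb <- function() {
  new_learner(
    "gaussian_nb", "classification",
    fit = function(x, y) e1071::naiveBayes(as.data.frame(x), y),
    predict = function(model, x) {
      as.character(predict(model, as.data.frame(x)))
    }
  )
}

#' @rdname learners
#' @export
learner_svm_linear <- function(cost = 1) {
  new_learner(
    "linear_svm", "classification",
    fit = function(x, y) {
      e1071::svm(x, y, kernel = "linear", type = "C-classification",
                 cost = cost, scale = FALSE)
    },
    predict = function(model, x) as.character(predict(model, x))
  )
}

#' @rdname learners
#' @export
learner_cox <- function() {
  new_learner(
    "cox_ph", "survival",
    fit = function(x, y) {
      df <- as.data.frame(x)
      df$.time <- y$time
      df$.event <- y$event
      suppressWarnings(survival::coxph(
        survival::Surv(.time, .event) ~ ., data = df,
        control = survival::coxph.control(iter.max = 50)
      ))
    },
    predict = function(model, x) {
      lp <- suppressWarnings(predict(model, newdata = as.data.frame(x),
                                     type = "lp"))
      lp[!is.finite(lp)] <- 0
      as.numeric(lp)
    }
  )
}

# fit with failure fallback; counts every attempted inner-model fit
fit_predict <- function(learner, data, fs, train_idx, test_idx) {
  xtr <- data$x[train_idx, fs$indices, drop = FALSE]
  xte <- data$x[test_idx, fs$indices, drop = FALSE]
  bump_fit_counter()
  if (learner$kind == "classification") {
    ytr <- droplevels(data$class[train_idx])
    model <- tryCatch(learner$fit(xtr, ytr), error = function(e) NULL)
    if (is.null(model)) {
      log_event("inner fit failed (%s); majority-class fallback", learner$name)
      maj <- names(which.max(table(ytr)))
      return(rep(maj, length(test_idx)))
    }
    out <- tryCatch(learner$predict(model, xte), error = function(e) NULL)
    if (is.null(out)) out <- rep(names(which.max(table(ytr))), length(test_idx))
    out
  } else {
    ytr <- list(time = data$time[train_idx], event = data$event[train_idx])
    model <- tryCatch(learner$fit(xtr, ytr), error = function(e) NULL)
    if (is.null(model)) {
      log_event("inner fit failed (%s); zero-risk fallback", learner$name)
      return(rep(0, length(test_idx)))
    }
    out <- tryCatch(learner$predict(model, xte), error = function(e) NULL)
    if (is.null(out)) out <- rep(0, length(test_idx))
    out
  }
}

# metric on pooled out-of-fold predictions; NA when undefined
pooled_metric <- function(learner, data, idx, pred) {
  if (learner$kind == "classification") {
    balanced_accuracy_(data$class[idx], pred, levels(data$class))
  } else {
    concordance_index_(data$time[idx], data$event[idx], pred)
  }
}

# ---- inner-CV fitness -----------------------------------------------------

#' Bootstrap standard deviation of a cross-validated metric
#'
#' Resamples the pooled (prediction, truth) pairs with replacement `B`
#' times, recomputing the metric on each resample; the SD over resamples
#' estimates the sampling variability of the fitness without refitting any
#' model. Resamples on which the metric is undefined (e.g. a class missing)
#' are redrawn, up to `10 * B` attempts in total.
#'
#' @param truth_idx Integer indices of the pooled samples in `data`.
#' @param pred Pooled out-of-fold predictions (labels or risk scores).
#' @param learner The `mo_learner` whose metric applies.
#' @param data The [mo_dataset()].
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return Non-negative scalar SD; 0 with a warning if every resample was
#'   undefined.
#' @export
bootstrap_sd <- function(truth_idx, pred, learner, data, B = 100, seed = 1) {
  stopifnot(B >= 2)
  n <- length(truth_idx)
  vals <- numeric(0)
  withr::with_seed(seed, {
    attempts <- 0L
    while (length(vals) < B && attempts < 10L * B) {
      attempts <- attempts + 1L
      take <- sample.int(n, n, replace = TRUE)
      v <- pooled_metric(learner, data, truth_idx[take], pred[take])
      if (!is.na(v)) vals <- c(vals, v)
    }
  })
  if (length(vals) < 2) {
    warning("bootstrap metric undefined on (almost) all resamples; sd = 0",
            call. = FALSE)
    return(0)
  }
  stats::sd(vals)
}

#' Inner cross-validated fitness of a feature set
#'
#' Fitness used by the optimizer during the search: the learner is fit on
#' each inner-CV training part restricted to the candidate features, the
#' out-of-fold predictions are pooled, and the metric (balanced accuracy or
#' concordance index) is computed once on the pooled predictions. The SD
#' comes from [bootstrap_sd()] on the same pooled pairs.
#'
#' @param fs A non-empty [feature_set()].
#' @param data An [mo_dataset()] with the outcome the learner needs.
#' @param learner A bundled learner, see [learners].
#' @param k_inner Number of inner folds (default 5, stratified).
#' @param B Bootstrap resamples for the SD.
#' @param seed Integer seed; the same seed gives identical results.
#' @return List with `fitness` in \[0,1\], `sd >= 0`, `n_features`.
#' @export
inner_cv_fitness <- function(fs, data, learner, k_inner = 5, B = 100, seed = 1) {
  if (n_features(fs) == 0) {
    stop("cannot evaluate an empty feature set", call. = FALSE)
  }
  folds <- create_folds(data, k_inner, seed)
  idx_all <- integer(0)
  pred_all <- if (learner$kind == "classification") character(0) else numeric(0)
  for (i in seq_len(k_inner)) {
    te <- fold_test_idx(folds, i)
    tr <- fold_train_idx(folds, i)
    pred_all <- c(pred_all, fit_predict(learner, data, fs, tr, te))
    idx_all <- c(idx_all, te)
  }
  fit <- pooled_metric(learner, data, idx_all, pred_all)
  if (is.na(fit)) fit <- if (learner$kind == "survival") 0.5 else 0
  sd <- bootstrap_sd(idx_all, pred_all, learner, data, B = B,
                     seed = (seed + 7919L) %% 2147480017L)
  list(fitness = min(max(fit, 0), 1), sd = sd, n_features = n_features(fs))
}

# ---- objective specs ------------------------------------------------------

new_objective <- function(name, kind, evaluator, holdout_eval, learner = NULL) {
  structure(
    list(name = name, kind = kind, evaluator = evaluator,
         holdout_eval = holdout_eval, learner = learner),
    class = "mo_objective"
  )
}

#' @export
print.mo_objective <- function(x, ...) {
  cat("<mo_objective> ", x$name, " (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' Objective specifications
#'
#' An objective bundles a fitness evaluator (maximized, in \[0,1\]) with
#' the way the same quantity is measured on held-out samples.
#' `objective_classification()` and `objective_survival()` wrap an inner
#' learner evaluated by [inner_cv_fitness()]; `objective_parsimony()` is
#' the deterministic [root_leanness()] of the panel size (SD 0).
#'
#' @param learner Inner learner, see [learners].
#' @param k_inner Inner CV folds.
#' @param B Bootstrap resamples for the fitness SD.
#' @param cap Panel size at which root-leanness reaches 0.
#' @param name Objective name used in reports.
#' @return An object of class `mo_objective`.
#' @name objectives
NULL

#' @rdname objectives
#' @export
objective_classification <- function(learner = learner_nb(), k_inner = 5,
                                     B = 100, name = "balanced_accuracy") {
  stopifnot(learner$kind == "classification")
  new_objective(
    name, "model_metric",
    evaluator = function(fs, data, seed) {
      inner_cv_fitness(fs, data, learner, k_inner = k_inner, B = B, seed = seed)
    },
    holdout_eval = function(fs, train_data, test_data) {
      holdout_metric(learner, fs, train_data, test_data)
    },
    learner = learner
  )
}

#' @rdname objectives
#' @export
objective_survival <- function(learner = learner_cox(), k_inner = 5,
                               B = 100, name = "c_index") {
  stopifnot(learner$kind == "survival")
  new_objective(
    name, "model_metric",
    evaluator = function(fs, data, seed) {
      inner_cv_fitness(fs, data, learner, k_inner = k_inner, B = B, seed = seed)
    },
    holdout_eval = function(fs, train_data, test_data) {
      holdout_metric(learner, fs, train_data, test_data)
    },
    learner = learner
  )
}

#' @rdname objectives
#' @export
objective_parsimony <- function(cap = 100, name = "root_leanness") {
  new_objective(
    name, "parsimony",
    evaluator = function(fs, data, seed) {
      list(fitness = root_leanness(n_features(fs), cap), sd = 0,
           n_features = n_features(fs))
    },
    holdout_eval = function(fs, train_data, test_data) {
      root_leanness(n_features(fs), cap)
    }
  )
}

# metric of a model trained on all of train_data, measured on test_data
holdout_metric <- function(learner, fs, train_data, test_data) {
  pred <- fit_predict(learner, combine_datasets(train_data, test_data), fs,
                      seq_len(n_samples(train_data)),
                      n_samples(train_data) + seq_len(n_samples(test_data)))
  v <- pooled_metric(learner,
                     combine_datasets(train_data, test_data),
                     n_samples(train_data) + seq_len(n_samples(test_data)),
                     pred)
  if (is.na(v)) v <- if (learner$kind == "survival") 0.5 else 0
  min(max(v, 0), 1)
}

combine_datasets <- function(a, b) {
  mo_dataset(
    rbind(a$x, b$x),
    class = if (!is.null(a$class)) {
      factor(c(as.character(a$class), as.character(b$class)),
             levels = union(levels(a$class), levels(b$class)))
    },
    time = if (!is.null(a$time)) c(a$time, b$time),
    event = if (!is.null(a$time)) c(a$event, b$event)
  )
}

#' Wrap an objective with a trained overestimation adjuster
#'
#' The adjusted evaluator computes the base fitness, its SD and the panel
#' size, asks the adjuster for the predicted overestimation of that triple,
#' and reports `clip(fitness - prediction, 0, 1)` with the base SD
#' unchanged. The held-out measurement is untouched.
#'
#' @param base An `mo_objective`.
#' @param adjuster A fitted adjuster from [fit_adjuster()].
#' @return An adjusted `mo_objective`.
#' @export
make_adjusted_objective <- function(base, adjuster) {
  stopifnot(inherits(base, "mo_objective"), inherits(adjuster, "mo_adjuster"))
  obj <- new_objective(
    base$name, base$kind,
    evaluator = function(fs, data, seed) {
      res <- base$evaluator(fs, data, seed)
      over <- predict_overestimation(
        adjuster,
        tibble::tibble(original_fitness = res$fitness, fitness_sd = res$sd,
                       n_feat = res$n_features)
      )
      res$fitness <- min(max(res$fitness - over, 0), 1)
      res
    },
    holdout_eval = base$holdout_eval,
    learner = base$learner
  )
  obj$adjuster <- adjuster
  obj
}
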