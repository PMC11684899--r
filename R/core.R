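#' Construct a feature set
#'
#' A feature set is one candidate solution of the wrapper feature-selection
#' problem: the indices (1-based) of the columns of the expression matrix
#' that form a candidate biomarker panel.
#'
#' @param indices Integer vector of selected feature indices (1-based).
#'   Duplicates are removed and the result is kept sorted.
#' @param n_total Total number of features in the dataset.
#' @return An object of class `feature_set`.
#' @export
#' @examples
#' feature_set(c(3, 1), n_total = 10)
feature_set <- function(indices, n_total) {
  indices <- sort(unique(as.integer(indices)))
  n_total <- as.integer(n_total)
  if (length(indices) > 0 && (min(indices) < 1L || max(indices) > n_total)) {
    stop("feature indices must lie in [1, n_total]", call. = FALSE)
  }
  structure(list(indices = indices, n_total = n_total), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", length(x$indices), " of ", x$n_total, " features\n",
      sep = "")
  invisible(x)
}

#' Number of features in a feature set
#' @param fs A `feature_set`.
#' @return Integer count of selected features.
#' @export
n_features <- function(fs) length(fs$indices)

# stable key for hall-of-fame bookkeeping and seed derivation
fs_key <- function(fs) paste(fs$indices, collapse = ",")

# deterministic small-integer hash of a feature set, for per-evaluation seeds
fs_hash <- function(fs) {
  h <- length(fs$indices)
  for (i in fs$indices) h <- (h * 131 + i) %% 2147480017
  as.integer(h)
}

#' Pareto dominance between two fitness vectors
#'
#' All objectives are maximized: `a` dominates `b` when it is at least as
#' good in every objective and strictly better in at least one.
#'
#' @param a,b Numeric fitness vectors of equal length.
#' @return Logical scalar.
#' @export
#' @examples
#' dominates(c(0.6, 0.5), c(0.5, 0.5)) # TRUE
#' dominates(c(0.6, 0.4), c(0.5, 0.5)) # FALSE (trade-off)
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fitness vectors must have equal length", call. = FALSE)
  }
  all(a >= b) && any(a > b)
}

#' Non-dominated front of a fitness matrix
#'
#' Returns the row indices of the mutually non-dominated rows of `points`
#' (rows are solutions, columns are maximized objectives in \[0,1\]).
#' Exact duplicate rows on the front are collapsed to the one with the
#' lowest row index, so the result is deterministic.
#'
#' @param points Numeric matrix, one row per solution.
#' @return Integer vector of retained row indices (possibly empty).
#' @export
#' @examples
#' nondominated_front(rbind(c(0.2, 0.8), c(0.8, 0.2), c(0.1, 0.1)))
nondominated_front <- function(points) {
  points <- as_fitness_matrix(points)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(points[j, ], points[i, ])) {
        keep[i] <- FALSE
        break
      }
      # duplicate collapse: an identical earlier row wins
      if (j < i && keep[j] && all(points[j, ] == points[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  which(keep)
}

# coerce to a validated numeric matrix of fitness values
as_fitness_matrix <- function(x, check_unit = FALSE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  if (nrow(x) > 0 && ncol(x) > 0) {
    if (any(!is.finite(x))) stop("fitness matrix must be finite", call. = FALSE)
    if (check_unit && (any(x < 0) || any(x > 1))) {
      stop("fitness values must lie in [0, 1]", call. = FALSE)
    }
  }
  x
}

#' Assemble a dataset of expression values and outcomes
#'
#' @param x Numeric samples-by-features matrix (rows are samples). Column
#'   names are used as feature names; row names as sample ids.
#' @param class Optional factor (or coercible) of class labels, one per sample.
#' @param time,event Optional numeric survival time and 0/1 event indicator,
#'   one per sample.
#' @return An object of class `mo_dataset`.
#' @export
mo_dataset <- function(x, class = NULL, time = NULL, event = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(n))
  if (!is.null(class)) {
    class <- factor(class)
    stopifnot(length(class) == n)
  }
  if (!is.null(time)) {
    stopifnot(length(time) == n, !is.null(event), length(event) == n)
    event <- as.integer(event)
    stopifnot(all(event %in% c(0L, 1L)))
  }
  structure(
    list(x = x, class = class, time = time, event = event),
    class = "mo_dataset"
  )
}

#' @export
print.mo_dataset <- function(x, ...) {
  cat("<mo_dataset> ", nrow(x$x), " samples x ", ncol(x$x), " features; ",
      "outcomes:", if (!is.null(x$class)) " class" else "",
      if (!is.null(x$time)) " survival" else "", "\n", sep = "")
  invisible(x)
}

n_samples <- function(data) nrow(data$x)

# subset an mo_dataset by sample index
dataset_subset <- function(data, idx) {
  mo_dataset(
    data$x[idx, , drop = FALSE],
    class = if (!is.null(data$class)) data$class[idx],
    time = if (!is.null(data$time)) data$time[idx],
    event = if (!is.null(data$time)) data$event[idx]
  )
}

#' Partition samples into cross-validation folds
#'
#' Folds are stratified on the class label when present, otherwise on the
#' event indicator for survival outcomes, otherwise unstratified. When a
#' stratum holds fewer than `k` samples the assignment falls back to an
#' unstratified split with a warning.
#'
#' @param data An [mo_dataset()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the same seed always gives the same assignment.
#' @return An object of class `mo_folds` with elements `k` and `assignment`
#'   (per-sample fold index in 1..k).
#' @export
create_folds <- function(data, k, seed) {
  n <- n_samples(data)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  strata <- if (!is.null(data$class)) {
    data$class
  } else if (!is.null(data$time)) {
    factor(data$event)
  } else {
    factor(rep(1L, n))
  }
  if (min(table(strata)) < k) {
    warning("a stratum has fewer than k samples; using unstratified folds",
            call. = FALSE)
    strata <- factor(rep(1L, n))
  }
  assignment <- integer(n)
  withr::with_seed(seed, {
    offset <- 0L
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      idx <- idx[sample.int(length(idx))]
      # deal fold labels round-robin, rotating the start so remainders
      # spread over folds rather than piling onto fold 1
      labs <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      assignment[idx] <- labs
      offset <- (offset + length(idx)) %% k
    }
  })
  structure(list(k = k, assignment = assignment), class = "mo_folds")
}

#' @export
print.mo_folds <- function(x, ...) {
  cat("<mo_folds> k =", x$k, "sizes:",
      paste(tabulate(x$assignment, x$k), collapse = " "), "\n")
  invisible(x)
}

fold_train_idx <- function(folds, i) which(folds$assignment != i)
fold_test_idx <- function(folds, i) which(folds$assignment == i)
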