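#' Hypervolume of a solution set
#'
#' Exact hypervolume indicator for maximized objectives normalized to
#' \[0,1\], with the reference point fixed at the origin: the Lebesgue
#' measure of the union of the axis-aligned boxes
#' `[0, x_i1] x ... x [0, x_im]`. Supports 1 to 4 objectives; the
#' two-objective case uses a sort-and-sweep, higher dimensions a recursive
#' dimension sweep over slices.
#'
#' @param points Numeric matrix with one row per solution and one column
#'   per objective, entries in \[0,1\]. A vector is treated as one row.
#' @return Non-negative scalar volume; 0 for an empty set.
#' @export
#' @examples
#' hypervolume(c(0.5, 0.5))                      # 0.25
#' hypervolume(rbind(c(0.2, 0.8), c(0.8, 0.2)))  # 0.28
hypervolume <- function(points) {
  X <- as_fitness_matrix(points, check_unit = TRUE)
  if (nrow(X) == 0 || ncol(X) == 0) return(0)
  if (ncol(X) > 4) stop("hypervolume supports at most 4 objectives", call. = FALSE)
  hv_rec(X)
}

# recursive exact HV; small-n exact algorithms, adequate for panel-scale fronts
hv_rec <- function(X) {
  m <- ncol(X)
  if (m == 1) return(max(X[, 1], 0))
  if (m == 2) {
    ord <- order(X[, 1], decreasing = TRUE)
    vol <- 0
    ymax <- 0
    for (i in ord) {
      if (X[i, 2] > ymax) {
        vol <- vol + X[i, 1] * (X[i, 2] - ymax)
        ymax <- X[i, 2]
      }
    }
    return(vol)
  }
  # sweep the last dimension: between consecutive cut heights the
  # cross-section is the (m-1)-dim union of the boxes reaching that high
  z <- sort(unique(X[, m]), decreasing = TRUE)
  z_next <- c(z[-1], 0)
  vol <- 0
  for (s in seq_along(z)) {
    sub <- X[X[, m] >= z[s], -m, drop = FALSE]
    vol <- vol + (z[s] - z_next[s]) * hv_rec(sub)
  }
  vol
}

#' Exact partial derivatives of the hypervolume
#'
#' Entry (i, j) is the right partial derivative of [hypervolume()] with
#' respect to the fitness of solution i in objective j: the
#' (m-1)-dimensional measure of the exclusive slice of box i at height
#' `x[i, j]` — the part of its cross-section not covered by any box that
#' reaches strictly higher in objective j. Rows that exactly duplicate an
#' earlier row get all zeros (the earlier copy carries the contribution),
#' and strictly dominated rows are zero everywhere.
#'
#' @inheritParams hypervolume
#' @return Matrix of the same shape as `points` with non-negative entries.
#' @export
#' @examples
#' hv_gradient(c(0.5, 0.5)) # 0.5 0.5
hv_gradient <- function(points) {
  X <- as_fitness_matrix(points, check_unit = TRUE)
  n <- nrow(X)
  m <- ncol(X)
  G <- matrix(0, n, m, dimnames = dimnames(X))
  if (n == 0 || m == 0) return(G)
  if (m == 1) {
    # measure of a 0-dim face is 1; only the (first) maximal point moves the HV
    imax <- which(X[, 1] == max(X[, 1]))[1]
    G[imax, 1] <- 1
    return(G)
  }
  dup_of_earlier <- duplicated(split(X, row(X)))
  for (i in seq_len(n)) {
    if (dup_of_earlier[i]) next
    for (j in seq_len(m)) {
      higher <- which(X[, j] > X[i, j])
      own <- X[i, -j]
      base <- prod(own)
      if (length(higher) == 0) {
        G[i, j] <- base
      } else {
        # exclusive face = vol(own box) - vol(own box  U-intersected with covers)
        capped <- sweep_pmin(X[higher, -j, drop = FALSE], own)
        G[i, j] <- max(0, base - hv_rec(capped))  # guard float underflow
      }
    }
  }
  G
}

# rowwise pmin of each row of A against vector v
sweep_pmin <- function(A, v) {
  t(pmin(t(A), v))
}

#' Cross function joining train and test coordinates
#'
#' The cross-hypervolume evaluates each solution at an effective coordinate
#' `v(train, test)`. Any function satisfying `v(x, x) = x` on \[0,1\] is
#' admissible; the default simply takes the test value clipped to \[0,1\],
#' so the cross-hypervolume is the hypervolume of the test fitness of the
#' train-selected front.
#'
#' @param f Function of two numeric arguments (train, test), vectorized.
#' @return The function, tagged for validation.
#' @export
cross_function <- function(f) {
  stopifnot(is.function(f))
  probe <- c(0, 0.25, 0.5, 1)
  if (max(abs(f(probe, probe) - probe)) > 1e-12) {
    stop("a cross function must satisfy v(x, x) = x on [0, 1]", call. = FALSE)
  }
  structure(f, class = c("cross_function", "function"))
}

#' @rdname cross_function
#' @export
cross_default <- function() {
  cross_function(function(train, test) pmin(pmax(test, 0), 1))
}

#' Cross-hypervolume of train and test fitness matrices
#'
#' Hypervolume of the matrix whose entries are `v(x_ij, x'_ij)`: the front
#' is the one chosen from training estimates, but each solution's
#' contribution is taken at the crossed coordinate. With the default cross
#' function this is the test-set hypervolume of the train-selected set.
#'
#' @param X Train fitness matrix (rows solutions, columns objectives).
#' @param X_test Test fitness matrix of identical shape.
#' @param v A [cross_function()]; default [cross_default()].
#' @return Non-negative scalar volume.
#' @export
cross_hypervolume <- function(X, X_test, v = cross_default()) {
  X <- as_fitness_matrix(X, check_unit = TRUE)
  X_test <- as_fitness_matrix(X_test, check_unit = TRUE)
  if (!all(dim(X) == dim(X_test))) {
    stop("train and test fitness matrices must have the same shape", call. = FALSE)
  }
  if (nrow(X) == 0 || ncol(X) == 0) return(0)
  M <- matrix(v(as.vector(X), as.vector(X_test)), nrow(X), ncol(X))
  hypervolume(pmin(pmax(M, 0), 1))
}

#' Multi-objective performance error (MOPE)
#'
#' Set-level estimation error of a multi-objective optimizer: the absolute
#' difference between the hypervolume computed on training estimates and
#' the cross-hypervolume that mixes in performance measured on new samples.
#'
#' @inheritParams cross_hypervolume
#' @return Non-negative scalar; 0 when train and test fitness agree.
#' @export
mope <- function(X, X_test, v = cross_default()) {
  abs(hypervolume(X) - cross_hypervolume(X, X_test, v))
}

#' Pareto delta
#'
#' Per-solution estimation error weighted by each solution's marginal
#' contribution to the training hypervolume: the absolute train-test
#' fitness gap of every solution and objective is multiplied by the partial
#' derivative of the training hypervolume at that coordinate, summed over
#' solutions, and averaged over objectives. Unlike [mope()], discrepancies
#' of opposite sign cannot cancel. Defined as exactly 0 for zero solutions
#' or zero objectives.
#'
#' @inheritParams cross_hypervolume
#' @return Non-negative scalar.
#' @export
pareto_delta <- function(X, X_test) {
  X <- as_fitness_matrix(X, check_unit = TRUE)
  X_test <- as_fitness_matrix(X_test, check_unit = TRUE)
  if (!all(dim(X) == dim(X_test))) {
    stop("train and test fitness matrices must have the same shape", call. = FALSE)
  }
  n <- nrow(X)
  m <- ncol(X)
  if (n == 0 || m == 0) return(0)
  G <- hv_gradient(X)
  sum(abs(X - X_test) * G) / m
}

#' HV-derivative sample weights for one objective
#'
#' Weights used when training an overestimation adjuster: each solution of
#' a fold's front is weighted by the partial derivative of that front's
#' training hypervolume with respect to its fitness in objective `j`,
#' rescaled to sum to 1. If every derivative in the column is zero the
#' weights fall back to uniform.
#'
#' @param X One fold's train fitness matrix.
#' @param j Objective (column) index.
#' @return Numeric weight vector summing to 1 (length 0 for an empty set).
#' @export
assign_weights <- function(X, j) {
  X <- as_fitness_matrix(X, check_unit = TRUE)
  n <- nrow(X)
  if (n == 0) return(numeric(0))
  j <- as.integer(j)
  stopifnot(j >= 1, j <= ncol(X))
  g <- hv_gradient(X)[, j]
  s <- sum(g)
  if (s <= 0) rep(1 / n, n) else g / s
}
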