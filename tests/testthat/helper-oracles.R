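# Independent oracles used to check the package's analytic code paths.
# They are deliberately naive (inclusion-exclusion, O(n^2) enumeration,
# finite differences) and never call the functions they verify.

# hypervolume by inclusion-exclusion over all subsets (n <= ~12)
hv_ie <- function(X) {
  X <- rbind(X)
  n <- nrow(X)
  if (n == 0 || ncol(X) == 0) return(0)
  total <- 0
  for (mask in 1:(2^n - 1)) {
    rows <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    vol <- prod(apply(X[rows, , drop = FALSE], 2, min))
    total <- total + (-1)^(length(rows) + 1) * vol
  }
  total
}

# central finite differences of the inclusion-exclusion hypervolume
hv_fd_gradient <- function(X, h = 1e-6) {
  X <- rbind(X)
  G <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      up <- X; up[i, j] <- up[i, j] + h
      dn <- X; dn[i, j] <- dn[i, j] - h
      G[i, j] <- (hv_ie(up) - hv_ie(dn)) / (2 * h)
    }
  }
  G
}

# brute-force non-dominated filter with lowest-index duplicate collapse
front_brute <- function(X) {
  X <- rbind(X)
  n <- nrow(X)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      better_eq <- all(X[j, ] >= X[i, ])
      if (better_eq && any(X[j, ] > X[i, ])) dominated <- TRUE
      if (j < i && all(X[j, ] == X[i, ])) dominated <- TRUE
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# mean per-class recall by direct counting
ba_brute <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  classes <- unique(y_true)
  mean(vapply(classes, function(cl) {
    mean(as.character(y_pred)[y_true == cl] == cl)
  }, numeric(1)))
}

# c-index by direct pair enumeration
cindex_brute <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

# weighted-L1 minimizer by brute force over the sample values
wmedian_brute <- function(v, w) {
  loss <- vapply(v, function(c) sum(w * abs(v - c)), numeric(1))
  min(v[loss <= min(loss) + 1e-12])
}

# random front matrix with distinct coordinates in each column
random_front <- function(n, m, seed) {
  withr::with_seed(seed, {
    matrix(sample(seq(0.05, 0.95, by = 0.9 / (n * m * 2)), n * m), n, m)
  })
}
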