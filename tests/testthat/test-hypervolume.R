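test_that("hypervolume matches closed-form values", {
  expect_equal(hypervolume(c(0.5, 0.5)), 0.25, tolerance = 1e-12)
  expect_equal(hypervolume(rbind(c(0.2, 0.8), c(0.8, 0.2))), 0.28,
               tolerance = 1e-12)
  expect_equal(hypervolume(matrix(0, 0, 3)), 0)
  expect_equal(hypervolume(rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))), 0.125)
  expect_error(hypervolume(c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("hypervolume agrees with inclusion-exclusion on random sets", {
  for (case in 1:50) {
    n <- sample(1:8, 1)
    m <- sample(2:4, 1)
    X <- withr::with_seed(1000 + case, matrix(stats::runif(n * m), n, m))
    expect_equal(hypervolume(X), hv_ie(X), tolerance = 1e-10,
                 info = paste("case", case))
  }
})

test_that("hypervolume is monotone in every coordinate", {
  for (case in 1:30) {
    X <- random_front(5, 3, seed = case)
    v0 <- hypervolume(X)
    i <- sample(5, 1); j <- sample(3, 1)
    X2 <- X
    X2[i, j] <- min(1, X2[i, j] + 0.05)
    expect_gte(hypervolume(X2), v0 - 1e-12)
  }
})

test_that("hypervolume agrees with a Monte-Carlo volume estimate", {
  for (case in 1:3) {
    m <- 1 + case  # 2, 3, 4
    n <- 4
    X <- random_front(n, m, seed = 50 + case)
    v <- hypervolume(X)
    N <- 1e6
    U <- withr::with_seed(case, matrix(stats::runif(N * m), N, m))
    inside <- rep(FALSE, N)
    for (i in seq_len(n)) {
      ok <- rep(TRUE, N)
      for (j in seq_len(m)) ok <- ok & (U[, j] <= X[i, j])
      inside <- inside | ok
    }
    p_hat <- mean(inside)
    se <- sqrt(p_hat * (1 - p_hat) / N)
    expect_lt(abs(v - p_hat), 3 * se + 1e-9)
  }
})

test_that("hv_gradient matches central finite differences", {
  for (case in 1:100) {
    n <- sample(1:6, 1)
    m <- sample(2:3, 1)
    X <- random_front(n, m, seed = 2000 + case)
    expect_equal(hv_gradient(X), hv_fd_gradient(X), tolerance = 1e-6,
                 info = paste("case", case))
  }
})

test_that("hv_gradient handles the documented special cases", {
  expect_equal(hv_gradient(c(0.5, 0.5)), rbind(c(0.5, 0.5)))
  # frozen from the finite-difference oracle (mirror-symmetric front)
  G <- hv_gradient(rbind(c(0.2, 0.8), c(0.8, 0.2)))
  expect_equal(G, hv_fd_gradient(rbind(c(0.2, 0.8), c(0.8, 0.2))),
               tolerance = 1e-6)
  expect_equal(G, rbind(c(0.6, 0.2), c(0.2, 0.6)), tolerance = 1e-12)
  # strictly dominated point contributes nothing
  expect_equal(hv_gradient(rbind(c(0.9, 0.9), c(0.1, 0.1)))[2, ], c(0, 0))
  # duplicate rows: the first copy carries the whole derivative
  Gd <- hv_gradient(rbind(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(Gd[2, ], c(0, 0))
  expect_equal(Gd[1, ], c(0.5, 0.5))
  # one objective: indicator on the (first) maximum
  expect_equal(hv_gradient(matrix(c(0.3, 0.9, 0.9), 3, 1)),
               matrix(c(0, 1, 0), 3, 1))
})

test_that("cross-hypervolume and MOPE match worked examples", {
  expect_equal(cross_hypervolume(c(0.5, 0.5), c(0.4, 0.5)), 0.20,
               tolerance = 1e-12)
  expect_equal(mope(c(0.5, 0.5), c(0.4, 0.5)), 0.05, tolerance = 1e-12)
  # symmetric under- and over-shoot give the same error
  expect_equal(mope(c(0.6, 0.5), c(0.4, 0.5)), 0.10, tolerance = 1e-12)
  expect_equal(mope(c(0.6, 0.5), c(0.8, 0.5)), 0.10, tolerance = 1e-12)
  X <- random_front(4, 2, seed = 9)
  expect_equal(cross_hypervolume(X, X), hypervolume(X), tolerance = 1e-12)
  expect_equal(cross_hypervolume(X, matrix(0, 4, 2)), 0)
  expect_error(cross_hypervolume(X, matrix(0.5, 3, 2)), "same shape")
})

test_that("identity metrics vanish when train equals test", {
  v_sqrt <- cross_function(function(a, b) sqrt(pmax(a, 0) * pmax(b, 0)))
  for (case in 1:100) {
    n <- sample(1:6, 1)
    m <- sample(2:3, 1)
    X <- random_front(n, m, seed = 3000 + case)
    expect_identical(pareto_delta(X, X), 0)
    expect_identical(mope(X, X), 0)
    expect_equal(mope(X, X, v_sqrt), 0, tolerance = 1e-12)
  }
})

test_that("pareto delta matches the gradient-weighted sum", {
  expect_equal(pareto_delta(c(0.5, 0.5), c(0.4, 0.5)), 0.025,
               tolerance = 1e-12)
  # independent recomputation through the finite-difference oracle
  X <- random_front(4, 2, seed = 77)
  Xt <- pmax(X - 0.07, 0)
  G <- hv_fd_gradient(X)
  expect_equal(pareto_delta(X, Xt), sum(abs(X - Xt) * G) / ncol(X),
               tolerance = 1e-5)
})

test_that("pareto delta is exactly 0 for zero solutions or objectives", {
  expect_identical(pareto_delta(matrix(0, 0, 2), matrix(0, 0, 2)), 0)
  expect_identical(pareto_delta(matrix(0, 3, 0), matrix(0, 3, 0)), 0)
})

test_that("cross functions must fix the diagonal", {
  expect_error(cross_function(function(a, b) (a + b) / 2 + 0.1), "v\\(x, x\\)")
  v <- cross_default()
  expect_equal(v(0.3, 1.4), 1)
  expect_equal(v(0.3, -0.2), 0)
})

test_that("HV-derivative weights are a probability vector per objective", {
  for (case in 1:50) {
    n <- sample(1:8, 1)
    m <- sample(2:3, 1)
    X <- random_front(n, m, seed = 4000 + case)
    for (j in seq_len(m)) {
      w <- assign_weights(X, j)
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  }
  expect_equal(assign_weights(c(0.5, 0.5), 1), 1)
  # duplicate row: kept solution takes all the weight
  expect_equal(assign_weights(rbind(c(0.5, 0.5), c(0.5, 0.5)), 1), c(1, 0))
  # all-zero gradient column falls back to uniform
  expect_equal(assign_weights(rbind(c(0.4, 0), c(0.2, 0)), 1),
               c(0.5, 0.5))
  expect_length(assign_weights(matrix(0, 0, 2), 1), 0)
})
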