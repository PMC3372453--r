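test_that("trivial row subproblems have closed-form solutions", {
  set.seed(1)
  X1 <- matrix(runif(3 * 6), 3, 6)
  # zero response: a = 0 is feasible and uniquely optimal for gamma > 0
  a <- ncinet:::solve_row_subproblem(X1, rep(0, 6), gamma = 0.01)
  expect_equal(a, rep(0, 3), tolerance = 1e-8)
  # overwhelming penalty drives the row to zero
  y <- runif(6)
  a2 <- ncinet:::solve_row_subproblem(X1, y, gamma = 1e6 * max(abs(X1 %*% y)))
  expect_equal(a2, rep(0, 3), tolerance = 1e-8)
})

test_that("the row QP matches an exhaustive grid search on 2-gene instances", {
  set.seed(7)
  for (rep in 1:3) {
    X1 <- matrix(rnorm(2 * 3), 2, 3)
    y <- rnorm(3)
    w <- runif(2)
    gamma <- 0.05; mu <- 0.5
    cvec <- mu * w + gamma
    a <- ncinet:::solve_row_subproblem(X1, y, w, gamma = gamma, mu = mu)
    best_grid <- grid_search_row(X1, y, cvec)
    expect_lte(row_objective(a, X1, y, cvec), best_grid + 1e-2)
  }
})

test_that("every estimated row satisfies the stability budget", {
  net <- generate_network(10, list(1:4, 5:8), n_edges = 18, seed = 4)
  X <- simulate_expression(net, m = 30, seed = 5)
  for (g in c(0.001, 0.05)) {
    A <- infer_network(X, gamma = g)
    expect_true(all(rowSums(abs(A)) <= 1 + 1e-6))
  }
})

test_that("support size is nonincreasing in the sparsity penalty", {
  X <- simulate_expression(test1_network(), m = 50, seed = 3)
  nn <- vapply(c(0.001, 0.01, 0.1, 1),
               function(g) sum(abs(sgn_baseline(X, g)) > 1e-4), 0)
  expect_true(all(diff(nn) <= 0))
})

test_that("zero weights reduce the weighted program to the plain sparse baseline", {
  X <- simulate_expression(test1_network(), m = 40, seed = 8)
  n <- nrow(X)
  A_w0 <- infer_network(X, W = matrix(0, n, n), gamma = 0.02, mu = 0.2)
  A_sgn <- sgn_baseline(X, gamma = 0.02)
  expect_equal(A_w0, A_sgn, tolerance = 1e-7)

  # all-ones weights at multiplier mu act as a uniform penalty gamma + mu
  A_ones <- infer_network(X, W = matrix(1, n, n), gamma = 0.02, mu = 0.2)
  A_gpm <- sgn_baseline(X, gamma = 0.22)
  expect_equal(A_ones, A_gpm, tolerance = 1e-6)
})

test_that("noise-free data from a separated-mode network is recovered", {
  A <- separated_mode_network()
  X <- simulate_expression(A, m = 60, seed = 5)
  est <- sgn_baseline(X, gamma = 1e-4)
  expect_gt(sign_accuracy(est, A), 0.9)
})

test_that("row decomposition agrees with a generic joint solve", {
  set.seed(10)
  n <- 4; m <- 12
  net <- generate_network(n, list(), n_edges = 5, seed = 10)
  X <- simulate_expression(net, m = m, seed = 11)
  W <- matrix(runif(n * n), n)
  gamma <- 0.02; mu <- 0.2
  X1 <- X[, -m]; X2 <- X[, -1]
  cvec_rows <- mu * W + gamma

  A_rows <- infer_network(X, W = W, gamma = gamma, mu = mu)
  A_joint <- constr_optim_rows(X1, X2, cvec_rows)

  obj <- function(A) sum((A %*% X1 - X2)^2) + sum((mu * W + gamma) * abs(A))
  expect_lt(abs(obj(A_rows) - obj(A_joint)), 1e-4)
})

test_that("infer_network objective never exceeds the zero solution", {
  X <- simulate_expression(test1_network(), m = 50, seed = 12)
  m <- ncol(X)
  A <- infer_network(X, gamma = 0.02)
  X1 <- X[, -m]; X2 <- X[, -1]
  expect_lte(sum((A %*% X1 - X2)^2) + 0.02 * sum(abs(A)), sum(X2^2))
})

test_that("estimates combine by largest magnitude with ties to the first", {
  A1 <- matrix(c(0.3, 0, 0, 0.2), 2)
  A2 <- matrix(c(-0.5, 0.1, 0, -0.2), 2)
  comb <- combine_estimates(list(A1, A2))
  expect_equal(comb, matrix(c(-0.5, 0.1, 0, 0.2), 2))  # tie at (2,2) keeps A1

  expect_identical(combine_estimates(list(A1)), A1)

  # disjoint supports: union
  B1 <- diag(c(1, 0)); B2 <- matrix(c(0, 0, 2, 0), 2)
  expect_equal(combine_estimates(list(B1, B2)), matrix(c(1, 0, 2, 0), 2))

  expect_error(combine_estimates(list()), "empty")
  expect_error(combine_estimates(list(A1, diag(3))), "shape")
})

test_that("input validation names the offending row and rejects bad weights", {
  X <- simulate_expression(diag(c(0.5, 0.5)), m = 5, x0 = c(1, 1))
  expect_error(infer_network(X, W = matrix(-1, 2, 2), gamma = 0.1),
               "nonnegative")
  expect_error(infer_network(X, W = matrix(0, 3, 3), gamma = 0.1))
})

test_that("default penalty grids follow the benchmark settings", {
  expect_equal(default_gamma_grid(14),
               list(gamma = c(0.05, 0.02, 0.008), gamma_tau = 0.02))
  expect_equal(default_gamma_grid(50),
               list(gamma = c(0.02, 0.005, 0.001), gamma_tau = 0.005))
  g <- default_gamma_grid(200)
  expect_true(all(g$gamma > 0) && g$gamma_tau > 0)
})
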