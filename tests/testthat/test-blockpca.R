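test_that("soft-thresholding follows its definition", {
  expect_equal(soft_threshold(1.5, 1), 0.5)
  expect_equal(soft_threshold(-0.3, 1), 0)
  x <- matrix(rnorm(9, sd = 2), 3)
  expect_equal(soft_threshold(x, 0), x)           # identity at eps = 0
  expect_error(soft_threshold(x, -0.1), "nonnegative")
})

test_that("weighted soft-thresholding generalises the scalar operator", {
  set.seed(1)
  X <- matrix(rnorm(16), 4)
  expect_equal(weighted_soft_threshold(X, matrix(0, 4, 4)), X)
  eps <- 0.3
  expect_equal(weighted_soft_threshold(X, matrix(eps, 4, 4)),
               soft_threshold(X, eps))
  # mixed thresholds: per-entry hand computation
  X2 <- matrix(c(1, -0.5, 0.2, -2), 2)
  W2 <- matrix(c(0.5, 1, 0.3, 0.5), 2)
  expect_equal(weighted_soft_threshold(X2, W2),
               matrix(c(0.5, 0, 0, -1.5), 2))
  expect_error(weighted_soft_threshold(X2, -W2), "nonnegative")
})

test_that("singular value thresholding shrinks the spectrum", {
  expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)))
  X <- matrix(rnorm(25), 5)
  expect_equal(svt(X, 2 * max(svd(X)$d)), matrix(0, 5, 5))
  # nuclear norm of the output equals the shrunk singular values
  out <- svt(X, 0.5)
  expect_equal(sum(svd(out)$d), sum(pmax(svd(X)$d - 0.5, 0)), tolerance = 1e-10)
  expect_error(svt(X, 0), "positive")
})

test_that("svt is nonexpansive in Frobenius norm", {
  set.seed(2)
  for (rep in 1:5) {
    X <- matrix(rnorm(36), 6); Y <- matrix(rnorm(36), 6)
    d_out <- sqrt(sum((svt(X, 0.7) - svt(Y, 0.7))^2))
    expect_lte(d_out, sqrt(sum((X - Y)^2)) + 1e-12)
  }
})

test_that("the decomposition objective matches closed forms", {
  n <- 6
  Z <- matrix(0, n, n)
  expect_equal(block_pca_objective(Z, Z, Z, 0.1, 0.5), 0)
  D <- matrix(1, n, n)
  # all-ones is rank one with singular value n
  expect_equal(block_pca_objective(D, Z, Z, 0.1, 0.5), n)
})

test_that("the splitting solver honours its stopping contract", {
  W1 <- matrix(1, 4, 4)
  fit <- block_pca(W1, eps1 = Inf, eps2 = Inf, max_iter = 100L)
  expect_identical(fit$report$iterations, 1L)
  expect_true(fit$report$converged)

  fit2 <- block_pca(W1, max_iter = 3L)
  expect_identical(fit2$report$iterations, 3L)
  expect_false(fit2$report$converged)

  # feasibility at reported convergence (primal residual criterion)
  set.seed(3)
  W1r <- cloud_weights(6)
  fit3 <- block_pca(W1r)
  expect_true(fit3$report$converged)
  D <- matrix(1, 6, 6)
  prim <- sqrt(sum((D - fit3$L - fit3$E)^2) + sum((fit3$L - fit3$U)^2)) /
    sqrt(sum(D^2))
  expect_lte(prim, 1e-6)
})

test_that("parameter validation matches the model's requirements", {
  W1 <- matrix(1, 3, 3)
  expect_error(block_pca(W1, lambda2 = 0.5, lambda1 = 0.6), "lambda")
  expect_error(block_pca(W1, beta = 0), "beta")
  expect_error(block_pca(W1, mu_split = 2), "mu_split")
  expect_error(block_pca(-W1), "nonnegative")
})

test_that("with zero weights the model reduces to robust PCA", {
  # low-rank plus sparse D; the weighted term is absent so both the
  # splitting solver and the independent reference solve plain robust PCA
  set.seed(4)
  n <- 8
  D <- tcrossprod(rnorm(n), rnorm(n))
  D[sample(n * n, 6)] <- 3
  W0 <- matrix(0, n, n)
  lam <- 1 / sqrt(n)
  # lambda1 multiplies an identically-zero term; any valid value works
  fit <- block_pca(W0, D = D, lambda2 = lam, lambda1 = 0.5 * lam,
                   eps1 = 1e-8, eps2 = 1e-8, max_iter = 20000L)
  ref <- block_pca_ref(W0, D = D, lambda2 = lam, lambda1 = 0.5 * lam)
  expect_lt(abs(fit$report$objective - ref$objective) / ref$objective, 1e-3)
})

test_that("block-structured weights confine the low-rank support to the blocks", {
  W1 <- matrix(10, 5, 5)
  W1[1:3, 1:3] <- 0
  W1[4:5, 4:5] <- 0
  # lambda2 large enough that blocks of size >= 2 pay for their nuclear cost
  fit <- block_pca(W1, lambda2 = 0.6, lambda1 = 0.12)
  inblock <- matrix(FALSE, 5, 5)
  inblock[1:3, 1:3] <- TRUE; inblock[4:5, 4:5] <- TRUE
  expect_true(all(abs(fit$L[!inblock]) < 1e-6))
  expect_true(all(abs(fit$L[inblock]) > 0.5))
})

test_that("symmetric problems keep every iterate symmetric", {
  set.seed(5)
  W1 <- cloud_weights(7)          # symmetric by construction
  fit <- block_pca(W1)
  expect_equal(fit$L, t(fit$L), tolerance = 1e-10)
  expect_equal(fit$E, t(fit$E), tolerance = 1e-10)
  expect_equal(fit$U, t(fit$U), tolerance = 1e-10)
})

test_that("the splitting and reference solvers agree on random weighted problems", {
  set.seed(6)
  for (n in c(5, 8)) {
    W1 <- cloud_weights(n)
    fit <- block_pca(W1, eps1 = 1e-8, eps2 = 1e-8, max_iter = 20000L)
    ref <- block_pca_ref(W1)
    expect_lt(abs(fit$report$objective - ref$objective) / ref$objective, 1e-3)
  }
})
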