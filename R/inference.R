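#' Solve one per-gene network-inference subproblem
#'
#' Minimises
#' \deqn{\|X_1^T a - x_2\|_2^2 + \langle \mu w + \gamma,\, |a| \rangle
#'       \quad \text{s.t.} \quad \|a\|_1 \le 1,}
#' the convex program for a single row of the transition matrix: a
#' least-squares fit of one gene's next-step expression on all current
#' expression levels, with an elementwise-weighted L1 penalty and the
#' row-stability budget.  Solved as a QP via the positive/negative-part lift
#' `a = u - v` (accelerated projected gradient, compiled).
#'
#' @param X1 `n x (m-1)` design matrix (expression at time points `1..m-1`).
#' @param x2_row Length-`(m-1)` response (one gene's expression at `2..m`).
#' @param w_row Nonnegative weight vector of length `n` (community penalty).
#' @param gamma Sparsity penalty, positive.
#' @param mu Weight-penalty multiplier, nonnegative.
#' @param tol Fixed-point (KKT) tolerance of the solver.
#' @param max_iter Iteration cap.
#' @return Numeric vector `a` of length `n` with `sum(abs(a)) <= 1 + tol`.
#' @keywords internal
solve_row_subproblem <- function(X1, x2_row, w_row = NULL, gamma, mu = 0,
                                 tol = 1e-9, max_iter = 20000L) {
  n <- nrow(X1)
  if (is.null(w_row)) w_row <- numeric(n)
  stopifnot(length(x2_row) == ncol(X1), length(w_row) == n,
            gamma > 0, mu >= 0, all(w_row >= 0))
  Q <- X1 %*% t(X1)
  b <- drop(X1 %*% x2_row)
  cvec <- mu * w_row + gamma
  # curvature of the lifted objective: H = [[2Q,-2Q],[-2Q,2Q]], |H| = 4|Q|
  lip <- 4 * max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values, 0)
  lip <- max(lip, 1e-12)
  fit <- .row_qp_cpp(Q, b, cvec, lip, tol, as.integer(max_iter))
  if (!fit$converged && fit$residual > sqrt(tol))
    stop("row subproblem did not converge (residual ",
         format(fit$residual), " after ", fit$iterations, " iterations)")
  drop(fit$a)
}

#' Infer a sparse stable network from time-course expression
#'
#' Estimates the discrete transition matrix `A` of the linear dynamics
#' \eqn{x_{k+1} = A x_k} from an expression matrix by solving, for each gene
#' `i`, the weighted sparse regression
#' \eqn{\min \|X_1^T a_i - X_{2,i}\|^2 + \gamma\|a_i\|_1 + \mu \langle w_i, |a_i| \rangle}
#' subject to the stability budget \eqn{\|a_i\|_1 \le 1}.  The joint problem
#' separates exactly into these `n` convex QPs because rows of `A` are
#' independent in both the objective and the constraints.
#'
#' @param X `n x m` expression matrix (genes by time points, `m >= 2`).
#' @param W Optional `n x n` nonnegative community weight matrix; `NULL`
#'   means no community penalty (the plain sparse baseline).
#' @param gamma Sparsity penalty, positive.
#' @param mu Community-weight multiplier; conventionally `10 * gamma`.
#' @param tol,max_iter Passed to the row solver.
#' @return The estimated `n x n` transition matrix with the dimnames of `X`.
#' @seealso [sgn_baseline()], [nci()]
#' @export
infer_network <- function(X, W = NULL, gamma, mu = 10 * gamma,
                          tol = 1e-9, max_iter = 20000L) {
  stopifnot(is.matrix(X), ncol(X) >= 2)
  n <- nrow(X)
  m <- ncol(X)
  if (!is.null(W)) {
    stopifnot(is.matrix(W), all(dim(W) == n))
    if (any(W < 0)) stop("W must be nonnegative")
  }
  X1 <- X[, -m, drop = FALSE]
  X2 <- X[, -1, drop = FALSE]
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    a <- tryCatch(
      solve_row_subproblem(X1, X2[i, ], if (is.null(W)) NULL else W[i, ],
                           gamma = gamma, mu = mu, tol = tol,
                           max_iter = max_iter),
      error = function(e) stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
    A[i, ] <- a
  }
  dimnames(A) <- list(rownames(X), rownames(X))
  A
}

#' Sparse stable network baseline (no community weights)
#'
#' The plain L1-penalised, stability-constrained least-squares estimate:
#' [infer_network()] with all community weights zero.  Used as the comparison
#' arm in benchmarks.
#'
#' @inheritParams infer_network
#' @export
sgn_baseline <- function(X, gamma, tol = 1e-9, max_iter = 20000L) {
  infer_network(X, W = NULL, gamma = gamma, mu = 0,
                tol = tol, max_iter = max_iter)
}

#' Combine several network estimates elementwise
#'
#' Merges estimates obtained at different sparsity levels by keeping, for
#' every matrix position, the entry of largest magnitude (sign preserved);
#' ties go to the earliest estimate in the list.  Averaging out errors over a
#' set of penalties gives a more reliable support for the community step.
#'
#' @param estimates Non-empty list of matrices of identical shape.
#' @return A single combined matrix.
#' @export
combine_estimates <- function(estimates) {
  if (!length(estimates)) stop("empty list of estimates")
  dims <- dim(estimates[[1]])
  A <- estimates[[1]]
  for (B in estimates[-1]) {
    if (!all(dim(B) == dims)) stop("estimates must share one shape")
    take <- abs(B) > abs(A)   # strict: ties keep the earlier estimate
    A[take] <- B[take]
  }
  A
}

#' Default sparsity-penalty grids
#'
#' Penalty grids used by [nci()] when none are supplied: the benchmark grids
#' `{0.05, 0.02, 0.008}` (final pass 0.02) for small networks and
#' `{0.02, 0.005, 0.001}` (final pass 0.005) for networks of around 50
#' genes; otherwise a geometric grid around `1/n`.
#'
#' @param n Number of genes.
#' @return List with elements `gamma` (vector) and `gamma_tau` (scalar).
#' @export
default_gamma_grid <- function(n) {
  if (n <= 20)
    list(gamma = c(0.05, 0.02, 0.008), gamma_tau = 0.02)
  else if (n <= 60)
    list(gamma = c(0.02, 0.005, 0.001), gamma_tau = 0.005)
  else
    list(gamma = (1 / n) * c(2.5, 1, 0.4), gamma_tau = 1 / n)
}
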