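#' Scalar/matrix soft-thresholding
#'
#' Shrink-toward-zero operator \eqn{S_\epsilon[t]}: `t - eps` for `t > eps`,
#' `t + eps` for `t < -eps`, zero otherwise; applied elementwise to matrices.
#'
#' @param t Numeric scalar, vector or matrix.
#' @param eps Threshold, nonnegative.
#' @export
soft_threshold <- function(t, eps) {
  if (any(eps < 0)) stop("eps must be nonnegative")
  sign(t) * pmax(abs(t) - eps, 0)
}

#' Elementwise-weighted soft-thresholding
#'
#' Applies `soft_threshold` with a separate threshold per entry:
#' \eqn{(S_W[X])_{ij} = S_{w_{ij}}[x_{ij}]}.  With a constant weight matrix
#' `W = eps * 1` this reduces to `soft_threshold(X, eps)`; with `W = 0` it is
#' the identity.
#'
#' @param X Numeric matrix.
#' @param W Nonnegative matrix of the same shape.
#' @export
weighted_soft_threshold <- function(X, W) {
  stopifnot(all(dim(X) == dim(W)))
  if (any(W < 0)) stop("W must be nonnegative")
  sign(X) * pmax(abs(X) - W, 0)
}

#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm: soft-threshold the singular
#' values, \eqn{D_\tau(X) = U S_\tau(\Sigma) V^T}.
#'
#' @param X Numeric matrix.
#' @param tau Threshold, positive.
#' @export
svt <- function(X, tau) {
  if (tau <= 0) stop("tau must be positive")
  s <- svd(X)
  d <- pmax(s$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(array(0, dim(X)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

#' Objective of the weighted low-rank + sparse decomposition
#'
#' \eqn{\|L\|_* + \lambda_1 \langle W_1, |L| \rangle + \lambda_2 \|E\|_1}.
#'
#' @param L,E Decomposition factors.
#' @param W1 Nonnegative weight matrix on `|L|`.
#' @param lambda1,lambda2 Penalty parameters, `0 < lambda1 < lambda2`.
#' @export
block_pca_objective <- function(L, E, W1, lambda1, lambda2) {
  sum(svd(L)$d) + lambda1 * sum(W1 * abs(L)) + lambda2 * sum(abs(E))
}

#' Block PCA: weighted robust-PCA decomposition by operator splitting
#'
#' Splits a matrix `D` (by default the all-ones matrix) into a low-rank
#' community indicator `L` and a sparse remainder `E`,
#' \deqn{\min_{L,E}\ \|L\|_* + \lambda_1 \langle W_1, |L| \rangle +
#'       \lambda_2 \|E\|_1 \quad \text{s.t.}\quad D = L + E,}
#' where the nonnegative weight matrix `W1` encodes pairwise distance priors
#' (large weights discourage entries of `L` linking distant genes).  Solved
#' by a three-operator splitting method with an auxiliary copy `U` of `L` and
#' two multiplier blocks: per sweep, `L` is updated by singular value
#' thresholding at `1/(2 beta)` of
#' `Y = (D - E + U)/2 + (Lambda1 + Lambda2)/(2 beta)`, the multipliers take a
#' half-step, `U` and `E` are updated by (weighted) soft-thresholding, and
#' the multipliers take the full step.  Initialisation is `L = U = D`,
#' `E = 0`, zero multipliers.
#'
#' The sweep terminates when both the relative primal residual
#' \eqn{(\|D-L-E\|_F^2 + \|L-U\|_F^2)^{1/2} / \|D\|_F \le \epsilon_1} and the
#' step length \eqn{(\|\Delta L\|_F^2 + \|\Delta E\|_F^2 +
#' \|\Delta U\|_F^2)^{1/2} \le \epsilon_2} hold, or at `max_iter` (reported,
#' not an error).
#'
#' @param W1 Nonnegative `n x n` weight matrix.
#' @param D Matrix to decompose; defaults to the all-ones matrix.
#' @param lambda2 Sparsity penalty on `E`; default `1/sqrt(n)`, the standard
#'   robust-PCA scaling.  (Any `lambda2 <= 1/n` makes the problem degenerate:
#'   `||L||_* >= ||L||_F >= ||L||_1 / n` forces the trivial solution `L = 0`
#'   whatever the weights.)
#' @param lambda1 Weighted penalty on `L`, in `(0, lambda2)`;
#'   default `0.2 * lambda2`.
#' @param beta Penalty parameter of the splitting scheme, positive.
#' @param mu_split Over-relaxation parameter, must exceed 2.
#' @param eps1,eps2 Stopping tolerances (primal residual, step length).
#' @param max_iter Iteration cap.
#' @return Object of class `"block_pca"`: list with `L`, `E`, `U`, and
#'   `report` (objective, primal_residual, step_residual, iterations,
#'   converged).
#' @examples
#' W1 <- matrix(5, 5, 5); W1[1:3, 1:3] <- 0; W1[4:5, 4:5] <- 0
#' fit <- block_pca(W1)
#' round(fit$L, 2)  # support confined to the two diagonal blocks
#' @export
block_pca <- function(W1, D = matrix(1, nrow(W1), ncol(W1)),
                      lambda2 = 1 / sqrt(nrow(W1)), lambda1 = 0.2 * lambda2,
                      beta = 0.25, mu_split = 2.5,
                      eps1 = 1e-6, eps2 = 1e-6, max_iter = 5000L) {
  stopifnot(is.matrix(W1), nrow(W1) == ncol(W1), all(dim(D) == dim(W1)))
  if (any(W1 < 0)) stop("W1 must be nonnegative")
  if (!(lambda1 > 0 && lambda1 < lambda2)) stop("need 0 < lambda1 < lambda2")
  if (beta <= 0) stop("beta must be positive")
  if (mu_split <= 2) stop("mu_split must exceed 2")

  L <- D
  E <- array(0, dim(D))
  U <- D
  Lam1 <- array(0, dim(D))
  Lam2 <- array(0, dim(D))
  normD <- sqrt(sum(D^2))
  bm <- beta * mu_split
  converged <- FALSE
  prim <- step <- Inf
  k <- 0L

  while (k < max_iter) {
    k <- k + 1L
    Y <- (D - E + U) / 2 + (Lam1 + Lam2) / (2 * beta)
    L_new <- svt(Y, 1 / (2 * beta))
    # half-step multiplier update
    Lam1h <- Lam1 - beta * (L_new + E - D)
    Lam2h <- Lam2 - beta * (L_new - U)
    U_new <- weighted_soft_threshold(U - Lam2h / bm, (lambda1 / bm) * W1)
    E_new <- soft_threshold(E + Lam1h / bm, lambda2 / bm)
    Lam1 <- Lam1 - beta * (L_new + E_new - D)
    Lam2 <- Lam2 - beta * (L_new - U_new)

    prim <- sqrt(sum((D - L_new - E_new)^2) + sum((L_new - U_new)^2)) / normD
    step <- sqrt(sum((L_new - L)^2) + sum((E_new - E)^2) + sum((U_new - U)^2))
    L <- L_new; E <- E_new; U <- U_new
    if (prim <= eps1 && step <= eps2) { converged <- TRUE; break }
  }

  report <- list(objective = block_pca_objective(L, E, W1, lambda1, lambda2),
                 primal_residual = prim, step_residual = step,
                 iterations = k, converged = converged)
  structure(list(L = L, E = E, U = U, report = report,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "block_pca")
}

#' @export
print.block_pca <- function(x, ...) {
  r <- x$report
  cat("Block PCA decomposition (", nrow(x$L), " x ", ncol(x$L), ")\n", sep = "")
  cat("  objective       ", format(r$objective, digits = 7), "\n")
  cat("  primal residual ", format(r$primal_residual, digits = 3), "\n")
  cat("  iterations      ", r$iterations,
      if (r$converged) "(converged)" else "(iteration cap reached)", "\n")
  invisible(x)
}

#' Reference solver for the Block PCA problem
#'
#' Independent solver used to cross-check [block_pca()]: eliminates `E`
#' through the constraint (`E = D - L`) and solves
#' \eqn{\min_L \|L\|_* + \lambda_1\langle W_1,|L|\rangle + \lambda_2\|D-L\|_1}
#' by a two-block ADMM (consensus split `L = Z`) whose `Z`-update is an exact
#' elementwise proximal map of the piecewise-linear penalty
#' \eqn{a|x| + b|d - x|}.  The derivation and iteration are unrelated to the
#' three-operator splitting scheme, so agreement of the two objectives is a
#' genuine two-route check.  Intended for small instances (`n <= 30`).
#'
#' @inheritParams block_pca
#' @param rho ADMM penalty parameter.
#' @param max_iter,tol Iteration cap and step tolerance.
#' @return List with `L`, `E = D - L` and `objective`.
#' @export
block_pca_ref <- function(W1, D = matrix(1, nrow(W1), ncol(W1)),
                          lambda2 = 1 / sqrt(nrow(W1)), lambda1 = 0.2 * lambda2,
                          rho = 0.5, max_iter = 20000L, tol = 1e-10) {
  stopifnot(nrow(W1) <= 50)
  a <- lambda1 * W1          # weight on |x|
  b <- lambda2               # weight on |d - x|
  Z <- D
  Uc <- array(0, dim(D))
  best_obj <- Inf
  best_L <- D
  for (k in seq_len(max_iter)) {
    Ls <- svt_or_zero(Z - Uc, 1 / rho)
    V <- Ls + Uc
    Z_new <- prox_abs_pair(V, a, b, D, rho)
    Uc <- Uc + Ls - Z_new
    step <- sqrt(sum((Z_new - Z)^2))
    Z <- Z_new
    if (k %% 100 == 0 || step <= tol) {
      obj <- block_pca_objective(Z, D - Z, W1, lambda1, lambda2)
      if (obj < best_obj) { best_obj <- obj; best_L <- Z }
      if (step <= tol) break
    }
  }
  obj <- block_pca_objective(Z, D - Z, W1, lambda1, lambda2)
  if (obj < best_obj) { best_obj <- obj; best_L <- Z }
  list(L = best_L, E = D - best_L, objective = best_obj)
}

# svt() requires tau > 0; allow tau = 0 for the reference solver's prox.
svt_or_zero <- function(X, tau) if (tau > 0) svt(X, tau) else X

# Elementwise prox of  a|x| + b|d - x|  at point v with parameter rho:
# argmin_x rho/2 (x - v)^2 + a|x| + b|d - x|.  a, b >= 0 elementwise.
prox_abs_pair <- function(V, a, b, D, rho) {
  lo <- pmin(0, D)
  hi <- pmax(0, D)
  # interior candidates in the three linear regions of the penalty
  c_low  <- V + (a + b) / rho                    # x < lo
  s_mid  <- (a - b) * sign(D)                    # slope on (lo, hi)
  c_mid  <- V - s_mid / rho
  c_high <- V - (a + b) / rho                    # x > hi
  obj <- function(X) rho / 2 * (X - V)^2 + a * abs(X) + b * abs(D - X)
  # fall back to the kinks 0 and d when no interior candidate is valid
  Z0 <- array(0, dim(V))
  X <- ifelse(obj(Z0) <= obj(D), Z0, D)          # best of the two kinks
  X <- ifelse(c_low < lo, c_low, X)
  X <- ifelse(c_mid > lo & c_mid < hi, c_mid, X)
  X <- ifelse(c_high > hi, c_high, X)
  X
}
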