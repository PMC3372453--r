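# Independent oracles used across the suite.

# Matrix exponential by plain Taylor series (oracle for the zero-order hold).
expm_series <- function(M, terms = 80L) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(terms)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

# Exhaustive grid search over the L1 ball for the 2-gene row subproblem.
grid_search_row <- function(X1, y, cvec, res = 1e-3) {
  best <- Inf
  a1s <- seq(-1, 1, by = res)
  for (a1 in a1s) {
    r <- 1 - abs(a1)
    a2s <- seq(-r, r, by = res)
    # vectorised over a2: residual matrix is (m-1) x length(a2s)
    resid <- outer(X1[1, ] * a1, rep(1, length(a2s))) +
      outer(X1[2, ], a2s) - y
    obj <- colSums(resid^2) + cvec[1] * abs(a1) + cvec[2] * abs(a2s)
    best <- min(best, min(obj))
  }
  best
}

# Row-subproblem objective (for comparing solvers).
row_objective <- function(a, X1, y, cvec) {
  sum((drop(t(X1) %*% a) - y)^2) + sum(cvec * abs(a))
}

# Generic constrained solver for the positive/negative-part lift of the
# (possibly multi-row) weighted sparse regression; independent of the
# package's projected-gradient path.
constr_optim_rows <- function(X1, X2, cvec_rows) {
  n <- nrow(X1)
  a_rows <- matrix(0, nrow(X2), n)
  for (i in seq_len(nrow(X2))) {
    y <- X2[i, ]; cvec <- cvec_rows[i, ]
    fobj <- function(z) {
      a <- z[1:n] - z[(n + 1):(2 * n)]
      sum((drop(t(X1) %*% a) - y)^2) + sum(cvec * (z[1:n] + z[(n + 1):(2 * n)]))
    }
    fgrad <- function(z) {
      a <- z[1:n] - z[(n + 1):(2 * n)]
      g <- drop(2 * X1 %*% (drop(t(X1) %*% a) - y))
      c(g + cvec, -g + cvec)
    }
    ui <- rbind(diag(2 * n), -rep(1, 2 * n))
    # constraints shifted by a hair so the log barrier stays finite when an
    # outer iterate lands exactly on the boundary
    ci <- c(rep(-1e-10, 2 * n), -1 - 1e-10)
    z0 <- rep(1 / (8 * n), 2 * n)
    co <- stats::constrOptim(z0, fobj, fgrad, ui = ui, ci = ci,
                             method = "BFGS",
                             control = list(maxit = 3000, reltol = 1e-12))
    a_rows[i, ] <- co$par[1:n] - co$par[(n + 1):(2 * n)]
  }
  a_rows
}

# A stable sparse transition matrix with well-separated decay modes (single
# decaying trajectories only identify such systems).
separated_mode_network <- function() {
  A <- diag(c(0.9, 0.6, 0.35, 0.75))
  A[1, 3] <- 0.3; A[2, 1] <- -0.3; A[4, 2] <- 0.25
  ncinet:::rescale_offdiag(A, 0.95)
}

# The worked 5-node low-rank community indicator (two blocks).
five_node_Lstar <- function() {
  L <- matrix(0, 5, 5)
  L[1:3, 1:3] <- 1
  L[4:5, 4:5] <- 1
  L
}

# Random planar point cloud and its distance-based penalty weights.
cloud_weights <- function(n, p0 = 0.5) {
  pts <- cbind(stats::runif(n), stats::runif(n))
  distance_weights(pts, p0 = p0)
}
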