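#' Fit a gene regulatory network with simultaneous community detection
#'
#' The NCI estimator alternates two convex steps until the community weight
#' matrix stabilises:
#'
#' * **N-step** (network): for every penalty in `gamma`, estimate a sparse,
#'   row-stable transition matrix by [infer_network()] with the current
#'   community weights `W` (multiplier `mu = mu_ratio * gamma`), then combine
#'   the estimates elementwise by largest magnitude ([combine_estimates()]).
#' * **C-step** (community): build shortest-path penalty weights from the
#'   combined support ([shortest_path_weights()]), decompose the all-ones
#'   matrix by [block_pca()] (`lambda2 = 1/sqrt(n)`,
#'   `lambda1 = lambda1_fraction * lambda2`), and refresh `W` from the
#'   low-rank factor ([update_weight_matrix()]).
#'
#' The loop starts from `W = 0`, stops when the Frobenius change of `W` falls
#' below `w_tol` or after `max_outer` iterations, re-solves the network once
#' more at `gamma_tau` with the final weights, and reads communities off the
#' final low-rank factor by sparse SVD ([ssvd_communities()]).
#'
#' @param X `n x m` expression matrix, genes as rows, `m >= 2` time points.
#' @param gamma Vector of sparsity penalties for the N-step; default from
#'   [default_gamma_grid()].
#' @param gamma_tau Penalty of the final network pass; default from
#'   [default_gamma_grid()].
#' @param mu_ratio Community-weight multiplier as a ratio `mu / gamma`
#'   (default 10; 0 disables the community penalty entirely).
#' @param lambda1_fraction `lambda1 / lambda2` for the community
#'   decomposition, in `(0, 1)`.
#' @param p0_fraction Shortest-path scale as a fraction of the estimated
#'   support's diameter.
#' @param p0 Optional fixed shortest-path scale, overriding `p0_fraction`
#'   (useful when the network's diameter is known a priori, e.g. for a
#'   benchmark network with known topology).
#' @param max_outer Maximum number of outer (N-step/C-step) iterations.
#' @param w_tol Convergence tolerance for the Frobenius change of `W`;
#'   default `1e-3 * n`.
#' @param sign_threshold Magnitude below which an entry counts as no
#'   interaction (used for the support and for [coef.nci()]).
#' @param sparsity_level,max_rank Passed to [ssvd_communities()].
#' @param qp_tol QP solver tolerance for the row subproblems.
#' @param block_pca_control Optional named list of [block_pca()] arguments
#'   (`beta`, `mu_split`, `eps1`, `eps2`, `max_iter`).
#' @return Object of class `"nci"` with components `A` (final transition
#'   matrix), `communities` (`"nci_communities"`), `W` (final weights), `L`
#'   (final low-rank factor, `NULL` if the C-step never ran), `trace`
#'   (per-iteration records), plus the inputs and settings.  Supports
#'   `print`, `summary`, `coef`, `predict`, `simulate`, `fitted`,
#'   `residuals` and `plot`.
#' @examples
#' net <- test1_network()
#' X <- simulate_expression(net, m = 50, seed = 7)
#' fit <- nci(X)
#' fit
#' sign_accuracy(coef(fit), net$A)
#' @export
nci <- function(X, gamma = NULL, gamma_tau = NULL, mu_ratio = 10,
                lambda1_fraction = 0.2, p0_fraction = 0.25, p0 = NULL,
                max_outer = 3L, w_tol = NULL, sign_threshold = 1e-4,
                sparsity_level = 0.5, max_rank = 10L, qp_tol = 1e-9,
                block_pca_control = list()) {
  stopifnot(is.matrix(X), ncol(X) >= 2)
  n <- nrow(X)
  grid <- default_gamma_grid(n)
  if (is.null(gamma)) gamma <- grid$gamma
  if (is.null(gamma_tau)) gamma_tau <- grid$gamma_tau
  if (is.null(w_tol)) w_tol <- 1e-3 * n
  if (!(lambda1_fraction > 0 && lambda1_fraction < 1))
    stop("lambda1_fraction must lie in (0, 1)")
  if (max_outer < 1) stop("max_outer must be at least 1")
  lambda2 <- 1 / sqrt(n)      # robust-PCA scaling; 1/n is provably degenerate
  lambda1 <- lambda1_fraction * lambda2

  W <- matrix(0, n, n)
  L <- NULL
  trace <- list()
  for (k in seq_len(max_outer)) {
    estimates <- lapply(gamma, function(g)
      infer_network(X, W = W, gamma = g, mu = mu_ratio * g, tol = qp_tol))
    A_comb <- combine_estimates(estimates)
    support <- abs(A_comb) > sign_threshold
    diag(support) <- FALSE

    if (!any(support)) {
      warning("iteration ", k, ": empty inferred support; keeping previous weights")
      trace[[k]] <- list(w_change = 0, block_pca = NULL, gamma = gamma,
                         support_size = 0L)
      break
    }
    spw <- shortest_path_weights(support, p0_fraction = p0_fraction, p0 = p0)
    bp <- do.call(block_pca,
                  c(list(W1 = spw$W1, lambda2 = lambda2, lambda1 = lambda1),
                    block_pca_control))
    L <- bp$L
    W_new <- update_weight_matrix(L)
    w_change <- sqrt(sum((W_new - W)^2))
    trace[[k]] <- list(w_change = w_change, block_pca = bp$report,
                       gamma = gamma, support_size = sum(support),
                       diameter = spw$diameter, p0 = spw$p0)
    W <- W_new
    if (w_change <= w_tol) break
  }

  A <- infer_network(X, W = W, gamma = gamma_tau, mu = mu_ratio * gamma_tau,
                     tol = qp_tol)
  communities <- if (is.null(L)) {
    structure(list(groups = list(), outliers = seq_len(n),
                   membership = rep(NA_integer_, n)),
              class = "nci_communities")
  } else {
    ssvd_communities(L, max_rank = max_rank, sparsity_level = sparsity_level)
  }

  structure(list(A = A, communities = communities, W = W, L = L,
                 trace = trace, X = X, gamma = gamma, gamma_tau = gamma_tau,
                 mu_ratio = mu_ratio, lambda1 = lambda1, lambda2 = lambda2,
                 sign_threshold = sign_threshold, call = match.call()),
            class = "nci")
}

#' Trichotomous sign accuracy of a network estimate
#'
#' Fraction of matrix positions whose trichotomised sign (promotion / no
#' interaction / repression, after thresholding small magnitudes to zero)
#' agrees between an estimate and the ground truth:
#' \eqn{(r_{11} + r_{22} + r_{33}) / n^2}, counting matched positives,
#' matched zeros and matched negatives.
#'
#' @param A_est,A_true Matrices of identical shape.
#' @param sign_threshold Magnitudes at or below this count as zero.
#' @return Accuracy in `[0, 1]`.
#' @export
sign_accuracy <- function(A_est, A_true, sign_threshold = 1e-4) {
  if (!all(dim(A_est) == dim(A_true))) stop("shape mismatch")
  tri <- function(M) sign(M) * (abs(M) > sign_threshold)
  mean(tri(A_est) == tri(A_true))
}

#' Paired benchmark of network-inference methods on a known network
#'
#' Runs a paired simulation experiment: for each run, a
#' fresh random initial state (and fresh noise, if configured) generates an
#' expression matrix from the known network, every requested method is fitted
#' to the *same* matrix, and its estimate is scored by [sign_accuracy()]
#' against the generating network.  Pairing the methods run-by-run makes the
#' comparison a paired one.
#'
#' @param network `"grn"` object or transition matrix (the ground truth).
#' @param n_runs Number of replicate runs.
#' @param methods Any of `"nci"` (multi-penalty), `"sgn"` (plain sparse
#'   baseline at `gamma_tau`), `"nci_single"` (NCI with the single penalty
#'   `gamma_tau` at the N-step).
#' @param m Number of simulated time points per run.
#' @param noise_fraction,sigma Passed to [add_noise()]; 0 disables noise.
#' @param seed RNG seed for the whole benchmark (per-run seeds derive from it).
#' @param ... Further arguments passed to [nci()].
#' @return Data frame of class `"nci_benchmark"` with columns `run`,
#'   `method`, `accuracy`; `summary()` gives per-method means.
#' @export
run_benchmark <- function(network, n_runs = 30L,
                          methods = c("nci", "sgn", "nci_single"),
                          m = 50L, noise_fraction = 0, sigma = 1,
                          seed = NULL, ...) {
  A_true <- if (inherits(network, "grn")) network$A else network
  n <- nrow(A_true)
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- default_gamma_grid(n)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)

  res <- vector("list", n_runs * length(methods))
  r <- 0L
  for (run in seq_len(n_runs)) {
    set.seed(run_seeds[run])
    X <- simulate_expression(A_true, m = m)
    if (noise_fraction > 0) X <- add_noise(X, noise_fraction, sigma)
    for (method in methods) {
      est <- switch(method,
        nci = coef(nci(X, ...)),
        sgn = sgn_baseline(X, gamma = grid$gamma_tau),
        nci_single = coef(nci(X, gamma = grid$gamma_tau, ...)))
      r <- r + 1L
      res[[r]] <- data.frame(run = run, method = method,
                             accuracy = sign_accuracy(est, A_true))
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("nci_benchmark", "data.frame")
  out
}

#' @export
summary.nci_benchmark <- function(object, ...) {
  means <- tapply(object$accuracy, object$method, mean)
  structure(list(means = means, n_runs = max(object$run)),
            class = "summary.nci_benchmark")
}

#' @export
print.summary.nci_benchmark <- function(x, ...) {
  cat("Paired benchmark over", x$n_runs, "runs; mean sign accuracy:\n")
  for (m in names(x$means))
    cat(sprintf("  %-11s %.1f%%\n", m, 100 * x$means[[m]]))
  invisible(x)
}

# ---- methods for the fitted object ----------------------------------------

#' @export
print.nci <- function(x, ...) {
  n <- nrow(x$A)
  cat("NCI network fit: ", n, " genes, ", ncol(x$X), " time points\n", sep = "")
  cat("  interactions (|a| > ", format(x$sign_threshold), "): ",
      sum(abs(x$A) > x$sign_threshold & row(x$A) != col(x$A)), "\n", sep = "")
  cat("  outer iterations: ", length(x$trace),
      ", final |dW|_F = ",
      format(if (length(x$trace)) x$trace[[length(x$trace)]]$w_change else NA,
             digits = 3), "\n", sep = "")
  cat("  communities: ", length(x$communities$groups),
      " (", length(x$communities$outliers), " outliers)\n", sep = "")
  invisible(x)
}

#' @export
summary.nci <- function(object, ...) {
  A <- coef(object)
  off <- row(A) != col(A)
  out <- list(
    n = nrow(A), m = ncol(object$X),
    n_interactions = sum(A[off] != 0),
    n_promotions = sum(A[off] > 0), n_repressions = sum(A[off] < 0),
    max_row_sum = max(rowSums(abs(object$A))),
    communities = object$communities,
    iterations = length(object$trace),
    gamma = object$gamma, gamma_tau = object$gamma_tau,
    rss = sum(residuals(object)^2))
  class(out) <- "summary.nci"
  out
}

#' @export
print.summary.nci <- function(x, ...) {
  cat("NCI network fit\n")
  cat("  genes / time points:   ", x$n, "/", x$m, "\n")
  cat("  interactions:          ", x$n_interactions,
      " (", x$n_promotions, " promoting, ", x$n_repressions,
      " repressing)\n", sep = "")
  cat("  max row |a| sum:       ", format(x$max_row_sum, digits = 4),
      " (stability budget 1)\n", sep = "")
  cat("  residual sum of squares:", format(x$rss, digits = 4), "\n")
  cat("  penalty grid:          ", paste(x$gamma, collapse = ", "),
      "; final pass ", x$gamma_tau, "\n", sep = "")
  print(x$communities)
  invisible(x)
}

#' Extract the estimated transition matrix
#'
#' @param object Fitted `"nci"` object.
#' @param threshold Entries with `|a_ij|` at or below this are reported as
#'   zero (no interaction); defaults to the fit's `sign_threshold`.
#' @param ... Unused.
#' @export
coef.nci <- function(object, threshold = object$sign_threshold, ...) {
  A <- object$A
  A[abs(A) <= threshold] <- 0
  A
}

#' @export
fitted.nci <- function(object, ...) {
  m <- ncol(object$X)
  object$A %*% object$X[, -m, drop = FALSE]
}

#' @export
residuals.nci <- function(object, ...) {
  object$X[, -1, drop = FALSE] - fitted(object)
}

#' Forward-predict expression from a fitted network
#'
#' Iterates the fitted dynamics `x_{k+1} = A x_k` for `n_ahead` steps from a
#' starting state (by default the last observed time point).
#'
#' @param object Fitted `"nci"` object.
#' @param x0 Starting state; defaults to the last column of the training data.
#' @param n_ahead Number of steps to predict.
#' @param ... Unused.
#' @return Matrix `n x n_ahead` of predicted expression levels.
#' @export
predict.nci <- function(object, x0 = NULL, n_ahead = 1L, ...) {
  if (is.null(x0)) x0 <- object$X[, ncol(object$X)]
  out <- matrix(0, nrow(object$A), n_ahead)
  x <- x0
  for (k in seq_len(n_ahead)) {
    x <- drop(object$A %*% x)
    out[, k] <- x
  }
  rownames(out) <- rownames(object$A)
  colnames(out) <- paste0("ahead", seq_len(n_ahead))
  out
}

#' Simulate new trajectories from a fitted network
#'
#' @param object Fitted `"nci"` object.
#' @param nsim Number of trajectories.
#' @param seed Optional RNG seed.
#' @param m Time points per trajectory.
#' @param ... Unused.
#' @return List of `n x m` expression matrices (initial states uniform on
#'   `(0,1)`).
#' @export
simulate.nci <- function(object, nsim = 1, seed = NULL, m = ncol(object$X), ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_expression(object$A, m = m), simplify = FALSE)
}

#' Plot a fitted network as a signed adjacency image
#'
#' Displays the thresholded transition matrix as an image, with genes
#' reordered so detected communities form contiguous blocks.
#'
#' @param x Fitted `"nci"` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.nci <- function(x, ...) {
  A <- coef(x)
  ord <- order(ifelse(is.na(x$communities$membership), Inf,
                      x$communities$membership))
  A <- A[ord, ord]
  n <- nrow(A)
  graphics::image(seq_len(n), seq_len(n), t(A[n:1, ]),
                  col = grDevices::hcl.colors(33, "Blue-Red 2"),
                  xlab = "regulator", ylab = "target",
                  main = "Estimated network (community order)", ...)
  invisible(x)
}
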