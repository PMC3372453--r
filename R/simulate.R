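#' Discretize a linear ODE model of transcription
#'
#' Converts the continuous linear model \eqn{\dot x = Cx + SFx} (degradation
#' plus linearised reaction kinetics) into its exact discrete transition matrix
#' under a zero-order hold at sampling interval `dt`:
#' \deqn{A = e^{C\Delta t} + (e^{C\Delta t} - I)\,C^{-1} S F.}
#'
#' @param C Diagonal degradation-rate matrix with strictly negative diagonal
#'   entries (\eqn{-c_i}, per hour), or a numeric vector of the diagonal.
#' @param S Stoichiometric matrix (`n x n`, dimensionless).
#' @param F_mat Reaction-rate coefficient matrix (`n x n`, dimensionless).
#' @param dt Sampling interval in hours; must be positive.
#' @return The `n x n` discrete transition matrix `A`.
#' @examples
#' A <- discretize_ode(diag(c(-1, -2)), diag(2), matrix(0, 2, 2), dt = 0.5)
#' @export
discretize_ode <- function(C, S, F_mat, dt) {
  if (is.vector(C)) C <- diag(C, nrow = length(C))
  n <- nrow(C)
  stopifnot(is.matrix(C), ncol(C) == n, all(dim(S) == n), all(dim(F_mat) == n))
  if (!isTRUE(all.equal(C, diag(diag(C), nrow = n), check.attributes = FALSE)))
    stop("C must be diagonal")
  d <- diag(C)
  if (any(d >= 0)) stop("C must have strictly negative diagonal (degradation rates)")
  if (any(d == 0)) stop("C is singular")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be a positive scalar")
  # C diagonal, so the matrix exponential is entrywise
  eCdt <- diag(exp(d * dt), nrow = n)
  eCdt + (eCdt - diag(n)) %*% diag(1 / d, nrow = n) %*% S %*% F_mat
}

#' Generate a stable, sparse, community-structured regulatory network
#'
#' Plants `n_edges` signed directed interactions among `n` genes, with edges
#' falling preferentially inside the given communities
#' (`within_density > between_density`), positive diagonal self-decay terms
#' mimicking zero-order-hold degradation, and every row rescaled so its
#' absolute sum is at most `stability_margin` (hence the spectral radius is
#' below 1 and trajectories are bounded).
#'
#' @param n Number of genes.
#' @param communities List of disjoint integer vectors (subsets of `1:n`)
#'   giving the planted communities.  Genes in no community are background.
#' @param n_edges Exact number of off-diagonal interactions to plant.
#' @param within_density,between_density Relative sampling weight of gene
#'   pairs inside the same community versus all other pairs; both in `[0, 1]`.
#' @param sign_fraction Fraction of repressive (negative) edges.
#' @param stability_margin Target row absolute sum, in `(0, 1)`.
#' @param seed Optional RNG seed.
#' @return An object of class `"grn"`: a list with elements `A` (the `n x n`
#'   transition matrix, gene ids as dimnames), `communities`, `edges`
#'   (data frame of planted interactions) and `gene_ids`.
#' @examples
#' net <- generate_network(14, list(1:5, 6:10), n_edges = 27, seed = 1)
#' sum(net$A[row(net$A) != col(net$A)] != 0)
#' @export
generate_network <- function(n, communities = list(), n_edges,
                             within_density = 0.7, between_density = 0.1,
                             sign_fraction = 0.3, stability_margin = 0.95,
                             seed = NULL) {
  stopifnot(n >= 2, n_edges >= 0)
  if (n_edges > n * (n - 1L))
    stop("n_edges exceeds the number of off-diagonal pairs for n = ", n)
  if (within_density < 0 || within_density > 1 ||
      between_density < 0 || between_density > 1)
    stop("densities must lie in [0, 1]")
  if (stability_margin <= 0 || stability_margin >= 1)
    stop("stability_margin must lie in (0, 1)")
  idx <- unlist(communities)
  if (length(idx) && (anyDuplicated(idx) || any(idx < 1) || any(idx > n)))
    stop("communities must be disjoint subsets of 1:n")
  if (!is.null(seed)) set.seed(seed)

  memb <- rep(0L, n)
  for (k in seq_along(communities)) memb[communities[[k]]] <- k

  src <- rep(seq_len(n), each = n)
  tgt <- rep(seq_len(n), times = n)
  off <- src != tgt
  src <- src[off]; tgt <- tgt[off]
  within <- memb[src] != 0L & memb[src] == memb[tgt]
  wts <- ifelse(within, within_density, between_density)
  if (all(wts == 0)) wts[] <- 1  # degenerate: fall back to uniform
  pick <- sample.int(length(src), n_edges, prob = wts)

  A <- matrix(0, n, n)
  signs <- ifelse(stats::runif(n_edges) < sign_fraction, -1, 1)
  mags <- stats::runif(n_edges, 0.5, 1)
  A[cbind(src[pick], tgt[pick])] <- signs * mags
  diag(A) <- stats::runif(n, 0.2, 0.9)

  # stability budget sum_j |a_ij| <= margin.  The diagonal (zero-order-hold
  # decay e^{-c dt}) is physical and kept as drawn; only the interaction
  # mass is rescaled into the remaining budget.
  A <- rescale_offdiag(A, stability_margin)

  ids <- paste0("g", seq_len(n))
  dimnames(A) <- list(ids, ids)
  edges <- data.frame(source = ids[src[pick]], target = ids[tgt[pick]],
                      weight = A[cbind(src[pick], tgt[pick])],
                      stringsAsFactors = FALSE)
  structure(list(A = A, communities = communities, edges = edges,
                 gene_ids = ids, n = n),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("Gene regulatory network: ", x$n, " genes, ",
      sum(x$A[row(x$A) != col(x$A)] != 0), " interactions\n", sep = "")
  if (length(x$communities))
    cat("Planted communities:",
        paste(vapply(x$communities, function(g) paste0("{", length(g), " genes}"),
                     ""), collapse = ", "), "\n")
  cat("Max row |sum|:", format(max(rowSums(abs(x$A))), digits = 4), "\n")
  invisible(x)
}

#' Deterministic 14-gene benchmark network
#'
#' A fixed synthetic benchmark network of 14 genes and 27 signed interactions
#' with two planted five-gene communities (genes 1-5 and 6-10), a bridge gene
#' (11) and a small periphery (12-14); the undirected diameter is 6.  It is a
#' synthetic stand-in for the classic small GRN benchmark configuration
#' (gene count, interaction count, community layout and diameter all match);
#' the exact wiring and weights are this package's own and are documented
#' as synthetic.
#'
#' Edge magnitudes and self-decay terms are fixed (not drawn at run time), so
#' the network is identical across sessions; rows are rescaled to an absolute
#' sum of at most 0.95 so the dynamics are stable.
#'
#' @return A `"grn"` object (see [generate_network()]).
#' @examples
#' net <- test1_network()
#' graph_stats(net$A)$diameter  # 6
#' @export
test1_network <- function() {
  edges <- rbind(
    # community A (genes 1-5), hub gene 5
    c(1, 2, +1), c(2, 3, +1), c(3, 4, -1), c(4, 5, +1), c(5, 1, +1),
    c(2, 5, -1), c(3, 5, +1), c(1, 4, +1), c(4, 2, -1), c(2, 1, +1),
    c(3, 1, -1),
    # community B (genes 6-10), hub gene 6
    c(6, 7, +1), c(7, 8, -1), c(8, 6, +1), c(6, 9, +1), c(9, 10, +1),
    c(10, 6, -1), c(8, 9, +1), c(7, 9, -1), c(10, 8, +1), c(7, 6, +1),
    # bridge gene 11 linking the two communities
    c(5, 11, +1), c(11, 6, +1),
    # periphery: gene 12 off community A, chain 13-14 off community B
    c(5, 12, -1), c(9, 13, +1), c(13, 14, +1), c(14, 13, -1)
  )
  n <- 14L
  A <- matrix(0, n, n)
  # fixed magnitudes cycling over a small set keeps the fixture deterministic
  mags <- rep(c(0.9, 0.7, 0.8, 0.6, 0.75), length.out = nrow(edges))
  A[edges[, 1:2]] <- edges[, 3] * mags
  diag(A) <- rep(c(0.6, 0.4, 0.8, 0.5, 0.7, 0.3, 0.65), length.out = n)
  A <- rescale_offdiag(A, 0.95)
  ids <- paste0("g", seq_len(n))
  dimnames(A) <- list(ids, ids)
  ii <- A[edges[, 1:2]]
  structure(list(A = A, communities = list(1:5, 6:10),
                 edges = data.frame(source = ids[edges[, 1]],
                                    target = ids[edges[, 2]],
                                    weight = ii, stringsAsFactors = FALSE),
                 gene_ids = ids, n = n),
            class = "grn")
}

#' Simulate time-course expression from a linear network
#'
#' Iterates the exact discrete dynamics \eqn{x_{k+1} = A x_k} from an initial
#' state, producing a genes-by-time expression matrix.  When `x0` is not
#' supplied it is drawn uniformly on \eqn{(0,1)^n}.
#'
#' @param A Transition matrix, or a `"grn"` object.
#' @param m Number of time points (columns); at least 2.
#' @param x0 Optional initial state vector of length `n`.
#' @param seed Optional RNG seed (used for the default `x0`).
#' @return An `n x m` matrix; columns are time points `t0, t1, ...`.
#' @export
simulate_expression <- function(A, m = 50L, x0 = NULL, seed = NULL) {
  if (inherits(A, "grn")) A <- A$A
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  if (m < 2) stop("m must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- stats::runif(n)
  if (length(x0) != n) stop("x0 must have length ", n)
  X <- matrix(0, n, m)
  X[, 1L] <- x0
  for (k in seq_len(m - 1L)) X[, k + 1L] <- A %*% X[, k]
  rownames(X) <- rownames(A) %||% paste0("g", seq_len(n))
  colnames(X) <- paste0("t", seq_len(m) - 1L)
  X
}

#' Corrupt a fraction of expression entries with Gaussian noise
#'
#' Perturbs exactly `round(fraction * n * m)` entries, chosen uniformly
#' without replacement, by independent Gaussian noise with standard deviation
#' `sigma`; all other entries are returned bit-identical.
#'
#' @param X Expression matrix.
#' @param fraction Fraction of entries to perturb, in `[0, 1]`.
#' @param sigma Noise standard deviation (default 1, i.e. unit variance).
#' @param seed Optional RNG seed.
#' @return The perturbed matrix.
#' @export
add_noise <- function(X, fraction = 0.1, sigma = 1, seed = NULL) {
  stopifnot(is.matrix(X))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  k <- round(fraction * length(X))
  if (k == 0) return(X)
  idx <- sample.int(length(X), k)
  X[idx] <- X[idx] + stats::rnorm(k, 0, sigma)
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shrink each row's off-diagonal absolute mass into the budget left over by
# the (physical) diagonal decay term, so sum_j |a_ij| <= margin per row.
rescale_offdiag <- function(A, margin) {
  d <- abs(diag(A))
  if (any(d >= margin))
    stop("diagonal entries must be below the stability margin")
  d0 <- diag(A)
  off <- rowSums(abs(A)) - d
  scale <- pmin(1, (margin - d) / pmax(off, .Machine$double.eps))
  A <- A * scale
  diag(A) <- d0
  A
}
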