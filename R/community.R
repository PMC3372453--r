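#' Shortest-path penalty weights from a network support
#'
#' Builds the nonnegative weight matrix used by the community step:
#' \eqn{w1_{ij} = (p_{ij}/p_0)^2}, where `p_ij` is the unweighted
#' shortest-path length between genes `i` and `j` on the undirected view of
#' the current network support and `p_0` scales which path lengths count as
#' "close".  Disconnected pairs are capped at `p_ij = n`, which keeps the
#' weights finite while strongly penalising cross-component entries.  The
#' diagonal is zero.
#'
#' @param support Square logical/0-1 adjacency matrix (off-diagonal support
#'   of the current network estimate); the undirected view is used.
#' @param p0_fraction `p0` as a fraction of the graph diameter (default 1/4).
#' @param p0 Optional explicit scale overriding `p0_fraction`.
#' @return List with `W1` (weight matrix), `p` (path-length matrix), `p0`
#'   and `diameter`.
#' @export
shortest_path_weights <- function(support, p0_fraction = 0.25, p0 = NULL) {
  stopifnot(is.matrix(support), nrow(support) == ncol(support))
  n <- nrow(support)
  adj <- (support != 0)
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  if (!any(adj)) stop("network support has no edges; diameter undefined")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  p <- igraph::distances(g)
  diam <- max(p[is.finite(p)])
  p[is.infinite(p)] <- n
  diag(p) <- 0
  if (is.null(p0)) p0 <- p0_fraction * diam
  if (p0 <= 0) stop("p0 must be positive")
  W1 <- (p / p0)^2
  dimnames(W1) <- dimnames(support)
  list(W1 = W1, p = p, p0 = p0, diameter = diam)
}

#' Distance-based penalty weights for a point cloud
#'
#' The point-cloud analogue of [shortest_path_weights()]: weights
#' \eqn{(d_{ij}/p_0)^2} from pairwise Euclidean distances, as used to test
#' the community step on planar clustering problems.
#'
#' @param points Numeric matrix, one row per point.
#' @param p0 Scale parameter, positive.
#' @return Nonnegative symmetric weight matrix with zero diagonal.
#' @export
distance_weights <- function(points, p0) {
  if (p0 <= 0) stop("p0 must be positive")
  d <- unname(as.matrix(stats::dist(points)))
  (d / p0)^2
}

#' Community weight matrix from a low-rank community indicator
#'
#' Turns the low-rank factor `L*` of the community decomposition into the
#' penalty weights of the next inference pass: `W = 1 - L*` after clipping
#' `L*` to `[0, 1]` (negatives set to zero; divided by its maximum when that
#' exceeds 1).  Gene pairs inside a detected community get weights near zero
#' (their interactions are cheap); pairs across communities get weights near
#' one.
#'
#' @param L_star Square numeric matrix.
#' @return Nonnegative weight matrix with all entries in `[0, 1]`.
#' @export
update_weight_matrix <- function(L_star) {
  stopifnot(is.matrix(L_star), nrow(L_star) == ncol(L_star))
  Lc <- pmax(L_star, 0)
  mx <- max(Lc)
  if (mx > 1) Lc <- Lc / mx
  1 - Lc
}

#' Extract communities from a low-rank matrix by sparse SVD
#'
#' Sequential rank-one extraction: take the leading singular triplet of the
#' (deflated) matrix, zero out left/right loadings smaller than
#' `sparsity_level` times the largest absolute loading of that vector, define
#' a candidate community as the genes with a nonzero thresholded loading in
#' either vector, subtract the thresholded rank-one layer and repeat.
#' Extraction stops at `max_rank` layers or when the leading singular value
#' drops below `sv_ratio_min` times the first one.  A gene captured by
#' several layers is assigned to the layer where its absolute loading is
#' largest (ties to the earlier layer); genes captured by no layer are
#' reported as outliers.
#'
#' @param L Square numeric matrix (low-rank community indicator).
#' @param max_rank Maximum number of layers to extract.
#' @param sparsity_level Loading threshold as a fraction of the maximum
#'   absolute loading, in `[0, 1)`.
#' @param sv_ratio_min Stop when the leading singular value falls below this
#'   fraction of the first layer's.
#' @return Object of class `"nci_communities"`: list with `groups` (list of
#'   integer vectors), `outliers` (integer vector) and `membership`
#'   (integer vector, `NA` for outliers).
#' @examples
#' L <- matrix(0, 5, 5); L[1:3, 1:3] <- 1; L[4:5, 4:5] <- 1
#' ssvd_communities(L)
#' @export
ssvd_communities <- function(L, max_rank = 10L, sparsity_level = 0.5,
                             sv_ratio_min = 0.1) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  n <- nrow(L)
  R <- L
  loading <- numeric(n)          # best |loading| seen per gene
  membership <- rep(NA_integer_, n)
  sv1 <- NA_real_
  layer <- 0L
  while (layer < max_rank) {
    s <- svd(R, nu = 1, nv = 1)
    d1 <- s$d[1]
    if (layer == 0L) sv1 <- d1
    if (!is.finite(d1) || d1 <= 0 || d1 < sv_ratio_min * sv1) break
    layer <- layer + 1L
    u <- drop(s$u); v <- drop(s$v)
    u[abs(u) < sparsity_level * max(abs(u))] <- 0
    v[abs(v) < sparsity_level * max(abs(v))] <- 0
    members <- which(u != 0 | v != 0)
    load <- pmax(abs(u), abs(v))
    take <- members[load[members] > loading[members]]  # strict: ties stay put
    membership[take] <- layer
    loading[take] <- load[take]
    R <- R - d1 * u %*% t(v)
  }
  ids <- sort(unique(membership[!is.na(membership)]))
  groups <- lapply(ids, function(k) which(membership == k))
  # renumber consecutively in extraction order
  membership <- match(membership, ids)
  structure(list(groups = groups, outliers = which(is.na(membership)),
                 membership = membership),
            class = "nci_communities")
}

#' @export
print.nci_communities <- function(x, ...) {
  cat("Communities:", length(x$groups), "\n")
  for (k in seq_along(x$groups))
    cat("  [", k, "] ", paste(x$groups[[k]], collapse = ", "), "\n", sep = "")
  if (length(x$outliers))
    cat("Outliers: ", paste(x$outliers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pairwise overlap between two community partitions
#'
#' @param est,truth Lists of integer vectors (gene index sets).
#' @return Integer matrix `length(est) x length(truth)` of intersection
#'   sizes, bounded by the smaller group size in each pair.
#' @export
community_overlap <- function(est, truth) {
  out <- matrix(0L, length(est), length(truth))
  for (i in seq_along(est))
    for (j in seq_along(truth))
      out[i, j] <- length(intersect(est[[i]], truth[[j]]))
  out
}

#' Basic graph statistics of a network estimate
#'
#' Vertex and arc counts (self-loops excluded), density `arcs / n^2`, and the
#' undirected diameter (longest finite shortest path).
#'
#' @param A Square matrix (weighted or 0/1 adjacency) or a `"grn"` object.
#' @param sign_threshold Entries with `|a_ij|` at or below this count as
#'   absent.
#' @return List with `n_vertices`, `n_arcs`, `density`, `diameter`.
#' @export
graph_stats <- function(A, sign_threshold = 0) {
  if (inherits(A, "grn")) A <- A$A
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  n <- nrow(A)
  supp <- abs(A) > sign_threshold
  diag(supp) <- FALSE
  n_arcs <- sum(supp)
  diam <- NA_real_
  if (any(supp)) {
    g <- igraph::graph_from_adjacency_matrix(supp | t(supp), mode = "undirected")
    p <- igraph::distances(g)
    diam <- max(p[is.finite(p)])
  }
  list(n_vertices = n, n_arcs = n_arcs, density = n_arcs / n^2,
       diameter = diam)
}
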