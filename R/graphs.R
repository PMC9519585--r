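#' Neighbourhood graph container
#'
#' Symmetric non-negative affinity matrix feeding the spectral embedding,
#' in one of three variants: `knn` (mutual-or nearest neighbours), `radius`
#' (fixed squared-distance threshold), or `full` (all pairs, weights only).
#'
#' @param affinity Symmetric non-negative matrix with zero diagonal.
#' @param variant `"knn"`, `"radius"` or `"full"`.
#' @param weighted Logical; weighted graphs carry correlation weights in
#'   `[0, 1]`, unweighted graphs carry 0/1 indicators.
#' @param params Named list of the construction parameters (`k` or `eps_radius`).
#' @return An object of class `cnp_graph`.
#' @export
cnp_graph <- function(affinity, variant, weighted, params = list()) {
  affinity <- check_matrix(affinity, "affinity")
  if (nrow(affinity) != ncol(affinity)) abort("affinity must be square")
  if (max(abs(affinity - t(affinity))) > 1e-12) abort("affinity must be symmetric")
  if (any(affinity < 0)) abort("affinity must be non-negative")
  if (any(diag(affinity) != 0)) abort("affinity must have a zero diagonal")
  structure(list(affinity = affinity, variant = variant,
                 weighted = isTRUE(weighted), params = params),
            class = "cnp_graph")
}

#' @export
print.cnp_graph <- function(x, ...) {
  cat(sprintf("<cnp_graph> %s (%s), %d nodes, %d edges\n", x$variant,
              if (x$weighted) "weighted" else "unweighted",
              nrow(x$affinity), sum(x$affinity[upper.tri(x$affinity)] > 0)))
  invisible(x)
}

#' Correlation similarity weights between samples
#'
#' Pearson correlation between rows of `X`, rescaled from `[-1, 1]` to
#' `[0, 1]` via `w = (r + 1) / 2`, so zero represents a perfect negative
#' correlation. Used to weight neighbourhood graphs (weights must be
#' non-negative).
#'
#' @param x Numeric matrix, samples in rows; every row needs variance > 0.
#' @return An `n x n` symmetric matrix of weights in `[0, 1]`.
#' @export
correlation_weight_matrix <- function(x) {
  x <- check_matrix(x, "x")
  v <- apply(x, 1, sd)
  if (any(v == 0)) abort(sprintf("row %d has zero variance", which(v == 0)[1]))
  (cor(t(x)) + 1) / 2
}

# shared edge -> affinity finisher
finish_graph <- function(x, adj, variant, weighted, params) {
  diag(adj) <- 0
  if (weighted) {
    w <- correlation_weight_matrix(x)
    adj <- adj * w
  }
  cnp_graph(adj, variant, weighted, params)
}

#' k-nearest-neighbour graph
#'
#' Directed k-nearest neighbours by squared Euclidean distance between
#' samples, made undirected by the OR rule: two samples are connected if
#' either lies within the `k` nearest neighbours of the other.
#'
#' @param x Samples-in-rows matrix.
#' @param k Neighbourhood size, `1 <= k < n`.
#' @param weighted Replace the 0/1 edges with correlation weights.
#' @return A [cnp_graph()].
#' @export
knn_graph <- function(x, k, weighted = FALSE) {
  x <- check_matrix(x, "x")
  n <- nrow(x)
  k <- as.integer(round(k))
  if (k < 1 || k >= n) abort(sprintf("`k` must satisfy 1 <= k < n (k = %d, n = %d)", k, n))
  d2 <- sq_dists(x)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[-1][seq_len(k)]   # nearest excluding self
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))                 # OR symmetrization
  finish_graph(x, adj, "knn", weighted, list(k = k))
}

#' Radius neighbourhood graph
#'
#' Connects two samples when their squared Euclidean distance is at most
#' `eps_radius` (the radius is expressed in squared-distance units). An empty
#' graph is allowed here; the embedding stage rejects disconnected graphs.
#'
#' @param x Samples-in-rows matrix.
#' @param eps_radius Positive squared-distance threshold.
#' @param weighted Replace the 0/1 edges with correlation weights.
#' @return A [cnp_graph()].
#' @export
radius_graph <- function(x, eps_radius, weighted = FALSE) {
  x <- check_matrix(x, "x")
  assert_scalar_number(eps_radius, "eps_radius", lower = 1e-300)
  adj <- (sq_dists(x) <= eps_radius) * 1
  finish_graph(x, adj, "radius", weighted, list(eps_radius = eps_radius))
}

#' Fully-connected weighted graph
#'
#' All samples connected to all others, differentiated only by the
#' correlation weights (no neighbourhood restriction).
#'
#' @param x Samples-in-rows matrix, `n >= 2`.
#' @return A weighted [cnp_graph()].
#' @export
full_graph <- function(x) {
  x <- check_matrix(x, "x")
  if (nrow(x) < 2) abort("need at least 2 samples")
  w <- correlation_weight_matrix(x)
  diag(w) <- 0
  cnp_graph(w, "full", TRUE, list())
}

# connected components of the affinity pattern (edge = positive affinity)
graph_components <- function(affinity) {
  g <- igraph::graph_from_adjacency_matrix(affinity > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$no
}
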