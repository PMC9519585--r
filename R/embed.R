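#' Embedding result container
#'
#' All dimensionality-reduction routines return two components per sample
#' (the two reconstructed gradient maps), plus provenance and solver
#' diagnostics. Component order is as produced by the algorithm; matching
#' components to ground-truth maps is the evaluation stage's job, and every
#' component carries an inherent sign ambiguity.
#'
#' @param components `n x m` numeric matrix (`m = 2`).
#' @param algorithm Algorithm identifier string.
#' @param params Named list of algorithm parameters.
#' @param diagnostics Named list (eigenvalues, final KL divergence, ...).
#' @return An object of class `cnp_embedding`.
#' @export
cnp_embedding <- function(components, algorithm, params = list(),
                          diagnostics = list()) {
  components <- check_matrix(components, "components")
  colnames(components) <- paste0("c", seq_len(ncol(components)))
  structure(list(components = fix_signs(components), algorithm = algorithm,
                 params = params, diagnostics = diagnostics),
            class = "cnp_embedding")
}

#' @export
print.cnp_embedding <- function(x, ...) {
  cat(sprintf("<cnp_embedding> %s: %d samples x %d components\n",
              x$algorithm, nrow(x$components), ncol(x$components)))
  invisible(x)
}

# reproducible sign convention: largest-magnitude entry of each column > 0
fix_signs <- function(components) {
  for (j in seq_len(ncol(components))) {
    v <- components[, j]
    if (v[which.max(abs(v))] < 0) components[, j] <- -v
  }
  components
}

disconnected_error <- function(n_comp) {
  abort(sprintf("neighbourhood graph is disconnected (%d components); choose a larger neighbourhood", n_comp),
        class = "cnp_disconnected_error")
}

as_matrix_input <- function(x) {
  if (inherits(x, "cnp_timeseries")) return(x$data)
  if (inherits(x, "cnp_fingerprints")) return(unclass(x))
  check_matrix(x, "x")
}

#' Spectral embedding (Laplacian eigenmaps)
#'
#' Converts a neighbourhood graph to its symmetric normalized graph
#' Laplacian `L = I - D^{-1/2} W D^{-1/2}` and decomposes it. The
#' eigenvectors of the `m` smallest non-zero eigenvalues are the connectopic
#' maps. The graph must be connected (exactly one zero eigenvalue up to a
#' relative tolerance of 1e-8); a disconnected graph raises a
#' `cnp_disconnected_error`, which parameter selection treats as an invalid
#' trial.
#'
#' @param graph A [cnp_graph()].
#' @param m Number of components (default 2).
#' @return A [cnp_embedding()]; `diagnostics$eigenvalues` holds the full
#'   ascending Laplacian spectrum.
#' @export
spectral_embed <- function(graph, m = 2) {
  stopifnot(inherits(graph, "cnp_graph"))
  w <- graph$affinity
  n <- nrow(w)
  if (n < m + 1) abort("graph too small for the requested number of components")
  deg <- rowSums(w)
  if (any(deg <= 0) || graph_components(w) > 1) {
    disconnected_error(max(graph_components(w), sum(deg <= 0) + 1))
  }
  dhalf <- 1 / sqrt(deg)
  lap <- diag(n) - (dhalf * w) * rep(dhalf, each = n)  # D^-1/2 W D^-1/2
  lap <- (lap + t(lap)) / 2
  eig <- eigen(lap, symmetric = TRUE)
  vals <- rev(eig$values)                 # ascending
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  tol <- 1e-8 * max(abs(vals))
  n_zero <- sum(vals < tol)
  if (n_zero != 1) disconnected_error(n_zero)
  idx <- (n_zero + 1):(n_zero + m)
  # rescale by D^{-1/2}: the random-walk eigenvectors, constant on the
  # trivial mode, as returned by the standard spectral-embedding solvers
  cnp_embedding(vecs[, idx, drop = FALSE] * (1 / sqrt(deg)),
                algorithm = paste0("spectral_", graph$variant,
                                   if (graph$weighted) "_weighted" else "_unweighted"),
                params = graph$params,
                diagnostics = list(eigenvalues = vals))
}

#' Linear embeddings: PCA and ICA
#'
#' `pca_embed()` returns the top-`m` principal-component scores of the
#' fingerprint rows. `ica_embed()` whitens to `m` dimensions and extracts
#' `m` independent components by symmetric FastICA (logcosh contrast) from a
#' seeded random orthonormal start. Neither takes a tunable parameter.
#'
#' @param x Samples-in-rows matrix (or fingerprints / timeseries object).
#' @param m Number of components (default 2).
#' @return A [cnp_embedding()].
#' @export
pca_embed <- function(x, m = 2) {
  x <- as_matrix_input(x)
  if (nrow(x) <= m) abort("need more samples than components")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > 1e-12 * pc$sdev[1]) < m) abort("input has rank below the requested components")
  cnp_embedding(pc$x[, seq_len(m), drop = FALSE], "pca",
                diagnostics = list(sdev = pc$sdev))
}

#' @rdname pca_embed
#' @param seed Integer seed for the FastICA initialisation.
#' @param max_iter,tol FastICA iteration controls.
#' @export
ica_embed <- function(x, m = 2, seed = 1, max_iter = 500, tol = 1e-8) {
  x <- as_matrix_input(x)
  n <- nrow(x)
  if (n <= m) abort("need more samples than components")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = m, nv = 0)
  if (sv$d[m] <= 1e-12 * sv$d[1]) abort("input has rank below the requested components")
  xw <- t(sv$u) * sqrt(n)                       # m x n, whitened (unit variance)
  w <- with_seed_(seed, matrix(rnorm(m * m), m, m))
  orth <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  w <- orth(w)
  for (it in seq_len(max_iter)) {
    wx <- w %*% xw
    g <- tanh(wx)
    gp <- 1 - g^2
    w_new <- orth(g %*% t(xw) / n - diag(rowMeans(gp), m) %*% w)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) break
  }
  cnp_embedding(t(w %*% xw), "ica", params = list(seed = seed),
                diagnostics = list(iterations = it, converged = delta < tol))
}

# kernel evaluations used by kernel PCA
kernel_matrix <- function(x, kernel, gamma = NULL) {
  switch(kernel,
    poly2 = (tcrossprod(x) + 1)^2,
    rbf = {
      assert_scalar_number(gamma, "gamma", lower = 1e-300)
      exp(-gamma * sq_dists(x))
    },
    abort(sprintf("unknown kernel '%s' (use 'poly2' or 'rbf')", kernel)))
}

#' Kernel PCA embedding
#'
#' Non-linear extension of PCA through a kernel: either a second-order
#' polynomial kernel `k(x, y) = (x'y + 1)^2` (parameter-free) or an RBF
#' kernel `k(x, y) = exp(-gamma ||x - y||^2)`. The kernel matrix is
#' double-centered in feature space and the top-`m` eigenvector projections
#' are returned.
#'
#' @param x Samples-in-rows matrix.
#' @param kernel `"poly2"` or `"rbf"`.
#' @param gamma Spread of the RBF kernel (> 0; ignored for `poly2`).
#' @param m Number of components (default 2).
#' @return A [cnp_embedding()].
#' @export
kpca_embed <- function(x, kernel = c("poly2", "rbf"), gamma = NULL, m = 2) {
  x <- as_matrix_input(x)
  kernel <- rlang::arg_match(kernel)
  n <- nrow(x)
  if (n <= m) abort("need more samples than components")
  k <- kernel_matrix(x, kernel, gamma)
  one <- matrix(1 / n, n, n)
  kc <- k - one %*% k - k %*% one + one %*% k %*% one
  kc <- (kc + t(kc)) / 2
  eig <- eigen(kc, symmetric = TRUE)
  vals <- eig$values[seq_len(m)]
  if (any(vals <= 1e-12 * max(abs(eig$values)))) abort("kernel matrix has rank below the requested components")
  proj <- eig$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(vals), m)
  cnp_embedding(proj, paste0("kpca_", kernel),
                params = list(gamma = gamma),
                diagnostics = list(eigenvalues = eig$values))
}

# k nearest neighbour indices (excluding self) by squared Euclidean distance
knn_indices <- function(x, k) {
  d2 <- sq_dists(x)
  t(vapply(seq_len(nrow(x)), function(i) order(d2[i, ])[-1][seq_len(k)],
           integer(k)))
}

# eigenvectors of the smallest eigenvalues of symmetric M, skipping the
# bottom `skip` (the near-null constant directions)
bottom_eigenvectors <- function(m_mat, m, skip = 1) {
  eig <- eigen((m_mat + t(m_mat)) / 2, symmetric = TRUE)
  n <- ncol(m_mat)
  list(vectors = eig$vectors[, rev(seq_len(n)), drop = FALSE][, (skip + 1):(skip + m), drop = FALSE],
       values = rev(eig$values))
}

#' Modified locally linear embedding (MLLE)
#'
#' Locally linear embedding using multiple local weight vectors per point,
#' which stabilises the reconstruction and reduces distortions relative to
#' standard LLE. Each point's neighbourhood contributes `s_i` weight vectors
#' built from the bottom eigenvectors of the local Gram matrix combined with
#' the regularised barycentric weights via a Householder transform. The
#' embedding is the null-space of the resulting alignment matrix.
#'
#' @param x Samples-in-rows matrix.
#' @param k Neighbourhood size; must satisfy `m < k < n`.
#' @param m Number of components (default 2).
#' @param reg Relative regularisation of the local Gram matrices.
#' @return A [cnp_embedding()].
#' @export
mlle_embed <- function(x, k, m = 2, reg = 1e-3) {
  x <- as_matrix_input(x)
  n <- nrow(x); d_in <- ncol(x)
  k <- as.integer(round(k))
  if (k <= m) abort("MLLE requires k > m")
  if (k >= n) abort("MLLE requires k < n")
  nbrs <- knn_indices(x, k)
  nev <- min(d_in, k)

  v_list <- vector("list", n)
  evals <- matrix(0, n, nev)
  for (i in seq_len(n)) {
    g <- x[nbrs[i, ], , drop = FALSE] - rep(x[i, ], each = k)
    c_loc <- tcrossprod(g)
    eig <- eigen(c_loc, symmetric = TRUE)   # descending
    v_list[[i]] <- eig$vectors
    evals[i, ] <- pmax(eig$values[seq_len(nev)], 0)
  }

  # regularised barycentric weights (standard LLE step)
  reg_i <- reg * rowSums(evals)
  w_reg <- matrix(0, n, k)
  for (i in seq_len(n)) {
    tmp <- crossprod(v_list[[i]], rep(1, k))
    denom <- c(evals[i, ] + reg_i[i], rep(reg_i[i], k - nev))
    w_reg[i, ] <- v_list[[i]] %*% (tmp / denom)
  }
  w_reg <- w_reg / rowSums(w_reg)

  # size of each point's "almost null space"
  rho <- rowSums(evals[, (m + 1):nev, drop = FALSE]) /
    rowSums(evals[, seq_len(m), drop = FALSE])
  eta <- median(rho)
  cumsums <- t(apply(evals, 1, cumsum))
  s_range <- integer(n)
  for (i in seq_len(n)) {
    eta_range <- cumsums[i, nev] / cumsums[i, seq_len(nev - 1)] - 1
    s_range[i] <- sum(rev(eta_range) < eta)
  }
  s_range <- pmax(s_range + (k - nev), 1L)

  m_mat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s_i <- s_range[i]
    vi <- v_list[[i]][, (k - s_i + 1):k, drop = FALSE]
    alpha_i <- sqrt(sum(colSums(vi)^2)) / sqrt(s_i)
    h <- alpha_i - crossprod(vi, rep(1, k))
    nh <- sqrt(sum(h^2))
    h <- if (nh < 1e-12) h * 0 else h / nh
    wi <- vi - 2 * (vi %*% h) %*% t(h) + (1 - alpha_i) * w_reg[i, ]
    nb <- nbrs[i, ]
    m_mat[nb, nb] <- m_mat[nb, nb] + tcrossprod(wi)
    wi_sum <- rowSums(wi)
    m_mat[i, nb] <- m_mat[i, nb] - wi_sum
    m_mat[nb, i] <- m_mat[nb, i] - wi_sum
    m_mat[i, i] <- m_mat[i, i] + s_i
  }
  ns <- bottom_eigenvectors(m_mat, m, skip = 1)
  cnp_embedding(ns$vectors, "mlle", params = list(k = k),
                diagnostics = list(eigenvalues = ns$values[seq_len(m + 1)]))
}

#' Local tangent space alignment (LTSA)
#'
#' Fits a local tangent hyperplane (local PCA) within each neighbourhood and
#' finds the global embedding that best aligns the local tangent
#' coordinates, via the null-space of an alignment matrix.
#'
#' @inheritParams mlle_embed
#' @return A [cnp_embedding()].
#' @export
ltsa_embed <- function(x, k, m = 2) {
  x <- as_matrix_input(x)
  n <- nrow(x)
  k <- as.integer(round(k))
  if (k <= m) abort("LTSA requires k > m")
  if (k >= n) abort("LTSA requires k < n")
  nbrs <- knn_indices(x, k)
  m_mat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xi <- x[nbrs[i, ], , drop = FALSE]
    xi <- sweep(xi, 2, colMeans(xi))
    v <- eigen(tcrossprod(xi), symmetric = TRUE)$vectors   # descending
    gi <- cbind(1 / sqrt(k), v[, seq_len(m), drop = FALSE])
    nb <- nbrs[i, ]
    m_mat[nb, nb] <- m_mat[nb, nb] - tcrossprod(gi)
    m_mat[cbind(nb, nb)] <- m_mat[cbind(nb, nb)] + 1
  }
  ns <- bottom_eigenvectors(m_mat, m, skip = 1)
  cnp_embedding(ns$vectors, "ltsa", params = list(k = k),
                diagnostics = list(eigenvalues = ns$values[seq_len(m + 1)]))
}

#' Isomap embedding
#'
#' Multidimensional scaling on geodesic rather than Euclidean distances: a
#' k-nearest-neighbour graph weighted by local Euclidean distances, all-pairs
#' shortest paths (Dijkstra), then classical MDS of the geodesic distance
#' matrix.
#'
#' @inheritParams mlle_embed
#' @return A [cnp_embedding()]; raises `cnp_disconnected_error` when the
#'   neighbourhood graph is disconnected.
#' @export
isomap_embed <- function(x, k, m = 2) {
  x <- as_matrix_input(x)
  n <- nrow(x)
  k <- as.integer(round(k))
  if (k < 1 || k >= n) abort(sprintf("`k` must satisfy 1 <= k < n (k = %d, n = %d)", k, n))
  d2 <- sq_dists(x)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[-1][seq_len(k)]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))
  dist_w <- sqrt(d2) * adj
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  if (igraph::components(g)$no > 1) disconnected_error(igraph::components(g)$no)
  igraph::E(g)$weight <- dist_w[as.matrix(igraph::as_edgelist(g, names = FALSE))]
  geo <- igraph::distances(g, algorithm = "dijkstra")
  mds <- cmdscale(geo, k = m, eig = TRUE)
  if (ncol(mds$points) < m) abort("geodesic MDS produced fewer components than requested")
  cnp_embedding(mds$points, "isomap", params = list(k = k),
                diagnostics = list(eigenvalues = mds$eig))
}

#' Diffusion map embedding
#'
#' Random-walk view of the neighbourhood graph: a kNN graph is weighted by a
#' Gaussian heat kernel `exp(-||x - y||^2 / eps)`, the kernel is
#' density-corrected by `K_alpha = D^-alpha K D^-alpha` (alpha between 0,
#' maximal influence of sampling density, and 1, none), row-normalised to a
#' transition matrix `P`, and the eigenvectors of the 2nd and 3rd largest
#' eigenvalues of `P` (the first is the trivial constant) scaled by
#' `lambda^t` form the embedding.
#'
#' @inheritParams mlle_embed
#' @param eps_diff Heat-kernel spread (> 0).
#' @param alpha Density-normalisation exponent in `[0, 1]`.
#' @param t Diffusion time (default 1).
#' @return A [cnp_embedding()]; raises `cnp_disconnected_error` on a
#'   disconnected graph.
#' @export
diffusion_embed <- function(x, k, eps_diff, alpha = 0.5, m = 2, t = 1) {
  x <- as_matrix_input(x)
  n <- nrow(x)
  k <- as.integer(round(k))
  if (k < 1 || k >= n) abort(sprintf("`k` must satisfy 1 <= k < n (k = %d, n = %d)", k, n))
  assert_scalar_number(eps_diff, "eps_diff", lower = 1e-300)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  d2 <- sq_dists(x)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[-1][seq_len(k)]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))
  if (graph_components(adj) > 1) disconnected_error(graph_components(adj))
  kern <- exp(-d2 / eps_diff) * adj
  diag(kern) <- 1                                   # self-similarity
  q <- rowSums(kern)
  k_alpha <- kern / outer(q^alpha, q^alpha)
  d_alpha <- rowSums(k_alpha)
  # symmetric conjugate of P (k_alpha is symmetric, so s is too)
  s <- k_alpha / outer(sqrt(d_alpha), sqrt(d_alpha))
  eig <- eigen(s, symmetric = TRUE)
  phi <- eig$vectors / sqrt(d_alpha)                # right eigenvectors of P
  lam <- eig$values
  comps <- phi[, 2:(m + 1), drop = FALSE] *
    rep(lam[2:(m + 1)]^t, each = n)
  cnp_embedding(comps, "diffusion",
                params = list(k = k, eps_diff = eps_diff, alpha = alpha, t = t),
                diagnostics = list(eigenvalues = lam))
}

#' t-SNE embedding with PCA initialisation and restarts
#'
#' Exact t-SNE (Barnes-Hut disabled) initialised from the PCA embedding,
#' fitted five times with seeded jitter on the initialisation; the fit with
#' the smallest final Kullback-Leibler divergence is returned, and all five
#' divergences are recorded in the diagnostics.
#'
#' @param x Samples-in-rows matrix.
#' @param perplexity Effective number of nearest neighbours (> 1 and small
#'   enough for `n`; t-SNE requires `3 * perplexity < n - 1`).
#' @param learning_rate Gradient-descent step size (> 0).
#' @param m Number of components (default 2).
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Number of restarts (default 5).
#' @param max_iter Gradient-descent iterations per fit.
#' @return A [cnp_embedding()]; `diagnostics$kl` is the winning divergence,
#'   `diagnostics$kl_all` all restart divergences.
#' @export
tsne_embed <- function(x, perplexity, learning_rate = 200, m = 2, seed = 1,
                       n_restarts = 5, max_iter = 1000) {
  x <- as_matrix_input(x)
  n <- nrow(x)
  if (perplexity >= n) abort("`perplexity` must be < n")
  if (3 * perplexity >= n - 1) abort("t-SNE requires 3 * perplexity < n - 1")
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-300)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(m), drop = FALSE]
  init0 <- pc / sd(pc[, 1]) * 1e-4          # small-scale PCA initialisation
  fits <- lapply(seq_len(n_restarts), function(r) {
    with_seed_(child_seed(seed, r), {
      init <- init0 + matrix(rnorm(length(init0), sd = 1e-6), n, m)
      fit <- Rtsne::Rtsne(x, dims = m, perplexity = perplexity,
                          theta = 0, eta = learning_rate, Y_init = init,
                          pca = FALSE, max_iter = max_iter,
                          check_duplicates = FALSE, verbose = FALSE)
      list(y = fit$Y, kl = utils::tail(fit$itercosts, 1))
    })
  })
  kls <- map_dbl(fits, "kl")
  best <- which.min(kls)
  cnp_embedding(fits[[best]]$y, "tsne",
                params = list(perplexity = perplexity,
                              learning_rate = learning_rate, seed = seed),
                diagnostics = list(kl = kls[best], kl_all = kls))
}

#' @export
tidy.cnp_embedding <- function(x, ...) {
  as_tibble(x$components) |>
    mutate(vertex = dplyr::row_number(), .before = 1) |>
    mutate(algorithm = x$algorithm)
}

#' @export
glance.cnp_embedding <- function(x, ...) {
  tibble(algorithm = x$algorithm,
         n = nrow(x$components),
         m = ncol(x$components),
         kl = x$diagnostics$kl %||% NA_real_)
}

#' Plot an embedding against itself or ground truth
#'
#' Scatter of the two embedding components, optionally coloured by a
#' ground-truth map to visualise gradient recovery.
#'
#' @param object A [cnp_embedding()].
#' @param colour Optional per-vertex vector (e.g. ground-truth eccentricity).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnp_embedding <- function(object, colour = NULL, ...) {
  d <- tidy(object)
  if (!is.null(colour)) d$truth <- colour
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$c1, y = .data$c2)) +
    ggplot2::labs(title = object$algorithm, x = "component 1", y = "component 2") +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$truth)) +
    ggplot2::scale_colour_viridis_c(name = "map value")
}
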