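path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  cnp_graph(a, "knn", FALSE, list(k = 1))
}

test_that("spectral embedding orders a path graph and rejects disconnection", {
  emb <- spectral_embed(path_graph(6))
  expect_true(all(diff(emb$components[, 1]) > 0) || all(diff(emb$components[, 1]) < 0))

  two_triangles <- matrix(0, 6, 6)
  two_triangles[1:3, 1:3] <- 1; two_triangles[4:6, 4:6] <- 1
  diag(two_triangles) <- 0
  expect_error(spectral_embed(cnp_graph(two_triangles, "knn", FALSE)),
               class = "cnp_disconnected_error")
})

test_that("spectral components solve the normalized Laplacian eigenproblem", {
  for (seed in 1:3) {
    x <- withr::with_seed(seed, matrix(rnorm(10 * 4), 10, 4))
    g <- knn_graph(x, 4, weighted = TRUE)
    emb <- spectral_embed(g)
    w <- g$affinity; d <- rowSums(w)
    lap <- diag(10) - diag(1 / sqrt(d)) %*% w %*% diag(1 / sqrt(d))
    vals <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
    # eigen equation holds for the returned components and eigenvalues
    # (components are the D^{-1/2}-rescaled eigenvectors)
    lam <- emb$diagnostics$eigenvalues[2:3]
    expect_equal(lam, vals[2:3], tolerance = 1e-8)
    for (j in 1:2) {
      v <- emb$components[, j] * sqrt(d)
      expect_lt(max(abs(lap %*% v - lam[j] * v)), 1e-8)
    }
    # the trivial constant mode (eigenvalue 0) is excluded
    expect_lt(abs(sum(emb$components[, 1] * d)), 1e-6)
  }
})

test_that("PCA recovers a planar configuration and decorrelates scores", {
  inp <- grid_embedding_input(8, 6, d = 10, seed = 11)
  emb <- pca_embed(inp$x)
  # noise-free planar input: scores recover the coordinates up to rotation
  coords <- cbind(rep(0:7, each = 6), rep(0:5, 8))
  expect_lt(procrustes_residual(emb$components, coords), 1e-10)
  expect_lt(abs(cov(emb$components[, 1], emb$components[, 2])), 1e-10)
  expect_error(pca_embed(outer(1:5, c(1, 1))), "rank")
})

test_that("ICA separates a two-source linear mixture", {
  s <- withr::with_seed(3, matrix(runif(500 * 2, -1, 1), 500, 2))
  a <- matrix(c(1, 0.6, -0.4, 1, 0.5, 0.3, 0.2, -0.7, 0.9, 0.1), 2, 5)
  emb <- ica_embed(s %*% a, seed = 4)
  cc <- abs(cor(emb$components, s))
  expect_gt(max(cc[1, ]), 0.99)
  expect_gt(max(cc[2, ]), 0.99)
  expect_equal(sort(apply(cc, 1, which.max)), 1:2, ignore_attr = TRUE)  # one source each
})

test_that("kernel PCA kernels match their closed forms", {
  km <- connectopy:::kernel_matrix(rbind(c(0, 0), c(1, 1)), "poly2")
  expect_equal(km[1, 1], 1)                    # (0 + 1)^2
  expect_equal(km[2, 2], 9)                    # (2 + 1)^2
  kr <- connectopy:::kernel_matrix(rbind(c(1, 2), c(1, 2), c(0, 0)), "rbf", gamma = 3)
  expect_equal(diag(kr), rep(1, 3))            # k(x, x) = 1 for any gamma
  expect_equal(kr[1, 3], exp(-3 * 5))
  expect_error(kpca_embed(diag(4), "cubic"), "must be one of")
})

test_that("kernel PCA agrees with the kernlab reference", {
  skip_if_not_installed("kernlab")
  x <- withr::with_seed(5, matrix(rnorm(30 * 4), 30, 4))
  ours <- kpca_embed(x, "rbf", gamma = 0.3)$components
  ref <- kernlab::rotated(kernlab::kpca(x, kernel = "rbfdot",
                                        kpar = list(sigma = 0.3), features = 2))
  expect_lt(procrustes_residual(ours, ref), 1e-8)
  ours2 <- kpca_embed(x, "poly2")$components
  ref2 <- kernlab::rotated(kernlab::kpca(x, kernel = "polydot",
                                         kpar = list(degree = 2, scale = 1, offset = 1),
                                         features = 2))
  expect_lt(procrustes_residual(ours2, ref2), 1e-8)
})

test_that("MLLE recovers a flat grid and is translation invariant", {
  inp <- grid_embedding_input(10, 8, d = 12, seed = 21)
  emb <- mlle_embed(inp$x, k = 10)
  expect_equal(dim(emb$components), c(80, 2))
  acc <- prediction_accuracy(emb, inp$truth)
  expect_true(all(acc$abs_r >= 0.9))
  shifted <- mlle_embed(inp$x + 5, k = 10)
  expect_lt(procrustes_residual(emb$components, shifted$components), 1e-6)
  expect_error(mlle_embed(inp$x, k = 2), "k > m")
})

test_that("LTSA recovers the coordinate plane up to rotation", {
  # LTSA solutions are defined only up to an affine map of the plane, so
  # recovery is scored rotation-invariantly: each grid axis must be nearly
  # a linear combination of the two components
  inp <- grid_embedding_input(10, 8, d = 12, seed = 21)
  emb <- ltsa_embed(inp$x, k = 10)
  expect_equal(dim(emb$components), c(80, 2))
  for (j in 1:2) {
    r2 <- summary(stats::lm(inp$truth[, j] ~ emb$components))$r.squared
    expect_gt(r2, 0.9)
  }
  # translation leaves the embedded plane unchanged (canonical correlations 1)
  shifted <- ltsa_embed(inp$x + 5, k = 10)
  expect_gt(min(stats::cancor(emb$components, shifted$components)$cor), 0.999)
  expect_error(ltsa_embed(inp$x, k = 2), "k > m")
})

test_that("Isomap reproduces orderings and reduces to MDS on complete graphs", {
  pts <- matrix(seq(0, 8, by = 2), ncol = 1)
  emb <- isomap_embed(cbind(pts, 0), k = 2)
  expect_equal(abs(cor(emb$components[, 1], pts[, 1], method = "spearman")), 1)

  x <- withr::with_seed(6, matrix(rnorm(9 * 3), 9, 3))
  emb_full <- isomap_embed(x, k = 8)           # single-hop: geodesic = Euclidean
  mds <- cmdscale(dist(x), k = 2)
  expect_lt(procrustes_residual(emb_full$components, mds), 1e-10)

  # disconnected neighbourhoods are an error
  far <- rbind(matrix(rnorm(8, sd = 0.01), 4, 2),
               matrix(rnorm(8, sd = 0.01), 4, 2) + 100)
  expect_error(isomap_embed(far, k = 2), class = "cnp_disconnected_error")
})

test_that("geodesic distances dominate Euclidean and match brute force", {
  x <- withr::with_seed(7, matrix(rnorm(8 * 2), 8, 2))
  d2 <- as.matrix(dist(x))^2
  adj <- matrix(0, 8, 8)
  for (i in 1:8) adj[i, order(d2[i, ])[-1][1:3]] <- 1
  adj <- pmax(adj, t(adj))
  w <- sqrt(d2)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(g)$weight <- w[as.matrix(igraph::as_edgelist(g, names = FALSE))]
  geo <- igraph::distances(g, algorithm = "dijkstra")
  expect_equal(geo, brute_force_geodesics(adj, w), ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(geo >= sqrt(d2) - 1e-12))
})

test_that("diffusion maps are a proper random walk and separate clusters", {
  x <- withr::with_seed(8, rbind(matrix(rnorm(20, sd = 0.3), 10, 2),
                                 matrix(rnorm(20, sd = 0.3), 10, 2) + 6,
                                 c(3, 3)))
  k <- 6; eps <- 4; alpha <- 0.5
  emb <- diffusion_embed(x, k = k, eps_diff = eps, alpha = alpha)
  # independent dense reconstruction of the transition matrix
  d2 <- as.matrix(dist(x))^2
  adj <- matrix(0, 21, 21)
  for (i in 1:21) adj[i, order(d2[i, ])[-1][1:k]] <- 1
  adj <- pmax(adj, t(adj))
  kern <- exp(-d2 / eps) * adj; diag(kern) <- 1
  q <- rowSums(kern)
  ka <- kern / outer(q^alpha, q^alpha)
  p <- ka / rowSums(ka)
  expect_equal(rowSums(p), rep(1, 21), tolerance = 1e-10, ignore_attr = TRUE)
  ep <- eigen(p)
  expect_equal(Re(ep$values[1]), 1, tolerance = 1e-10)
  expect_lt(diff(range(Re(ep$vectors[, 1]))), 1e-10)  # constant trivial eigenvector
  # first non-trivial eigenvector separates the blobs by sign
  c1 <- emb$components[, 1]
  expect_true(all(sign(c1[1:10]) == sign(c1[1])))
  expect_true(all(sign(c1[11:20]) == -sign(c1[1])))
  # and matches the dense eigendecomposition up to sign/scale
  v2 <- Re(ep$vectors[, 2])
  expect_gt(abs(cor(c1, v2)), 1 - 1e-8)
})

test_that("t-SNE keeps the best of five restarts and is deterministic", {
  inp <- grid_embedding_input(12, 10, d = 12, seed = 31)
  emb <- tsne_embed(inp$x, perplexity = 30, seed = 2, max_iter = 600)
  expect_equal(emb$diagnostics$kl, min(emb$diagnostics$kl_all))
  expect_length(emb$diagnostics$kl_all, 5)
  emb2 <- tsne_embed(inp$x, perplexity = 30, seed = 2, max_iter = 600)
  expect_identical(emb$components, emb2$components)
  acc <- prediction_accuracy(emb, inp$truth)
  expect_true(all(acc$abs_r >= 0.8))
  expect_error(tsne_embed(inp$x, perplexity = 200), "perplexity")
})

test_that("accuracy is invariant to component sign flips", {
  inp <- grid_embedding_input(8, 6, seed = 41)
  emb <- pca_embed(inp$x)
  acc <- prediction_accuracy(emb$components, inp$truth)
  flipped <- emb$components %*% diag(c(-1, 1))
  expect_equal(prediction_accuracy(flipped, inp$truth)$abs_r, acc$abs_r)
})
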