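# small fixtures and independent oracles shared across test files

# quick low-resolution simulation setup for unit tests
tiny_config <- function(seed = 1, ...) {
  sim_config(grid_shape = c(6, 5), timepoints_per_run = 60, n_runs = 2,
             n_nonroi_sources = 150, seed = seed, ...)
}

# noise-free "fingerprints": grid coordinates pushed through a random
# orthonormal linear map into d dimensions (recovery tests for embeddings)
grid_embedding_input <- function(n_ecc = 12, n_pol = 10, d = 12, seed = 42,
                                 curvature = 0) {
  grid <- make_retinotopic_grid(c(n_ecc, n_pol))
  coords <- cbind(grid$ecc_idx - 1, grid$pol_idx - 1)
  if (curvature > 0) {
    x <- coords[, 1] - mean(coords[, 1])
    coords <- cbind(sin(curvature * x) / curvature, coords[, 2],
                    (1 - cos(curvature * x)) / curvature)
  }
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(d * ncol(coords)), d)))[, seq_len(ncol(coords))]
    list(x = coords %*% t(q), grid = grid,
         truth = ground_truth_maps(grid))
  })
}

# orthogonal-Procrustes residual after centering and Frobenius normalisation;
# ~0 when a equals b up to rotation/reflection, translation and global scale
procrustes_residual <- function(a, b) {
  ac <- scale(a, center = TRUE, scale = FALSE)
  bc <- scale(b, center = TRUE, scale = FALSE)
  ac <- ac / sqrt(sum(ac^2))
  bc <- bc / sqrt(sum(bc^2))
  sv <- svd(crossprod(ac, bc))
  rot <- sv$u %*% t(sv$v)
  scale_opt <- sum(sv$d)
  sum((bc - scale_opt * ac %*% rot)^2)
}

# exhaustive shortest-path oracle: minimum weight over all simple paths
brute_force_geodesics <- function(adj, w) {
  n <- nrow(adj)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  recurse <- function(path, len, target) {
    i <- path[length(path)]
    if (i == target) {
      best[path[1], target] <<- min(best[path[1], target], len)
      return(invisible())
    }
    for (j in seq_len(n)) {
      if (adj[i, j] > 0 && !(j %in% path)) {
        recurse(c(path, j), len + w[i, j], target)
      }
    }
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) recurse(s, 0, t)
  }
  best[lower.tri(best)] <- t(best)[lower.tri(best)]
  best
}

# mean matched accuracy of the two maps for one algorithm on held-out data
fit_and_score <- function(alg, fp_train, fp_test, truth, seed,
                          budget = 25, n_random = 8) {
  opt <- crossval_optimize(alg, fp_train, truth, budget = budget,
                           n_random = n_random, seed = seed)
  prediction_accuracy(embed_algorithm(fp_test, alg, opt$params, seed = seed),
                      truth, algorithm = alg)
}
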