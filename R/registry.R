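# Algorithm registry: one place that knows, for every algorithm id, which
# free parameters it has (with search bounds derived from the data) and how
# to produce an embedding from a fingerprint matrix.

spectral_variants <- c("knn_unweighted", "knn_weighted",
                       "radius_unweighted", "radius_weighted", "full")

#' Algorithms available to the pipeline
#'
#' @return Character vector of algorithm identifiers accepted by
#'   [embed_algorithm()], [crossval_optimize()] and [run_subject()].
#'   Spectral embedding appears once per graph variant.
#' @export
list_algorithms <- function() {
  c(paste0("spectral_", spectral_variants),
    "pca", "ica", "kpca_poly", "kpca_rbf", "mlle", "ltsa",
    "isomap", "diffusion", "tsne")
}

# search-space definition for one parameter
param_def <- function(name, lower, upper, log = FALSE, integer = FALSE) {
  list(name = name, lower = lower, upper = upper, log = log, integer = integer)
}

# data-dependent search bounds, following the usual conventions: integer
# neighbourhood sizes log-spaced in [3, n/2]; radius between the 1st and 99th
# percentiles of the squared distances; kernel spreads log-uniform around the
# median squared distance; alpha on [0, 1]; perplexity in [5, n/4];
# learning rate in [10, 1000].
algorithm_params <- function(algorithm, x) {
  n <- nrow(x)
  k_def <- function() param_def("k", 3, max(4, floor(n / 2)), log = TRUE, integer = TRUE)
  med_d2 <- function() {
    d2 <- sq_dists(x)
    stats::median(d2[upper.tri(d2)])
  }
  switch(algorithm,
    pca = ,
    ica = ,
    kpca_poly = ,
    spectral_full = list(),
    kpca_rbf = {
      s <- med_d2()
      list(param_def("gamma", 1e-4 / s, 1e4 / s, log = TRUE))
    },
    spectral_knn_unweighted = ,
    spectral_knn_weighted = ,
    mlle = ,
    ltsa = ,
    isomap = list(k_def()),
    spectral_radius_unweighted = ,
    spectral_radius_weighted = {
      d2 <- sq_dists(x)
      qs <- quantile(d2[upper.tri(d2)], c(0.01, 0.99))
      list(param_def("eps_radius", qs[[1]], qs[[2]], log = TRUE))
    },
    diffusion = {
      s <- med_d2()
      list(k_def(),
           param_def("eps_diff", 1e-4 * s, 1e4 * s, log = TRUE),
           param_def("alpha", 0, 1))
    },
    tsne = list(param_def("perplexity", 5, max(6, floor(n / 4)), log = TRUE),
                param_def("learning_rate", 10, 1000, log = TRUE)),
    abort(sprintf("unknown algorithm '%s'", algorithm), class = "cnp_unknown_algorithm")
  )
}

#' Embed fingerprints with a named algorithm
#'
#' Uniform front-end over the embedding suite: dispatches on the algorithm
#' id, passing the supplied parameter values (as selected by
#' [crossval_optimize()], or defaults for parameter-free algorithms).
#'
#' @param x Fingerprint matrix (or [cnp_fingerprints()]).
#' @param algorithm One of [list_algorithms()].
#' @param params Named list of parameter values for the algorithm.
#' @param seed Seed for the stochastic algorithms (ICA, t-SNE).
#' @param m Number of components (default 2).
#' @return A [cnp_embedding()].
#' @export
embed_algorithm <- function(x, algorithm, params = list(), seed = 1, m = 2) {
  x <- as_matrix_input(x)
  switch(algorithm,
    pca = pca_embed(x, m),
    ica = ica_embed(x, m, seed = seed),
    kpca_poly = kpca_embed(x, "poly2", m = m),
    kpca_rbf = kpca_embed(x, "rbf", gamma = params$gamma, m = m),
    spectral_knn_unweighted = spectral_embed(knn_graph(x, params$k, weighted = FALSE), m),
    spectral_knn_weighted = spectral_embed(knn_graph(x, params$k, weighted = TRUE), m),
    spectral_radius_unweighted = spectral_embed(radius_graph(x, params$eps_radius, weighted = FALSE), m),
    spectral_radius_weighted = spectral_embed(radius_graph(x, params$eps_radius, weighted = TRUE), m),
    spectral_full = spectral_embed(full_graph(x), m),
    mlle = mlle_embed(x, params$k, m),
    ltsa = ltsa_embed(x, params$k, m),
    isomap = isomap_embed(x, params$k, m),
    diffusion = diffusion_embed(x, params$k, params$eps_diff, params$alpha, m),
    tsne = tsne_embed(x, params$perplexity, params$learning_rate, m, seed = seed),
    abort(sprintf("unknown algorithm '%s'", algorithm), class = "cnp_unknown_algorithm")
  )
}
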