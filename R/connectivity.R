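#' Lossless PCA compression of non-ROI timeseries
#'
#' When the number of non-ROI sources `M` exceeds the number of timepoints
#' `T`, the source data can be compressed without loss by treating the `T`
#' timepoints as observations in the `M`-dimensional feature space: after
#' mean-centering, at most `T - 1` principal components carry variance, so
#' retaining all `T - 1` explains 100% of it. The operation amounts to
#' rotating the samples within the feature space and dropping unused
#' dimensions; pairwise distances between timepoint-samples are preserved.
#'
#' @param source_ts A [cnp_timeseries()] (or bare matrix) of `M` source rows
#'   by `T` timepoints with `M > T`.
#' @return A [cnp_timeseries()] of `T - 1` component-score rows by `T`
#'   timepoints, with attribute `explained_variance` (fraction, = 1).
#' @export
lossless_pca <- function(source_ts) {
  offsets <- NULL
  if (inherits(source_ts, "cnp_timeseries")) {
    offsets <- source_ts$run_offsets
    x <- source_ts$data
  } else {
    x <- check_matrix(source_ts, "source_ts")
  }
  m <- nrow(x); tt <- ncol(x)
  if (m <= tt) {
    abort(paste0("lossless PCA expects more sources than timepoints (M > T); ",
                 "got M = ", m, ", T = ", tt,
                 ". Omit the PCA stage (within-ROI path) instead."),
          class = "cnp_pca_rank_error")
  }
  # observations = timepoints (columns of x); center each feature over time
  obs <- t(x - rowMeans(x))
  sv <- svd(obs)
  comp <- t(obs %*% sv$v[, seq_len(tt - 1L), drop = FALSE])
  total <- sum(sv$d^2)
  ev <- if (total > 0) sum(sv$d[seq_len(tt - 1L)]^2) / total else 1
  out <- cnp_timeseries(comp, offsets %||% c(0L, tt))
  attr(out, "explained_variance") <- ev
  out
}

#' Connectivity fingerprint container
#'
#' An `N_roi x D` matrix of Fisher-z transformed correlations between ROI
#' vertex timeseries and reference timeseries, tagged with its provenance.
#'
#' @param values Numeric matrix of Fisher-z correlations.
#' @param source_mode One of `"all"`, `"cortex"`, `"subcortex"`, `"noise"`,
#'   `"within_roi"`.
#' @param pca_applied Logical; were the reference rows PCA component scores?
#' @param split_id Optional label for the data split (e.g. `"odd"`).
#' @return A matrix of class `cnp_fingerprints`.
#' @export
cnp_fingerprints <- function(values, source_mode, pca_applied, split_id = NA_character_) {
  values <- check_matrix(values, "values")
  structure(values, class = c("cnp_fingerprints", "matrix", "array"),
            source_mode = source_mode, pca_applied = isTRUE(pca_applied),
            split_id = split_id)
}

#' @export
print.cnp_fingerprints <- function(x, ...) {
  cat(sprintf("<cnp_fingerprints> %d vertices x %d dims (source = %s, pca = %s, split = %s)\n",
              nrow(x), ncol(x), attr(x, "source_mode"),
              attr(x, "pca_applied"), attr(x, "split_id")))
  invisible(x)
}

# Pearson correlation of every row of `a` with every row of `b`, then
# Fisher z. |r| is clipped at 1 - 1e-7 first so accidental duplicates stay
# finite (the same protection the within-ROI diagonal gets by construction).
fisher_cor <- function(a, b, fisher = TRUE) {
  va <- apply(a, 1, sd); vb <- apply(b, 1, sd)
  if (any(va == 0)) abort(sprintf("ROI row %d has zero variance", which(va == 0)[1]))
  if (any(vb == 0)) abort(sprintf("source row %d has zero variance", which(vb == 0)[1]))
  r <- cor(t(a), t(b))
  if (!fisher) return(r)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  atanh(r)
}

#' Correlate ROI timeseries with reference timeseries
#'
#' Builds the connectivity space: the Pearson correlation of every ROI vertex
#' timeseries with every reference row, Fisher z-transformed
#' (`z = atanh(r)` after clipping `|r| <= 1 - 1e-7`).
#'
#' @param roi_ts ROI [cnp_timeseries()] (or matrix), `N x T`, `N >= 3`.
#' @param source_ts Reference [cnp_timeseries()] (or matrix), `D x T`.
#' @param fisher Apply the Fisher transform (default `TRUE`).
#' @param source_mode,pca_applied,split_id Provenance tags stored on the result.
#' @return A [cnp_fingerprints()] matrix, `N x D`.
#' @export
compute_fingerprints <- function(roi_ts, source_ts, fisher = TRUE,
                                 source_mode = "all", pca_applied = FALSE,
                                 split_id = NA_character_) {
  a <- if (inherits(roi_ts, "cnp_timeseries")) roi_ts$data else check_matrix(roi_ts, "roi_ts")
  b <- if (inherits(source_ts, "cnp_timeseries")) source_ts$data else check_matrix(source_ts, "source_ts")
  if (ncol(a) != ncol(b)) abort("ROI and source timeseries must share the same timepoints")
  if (nrow(a) < 3) abort("need at least 3 ROI vertices")
  cnp_fingerprints(fisher_cor(a, b, fisher), source_mode, pca_applied, split_id)
}

#' Within-ROI connectivity fingerprints
#'
#' Correlates ROI vertices among themselves, disregarding non-ROI data
#' entirely. Without PCA the result is the `N x N` Fisher-z correlation
#' matrix with the diagonal set exactly to zero (a vertex is trivially
#' connected to itself and the perfect correlation would invalidate the
#' Fisher transform). With PCA, the ROI rows are instead correlated with
#' principal components derived from those same timeseries, retaining
#' `min(N, T) - 1` components.
#'
#' @param roi_ts ROI [cnp_timeseries()] (or matrix), `N x T`, `N >= 3`.
#' @param apply_pca Correlate with the ROI's own principal components
#'   instead of the raw vertex rows.
#' @param split_id Provenance tag.
#' @return A [cnp_fingerprints()] matrix (`N x N`, or `N x (min(N, T) - 1)`
#'   when `apply_pca = TRUE`).
#' @export
within_roi_fingerprints <- function(roi_ts, apply_pca = FALSE,
                                    split_id = NA_character_) {
  a <- if (inherits(roi_ts, "cnp_timeseries")) roi_ts$data else check_matrix(roi_ts, "roi_ts")
  n <- nrow(a); tt <- ncol(a)
  if (n < 3) abort("need at least 3 ROI vertices")
  if (!apply_pca) {
    z <- fisher_cor(a, a)
    diag(z) <- 0
    return(cnp_fingerprints(z, "within_roi", FALSE, split_id))
  }
  # component scores of the ROI's own timepoint-samples
  obs <- t(a - rowMeans(a))                 # T x N
  d <- min(n, tt) - 1L
  v <- svd(obs, nu = 0)$v[, seq_len(d), drop = FALSE]
  comp <- t(obs %*% v)                      # d x T
  cnp_fingerprints(fisher_cor(a, comp), "within_roi", TRUE, split_id)
}

#' Build fingerprints for one connectivity-source variant
#'
#' Dispatches the five connectivity sources used to probe where the mapping
#' signal comes from: `all` stacks cortex + subcortex rows, compresses them
#' with [lossless_pca()], and correlates; `cortex` / `subcortex` use one
#' block only; `noise` replaces the stacked rows with moment-matched Gaussian
#' noise ([noise_substitute()]) before the same PCA + correlation path;
#' `within_roi` ignores the sources entirely ([within_roi_fingerprints()]).
#'
#' @param roi_ts ROI [cnp_timeseries()].
#' @param sources Named list with [cnp_timeseries()] elements `cortex` and/or
#'   `subcortex` (as required by `mode`).
#' @param mode Connectivity source, one of `"all"`, `"cortex"`,
#'   `"subcortex"`, `"noise"`, `"within_roi"`.
#' @param seed Seed for the noise substitution (mode `"noise"`).
#' @param within_roi_pca Apply PCA on the within-ROI path (default `FALSE`,
#'   the standard within-ROI analysis).
#' @param split_id Provenance tag.
#' @return A [cnp_fingerprints()] matrix.
#' @export
build_connectivity <- function(roi_ts, sources = list(),
                               mode = c("all", "cortex", "subcortex", "noise", "within_roi"),
                               seed = 1, within_roi_pca = FALSE,
                               split_id = NA_character_) {
  mode <- rlang::arg_match(mode)
  if (mode == "within_roi") {
    return(within_roi_fingerprints(roi_ts, apply_pca = within_roi_pca,
                                   split_id = split_id))
  }
  need <- switch(mode, all = c("cortex", "subcortex"), noise = c("cortex", "subcortex"),
                 cortex = "cortex", subcortex = "subcortex")
  missing <- setdiff(need, names(sources))
  if (length(missing)) {
    abort(sprintf("mode '%s' requires source block(s): %s", mode,
                  paste(missing, collapse = ", ")))
  }
  stack <- function(blocks) {
    mats <- lapply(blocks, function(b) if (inherits(b, "cnp_timeseries")) b$data else b)
    offs <- sources[[need[1]]]
    offs <- if (inherits(offs, "cnp_timeseries")) offs$run_offsets else c(0L, ncol(mats[[1]]))
    cnp_timeseries(do.call(rbind, mats), offs)
  }
  stacked <- stack(sources[need])
  if (mode == "noise") stacked <- noise_substitute(stacked, seed)
  comp <- lossless_pca(stacked)
  compute_fingerprints(roi_ts, comp, source_mode = mode, pca_applied = TRUE,
                       split_id = split_id)
}

#' @export
tidy.cnp_fingerprints <- function(x, ...) {
  tibble(vertex = rep(seq_len(nrow(x)), ncol(x)),
         dim = rep(seq_len(ncol(x)), each = nrow(x)),
         z = as.vector(unclass(x)))
}
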