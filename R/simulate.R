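#' Simulation configuration
#'
#' Collects the parameters of the synthetic-data generator. The generator
#' emulates the statistical structure the connectopic-mapping pipeline
#' assumes: an ROI whose vertices carry a smooth 2-D topographic coordinate,
#' timeseries whose pairwise correlation decays with topographic distance,
#' non-ROI sources that are mixtures of the same latent signals, and
#' additive measurement noise.
#'
#' @param grid_shape `c(n_ecc, n_pol)` vertices along the two map axes.
#' @param timepoints_per_run Timepoints per scan run (>= 4).
#' @param n_runs Number of scan runs; must be even and >= 2 so the recording
#'   can be partitioned into odd and even runs.
#' @param correlation_length Spatial scale `l` (grid units) of the Gaussian
#'   mixing profile `a(v, s) = exp(-d(v, s)^2 / (2 l^2))`; larger values give
#'   smoother, longer-range correlation structure.
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian noise on
#'   each ROI vertex, in latent-signal units (>= 0).
#' @param n_nonroi_sources Number of cortex-like non-ROI source timeseries.
#' @param manifold_curvature Bend (radians per grid unit) applied to the
#'   latent coordinate sheet before distances are computed. 0 leaves the
#'   sheet flat; positive values roll it onto a cylinder so that ambient
#'   chord geometry folds while intrinsic geodesic geometry is preserved —
#'   the regime in which non-linear manifold learners hold an advantage over
#'   linear embeddings.
#' @param seed Integer master seed; all generator randomness derives from it.
#' @return A list of class `cnp_sim_config`.
#' @export
sim_config <- function(grid_shape = c(12, 10), timepoints_per_run = 300,
                       n_runs = 4, correlation_length = 1.5, noise_sd = 0.5,
                       n_nonroi_sources = 1300, manifold_curvature = 0,
                       seed = 1) {
  timepoints_per_run <- as.integer(timepoints_per_run)
  n_runs <- as.integer(n_runs)
  if (timepoints_per_run < 4) abort("`timepoints_per_run` must be >= 4")
  if (n_runs < 2 || n_runs %% 2 != 0) abort("`n_runs` must be even and >= 2")
  assert_scalar_number(correlation_length, "correlation_length", lower = 1e-12)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(manifold_curvature, "manifold_curvature", lower = 0)
  if (n_nonroi_sources < 1) abort("`n_nonroi_sources` must be >= 1")
  structure(list(
    grid_shape = as.integer(grid_shape),
    timepoints_per_run = timepoints_per_run,
    n_runs = n_runs,
    correlation_length = correlation_length,
    noise_sd = noise_sd,
    n_nonroi_sources = as.integer(n_nonroi_sources),
    manifold_curvature = manifold_curvature,
    seed = as.integer(seed)
  ), class = "cnp_sim_config")
}

run_offsets_for <- function(config) {
  as.integer(seq(0, config$n_runs * config$timepoints_per_run,
                 by = config$timepoints_per_run))
}

#' Latent source signals on the grid
#'
#' One i.i.d. standard-normal latent source per grid node, drawn
#' independently within each run. ROI vertices and (cortex/subcortex)
#' non-ROI sources are both mixtures of these signals, which is what ties
#' their correlation structure to the grid topography.
#'
#' @param grid A [make_retinotopic_grid()] result.
#' @param config A [sim_config()].
#' @return A [cnp_timeseries()] with one row per grid node.
#' @export
simulate_latents <- function(grid, config) {
  s <- nrow(grid)
  t_total <- config$n_runs * config$timepoints_per_run
  z <- with_seed_(child_seed(config$seed, 1),
                  matrix(rnorm(s * t_total), s, t_total))
  cnp_timeseries(z, run_offsets_for(config))
}

# add a baseline so percent signal change is defined, then normalise per run
finalize_bold <- function(signal, offsets, baseline = 100) {
  percent_signal_change(cnp_timeseries(signal + baseline, offsets))
}

#' Simulate ROI timeseries with a known 2-D topography
#'
#' Vertex `v` receives `sum_s a(v, s) z_s(t) + noise_sd * eta_v(t)` where the
#' latent sources `z_s` sit at the grid nodes, the mixing weight
#' `a(v, s) = exp(-d(v, s)^2 / (2 l^2))` decays with (optionally
#' curvature-warped) grid distance `d`, and `eta` is i.i.d. standard normal.
#' A baseline of 100 raw units is added and each row is converted to percent
#' signal change run by run. Expected pairwise correlation therefore
#' decreases monotonically with topographic distance.
#'
#' @inheritParams simulate_latents
#' @param latents Optional pre-generated [simulate_latents()] output (reused
#'   so non-ROI sources can mix the very same signals).
#' @return A [cnp_timeseries()], one row per grid vertex.
#' @export
simulate_roi_timeseries <- function(grid, config, latents = NULL) {
  stopifnot(inherits(grid, "cnp_grid"), inherits(config, "cnp_sim_config"))
  if (config$noise_sd < 0) abort("`noise_sd` must be >= 0")
  latents <- latents %||% simulate_latents(grid, config)
  coords <- warp_coords(grid_coords(grid), config$manifold_curvature)
  d2 <- sq_dists(coords)
  a <- exp(-d2 / (2 * config$correlation_length^2))
  signal <- a %*% latents$data
  noise <- with_seed_(child_seed(config$seed, 2),
                      matrix(rnorm(length(signal)), nrow(signal), ncol(signal)))
  finalize_bold(signal + config$noise_sd * noise, latents$run_offsets)
}

#' Simulate non-ROI source timeseries
#'
#' Generates the "rest of the brain": timeseries outside the ROI that feed
#' the connectivity fingerprints. `cortex` rows are dense random mixtures of
#' all latent sources; `subcortex` rows each mix only a few randomly chosen
#' latents (and there are half as many of them by default, mirroring the
#' roughly 2:1 cortical/subcortical split of whole-brain grayordinates);
#' `unrelated` rows are pure noise, sharing nothing with the ROI.
#'
#' @param roi_latents The [simulate_latents()] output used for the ROI.
#' @param config A [sim_config()].
#' @param mode One of `"cortex"`, `"subcortex"`, `"unrelated"`.
#' @param m Number of rows to generate; defaults to `n_nonroi_sources` for
#'   cortex and unrelated, and half of that for subcortex.
#' @return A [cnp_timeseries()] with `m` rows.
#' @export
simulate_nonroi_timeseries <- function(roi_latents, config,
                                       mode = c("cortex", "subcortex", "unrelated"),
                                       m = NULL) {
  mode <- rlang::arg_match(mode)
  stopifnot(inherits(roi_latents, "cnp_timeseries"), inherits(config, "cnp_sim_config"))
  s <- nrow(roi_latents$data)
  t_total <- ncol(roi_latents$data)
  m <- as.integer(m %||% switch(mode,
    cortex = config$n_nonroi_sources,
    subcortex = max(1L, as.integer(round(config$n_nonroi_sources / 2))),
    unrelated = config$n_nonroi_sources))
  if (m < 1) abort("`m` must be >= 1")
  stream <- switch(mode, cortex = 3, subcortex = 4, unrelated = 5)
  signal <- with_seed_(child_seed(config$seed, stream), {
    if (mode == "unrelated") {
      matrix(rnorm(m * t_total), m, t_total)
    } else {
      b <- if (mode == "cortex") {
        matrix(rnorm(m * s), m, s)
      } else {
        # each subcortical row taps a small subset of the latent pool
        n_mix <- min(5L, s)
        w <- matrix(0, m, s)
        for (i in seq_len(m)) {
          w[i, sample.int(s, n_mix)] <- rnorm(n_mix)
        }
        w
      }
      mixed <- b %*% roi_latents$data
      noise <- matrix(rnorm(m * t_total), m, t_total)
      # scale noise to the typical row amplitude so noise_sd keeps its meaning
      mixed + config$noise_sd * noise * mean(sqrt(rowSums(b^2)))
    }
  })
  finalize_bold(signal, roi_latents$run_offsets)
}

#' Generate a full synthetic subject
#'
#' Convenience wrapper producing everything one simulated subject needs:
#' grid (with ground-truth maps), ROI timeseries, and cortex + subcortex
#' non-ROI sources, all from one seed.
#'
#' @param config A [sim_config()].
#' @param ecc_range,polar_range Passed to [make_retinotopic_grid()].
#' @return A list with elements `grid`, `truth` (n x 2 matrix), `roi`,
#'   `cortex`, `subcortex`, `config`.
#' @export
simulate_subject <- function(config = sim_config(), ecc_range = c(1, 8),
                             polar_range = c(0, pi)) {
  grid <- make_retinotopic_grid(config$grid_shape, ecc_range, polar_range)
  latents <- simulate_latents(grid, config)
  list(
    grid = grid,
    truth = ground_truth_maps(grid),
    roi = simulate_roi_timeseries(grid, config, latents),
    cortex = simulate_nonroi_timeseries(latents, config, "cortex"),
    subcortex = simulate_nonroi_timeseries(latents, config, "subcortex"),
    config = config
  )
}
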