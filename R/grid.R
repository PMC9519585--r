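#' Build a rectangular retinotopic grid with ground-truth map values
#'
#' Lays out an ROI as a regular `n_ecc x n_pol` grid of vertices, each
#' carrying an eccentricity (degrees of visual angle, increasing along the
#' first grid axis) and a polar angle (radians, increasing along the second
#' axis). These two per-vertex scalars are the ground-truth maps that
#' connectopic reconstructions are benchmarked against. The polar range
#' defaults to one hemifield, `[0, pi]`, since a single-hemisphere V1 ROI
#' covers one hemifield and this avoids a circular wrap inside the ROI.
#'
#' @param grid_shape Integer vector `c(n_ecc, n_pol)`, both at least 2.
#' @param ecc_range Length-2 numeric, eccentricity at the first and last grid
#'   row (degrees, > 0).
#' @param polar_range Length-2 numeric, polar angle at the first and last
#'   grid column (radians).
#' @return A tibble of class `cnp_grid` with columns `vertex`, `ecc_idx`,
#'   `pol_idx`, `ecc`, `polar`; attributes `grid_shape`, `ecc_range`,
#'   `polar_range`.
#' @export
#' @examples
#' g <- make_retinotopic_grid(c(3, 2), ecc_range = c(1, 8))
#' unique(g$ecc)   # 1, 4.5, 8
make_retinotopic_grid <- function(grid_shape, ecc_range = c(1, 8),
                                  polar_range = c(0, pi)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2 || any(grid_shape < 2)) {
    abort("`grid_shape` must be two integers, each >= 2")
  }
  for (rg in list(ecc_range = ecc_range, polar_range = polar_range)) {
    if (length(rg) != 2 || !all(is.finite(rg)) || rg[1] == rg[2]) {
      abort("coordinate ranges must be two distinct finite values")
    }
  }
  if (any(ecc_range <= 0)) abort("`ecc_range` must be positive (degrees of visual angle)")
  n_ecc <- grid_shape[1]; n_pol <- grid_shape[2]
  ecc_vals <- seq(ecc_range[1], ecc_range[2], length.out = n_ecc)
  pol_vals <- seq(polar_range[1], polar_range[2], length.out = n_pol)
  g <- tidyr::expand_grid(ecc_idx = seq_len(n_ecc), pol_idx = seq_len(n_pol)) |>
    mutate(vertex = dplyr::row_number(),
           ecc = ecc_vals[.data$ecc_idx],
           polar = pol_vals[.data$pol_idx]) |>
    select("vertex", "ecc_idx", "pol_idx", "ecc", "polar")
  structure(g, class = c("cnp_grid", class(g)),
            grid_shape = grid_shape, ecc_range = ecc_range,
            polar_range = polar_range)
}

#' Extract the ground-truth map matrix from a grid
#'
#' @param grid A [make_retinotopic_grid()] result.
#' @return An `n x 2` matrix with columns `ecc` and `polar`.
#' @export
ground_truth_maps <- function(grid) {
  stopifnot(inherits(grid, "cnp_grid"))
  cbind(ecc = grid$ecc, polar = grid$polar)
}

# grid-index coordinates (unit spacing along each axis), n x 2
grid_coords <- function(grid) {
  cbind(grid$ecc_idx - 1, grid$pol_idx - 1)
}

# Embed the flat index-coordinate sheet on a cylinder bent along the first
# (eccentricity) axis. `curvature` is the bend in radians per grid unit; the
# map is an isometry of the sheet (arc length preserved), so intrinsic
# geodesic distances are unchanged while ambient chord distances contract —
# exactly the regime where linear embeddings fold and manifold learners do not.
warp_coords <- function(coords, curvature) {
  if (curvature <= 0) return(cbind(coords, 0))
  x <- coords[, 1] - mean(coords[, 1])
  cbind(sin(curvature * x) / curvature,
        coords[, 2],
        (1 - cos(curvature * x)) / curvature)
}
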