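#' Cone-beam projection stack
#'
#' A stack of 2D line-integral frames (dimensionless), one per gantry angle,
#' with the angle/timestamp schedule and the source intensity `n0` (photons
#' per detector element) used to convert between line integrals and photon
#' counts.
#'
#' @param frames numeric array `det_rows x det_cols x n_views`, finite and
#'   >= 0.
#' @param angles_deg,times_s per-view gantry angles (degrees) and timestamps
#'   (seconds).
#' @param n0 photons per detector element emitted by the source.
#' @return A `projection_set`.
#' @export
projection_set <- function(frames, angles_deg, times_s, n0 = 1e5) {
  if (length(dim(frames)) != 3) stop("frames must be a 3D array")
  if (dim(frames)[3] < 1) stop("frame count must match angles: empty stack")
  if (dim(frames)[3] != length(angles_deg) ||
      length(angles_deg) != length(times_s))
    stop("frame count must match angles and timestamps")
  if (any(!is.finite(frames))) stop("line integrals must be finite")
  if (min(frames) < 0) stop("line integrals must be >= 0")
  if (n0 <= 0) stop("n0 must be > 0")
  structure(list(frames = frames, angles_deg = as.numeric(angles_deg),
                 times_s = as.numeric(times_s), n0 = n0),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("projection_set: %d frames of %dx%d (M = %d elements), n0 = %g\n",
              d[3], d[1], d[2], prod(d), x$n0))
  invisible(x)
}

#' Number of projection elements
#'
#' Total element count M = detector elements x number of views.
#' @param projections a [projection_set()].
#' @return integer count.
#' @export
element_count <- function(projections) prod(dim(projections$frames))

check_frames_match <- function(projections, geometry) {
  d <- dim(projections$frames)
  if (d[1] != geometry$det_rows || d[2] != geometry$det_cols)
    stop("frame shape does not match scan geometry")
}

#' Ray-driven cone-beam forward projection
#'
#' Computes line integrals y = A mu: for every detector cell, the sum of
#' voxel values times the exact intersection lengths of the single ray from
#' the source to the cell center (Siddon traversal). Noiseless and
#' deterministic; rays that exit the grid integrate only over intersected
#' voxels.
#'
#' @param volume a [volume_image()] of attenuation coefficients (1/mm).
#' @param geometry a [make_geometry()] scan description.
#' @param angle_subset optional integer indices of views to project.
#' @param n0 source intensity recorded in the returned set.
#' @return A [projection_set()] holding one frame per requested view.
#' @export
forward_project <- function(volume, geometry, angle_subset = NULL, n0 = 1e5) {
  b <- detector_basis(geometry, angle_subset)
  raw <- cpp_siddon_forward(as_dbl(volume$values), dim(volume$values),
                            volume$voxel_size, volume$origin,
                            b$src, b$det0, b$eu, b$ev,
                            geometry$det_rows, geometry$det_cols)
  frames <- array(raw, c(geometry$det_rows, geometry$det_cols, length(b$view_idx)))
  projection_set(frames, geometry$angles_deg[b$view_idx],
                 geometry$times_s[b$view_idx], n0)
}

#' Exact adjoint of the forward projector
#'
#' Backprojects a projection stack onto a voxel grid: the transpose of the
#' system matrix A under the standard inner products (each traversed voxel
#' accumulates detector value x intersection length). This is the adjoint
#' used by the iterative solver, not a filtered backprojection.
#'
#' @param projections a [projection_set()].
#' @param geometry the matching [make_geometry()].
#' @param grid a `volume_image` template defining the output grid.
#' @param angle_subset optional view indices of `geometry` matching
#'   `projections` (defaults to matching by angle).
#' @return A `volume_image` (values may be any sign if input is).
#' @export
back_project <- function(projections, geometry, grid, angle_subset = NULL) {
  check_frames_match(projections, geometry)
  idx <- angle_subset %||% match_views(projections, geometry)
  if (length(idx) != dim(projections$frames)[3])
    stop("view count mismatch between projections and geometry")
  b <- detector_basis(geometry, idx)
  raw <- cpp_siddon_back(as_dbl(projections$frames), dim(grid$values),
                         grid$voxel_size, grid$origin,
                         b$src, b$det0, b$eu, b$ev,
                         geometry$det_rows, geometry$det_cols)
  out <- grid
  out$values <- array(raw, dim(grid$values))
  out
}

match_views <- function(projections, geometry) {
  idx <- match(round(projections$angles_deg, 6), round(geometry$angles_deg, 6))
  if (any(is.na(idx)))
    stop("projection angles not found in geometry")
  idx
}

#' Photon counts from line integrals
#'
#' Applies the count model n = n0 exp(-y). In noisy mode, draws Poisson
#' counts with that mean, reproducibly for a fixed seed.
#'
#' @param y a [projection_set()] of line integrals, or a numeric array.
#' @param n0 photons per element; defaults to the set's own `n0`.
#' @param noisy draw Poisson counts instead of returning the means.
#' @param seed integer seed for the noisy draw.
#' @return Numeric array of counts, same shape as the frames.
#' @export
counts_from_line_integrals <- function(y, n0 = NULL, noisy = FALSE, seed = 1L) {
  vals <- if (inherits(y, "projection_set")) {
    n0 <- n0 %||% y$n0
    y$frames
  } else {
    if (is.null(n0)) stop("n0 required for a bare array")
    y
  }
  if (n0 <= 0) stop("n0 must be > 0")
  if (min(vals) < 0) stop("negative line integrals")
  mean_counts <- n0 * exp(-vals)
  if (!noisy) return(mean_counts)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  array(rpois(length(mean_counts), mean_counts), dim(mean_counts))
}
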