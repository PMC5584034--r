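#' Simulate a cone-beam scan of the moving phantom
#'
#' Creates noiseless line-integral projections of the time-dependent
#' phantom: every view is projected with the phantom frozen at that view's
#' timestamp. By default the projection is decomposed into the static-body
#' projection (computed once for all views) plus the projection of the
#' sphere-difference sub-volume on the same voxel lattice, which is exact
#' for the center-sampled voxelization by linearity of the line integral;
#' `decompose = FALSE` voxelizes and projects the full phantom per view.
#'
#' @param geometry a [make_geometry()].
#' @param spec a [phantom_spec()].
#' @param n0 source photons per element recorded in the set.
#' @param decompose use the exact body + sphere-difference decomposition.
#' @param body_frames optional precomputed static-body projection frames
#'   (from a previous call's attribute `body_frames`), reused across speeds
#'   since the body does not move.
#' @return A [projection_set()] of line integrals, with the static-body
#'   frames attached as attribute `body_frames`.
#' @export
simulate_phantom_scan <- function(geometry, spec, n0 = 1e5, decompose = TRUE,
                                  body_frames = NULL) {
  grid <- volume_template(spec$grid_dims, spec$voxel_size)
  nv <- length(geometry$angles_deg)
  if (!decompose) {
    frames <- array(0, c(geometry$det_rows, geometry$det_cols, nv))
    for (k in seq_len(nv)) {
      ph <- phantom_volume(spec, geometry$times_s[k], grid)
      frames[, , k] <- forward_project(ph, geometry, k, n0)$frames[, , 1]
    }
    return(projection_set(frames, geometry$angles_deg, geometry$times_s, n0))
  }
  if (is.null(body_frames)) {
    body <- phantom_volume(spec, 0, grid, include_sphere = FALSE)
    body_frames <- forward_project(body, geometry, n0 = n0)$frames
  }
  frames <- body_frames
  r <- spec$sphere_diameter / 2
  vz <- grid$voxel_size
  for (k in seq_len(nv)) {
    zc <- sphere_center_z(spec, geometry$times_s[k])
    # sub-grid aligned with the main lattice, covering the sphere
    lo <- floor((c(-r, -r, zc - r) - grid$origin) / vz) - 1
    hi <- ceiling((c(r, r, zc + r) - grid$origin) / vz) + 1
    lo <- pmax(lo, 0); hi <- pmin(hi, dim(grid$values))
    dims <- as.integer(hi - lo)
    sub <- volume_image(array(0, dims), vz, grid$origin + lo * vz)
    x <- grid_axis(sub, 1); y <- grid_axis(sub, 2); z <- grid_axis(sub, 3)
    e2 <- outer((x / spec$ellipse_semi_axis_x)^2,
                (y / spec$ellipse_semi_axis_y)^2, `+`)
    for (kk in seq_len(dims[3])) {
      dz2 <- (z[kk] - zc)^2
      if (dz2 >= r^2) next
      inside <- (outer(x^2, y^2, `+`) <= r^2 - dz2) & (e2 <= 1)
      sl <- sub$values[, , kk]
      sl[inside] <- spec$sphere_mu - spec$body_mu
      sub$values[, , kk] <- sl
    }
    b <- detector_basis(geometry, k)
    raw <- cpp_siddon_forward(as_dbl(sub$values), dims, vz, sub$origin,
                              b$src, b$det0, b$eu, b$ev,
                              geometry$det_rows, geometry$det_cols)
    frames[, , k] <- frames[, , k] + array(raw, c(geometry$det_rows,
                                                  geometry$det_cols))
  }
  frames[frames < 0] <- 0   # guard tiny negative round-off
  out <- projection_set(frames, geometry$angles_deg, geometry$times_s, n0)
  attr(out, "body_frames") <- body_frames
  out
}
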