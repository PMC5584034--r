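#' Moving-sphere digital phantom description
#'
#' An elliptic cylinder of uniform attenuation aligned with the rotation
#' axis, containing a spherical cavity (air by default) that translates
#' along the axis at constant speed between `motion_start_time` and
#' `motion_end_time`, centered on the axis midpoint. Defaults reproduce the
#' study phantom: a 3 cm air sphere moving 3 cm along z inside a
#' 220 x 160 mm elliptic cylinder of 0.02/mm.
#'
#' @param ellipse_semi_axis_x,ellipse_semi_axis_y transaxial semi-axes (mm).
#' @param cylinder_length cylinder extent along z (mm); `Inf` spans the grid.
#' @param body_mu body attenuation (1/mm).
#' @param sphere_diameter moving sphere diameter (mm).
#' @param sphere_mu sphere attenuation (1/mm), 0 = air.
#' @param motion_extent total travel along z (mm).
#' @param motion_start_time,motion_end_time motion interval (s); before/after,
#'   the sphere rests at the start/end position.
#' @param voxel_size reconstruction/phantom voxel size (mm, length 1 or 3).
#' @param grid_dims phantom grid size (length 3).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(ellipse_semi_axis_x = 110, ellipse_semi_axis_y = 80,
                         cylinder_length = Inf, body_mu = 0.02,
                         sphere_diameter = 30, sphere_mu = 0,
                         motion_extent = 30,
                         motion_start_time = 0, motion_end_time = 60,
                         voxel_size = 1, grid_dims = c(256, 256, 60)) {
  r <- sphere_diameter / 2
  if (sphere_mu < 0) stop("configuration error: sphere_mu must be >= 0")
  if (body_mu <= sphere_mu)
    stop("configuration error: body_mu must exceed sphere_mu")
  if (motion_end_time <= motion_start_time)
    stop("configuration error: motion_end_time must exceed motion_start_time")
  if (r > min(ellipse_semi_axis_x, ellipse_semi_axis_y))
    stop("configuration error: sphere outside cylinder (transaxial)")
  if (is.finite(cylinder_length) && motion_extent + sphere_diameter > cylinder_length)
    stop("configuration error: sphere outside cylinder (axial)")
  structure(list(
    ellipse_semi_axis_x = ellipse_semi_axis_x,
    ellipse_semi_axis_y = ellipse_semi_axis_y,
    cylinder_length = cylinder_length, body_mu = body_mu,
    sphere_diameter = sphere_diameter, sphere_mu = sphere_mu,
    motion_extent = motion_extent,
    motion_start_time = motion_start_time,
    motion_end_time = motion_end_time,
    voxel_size = rep(as.numeric(voxel_size), length.out = 3),
    grid_dims = as.integer(rep(grid_dims, length.out = 3))
  ), class = "phantom_spec")
}

#' Sphere center position along z at a given time
#'
#' Linear interpolation between -extent/2 and +extent/2 over the motion
#' interval, clamped at both ends.
#'
#' @param spec a [phantom_spec()].
#' @param time time in seconds.
#' @return z position of the sphere center (mm).
#' @export
sphere_center_z <- function(spec, time) {
  f <- (time - spec$motion_start_time) /
    (spec$motion_end_time - spec$motion_start_time)
  f <- pmin(1, pmax(0, f))
  (f - 0.5) * spec$motion_extent
}

#' Voxelize the phantom at a given time
#'
#' Center-sampled voxelization: a voxel takes the sphere value when its
#' center lies inside the sphere, the body value when inside the elliptic
#' cylinder, 0 outside.
#'
#' @param spec a [phantom_spec()].
#' @param time acquisition time (s); the sphere position is clamped outside
#'   the motion interval.
#' @param template optional `volume_image` defining the grid (defaults to the
#'   spec's own centered grid).
#' @param include_sphere set `FALSE` to voxelize the static body only.
#' @return A `volume_image`.
#' @export
phantom_volume <- function(spec, time, template = NULL, include_sphere = TRUE) {
  vol <- template %||% volume_template(spec$grid_dims, spec$voxel_size)
  d <- dim(vol$values)
  x <- grid_axis(vol, 1); y <- grid_axis(vol, 2); z <- grid_axis(vol, 3)
  e2 <- outer((x / spec$ellipse_semi_axis_x)^2, (y / spec$ellipse_semi_axis_y)^2, `+`)
  body2d <- ifelse(e2 <= 1, spec$body_mu, 0)
  zin <- if (is.finite(spec$cylinder_length)) abs(z) <= spec$cylinder_length / 2
         else rep(TRUE, d[3])
  vals <- array(0, d)
  for (k in which(zin)) vals[, , k] <- body2d
  if (include_sphere) {
    r <- spec$sphere_diameter / 2
    zc <- sphere_center_z(spec, time)
    for (k in seq_len(d[3])) {
      dz2 <- (z[k] - zc)^2
      if (dz2 >= r^2) next
      r2xy <- r^2 - dz2
      inside <- outer(x^2, y^2, `+`) <= r2xy
      sl <- vals[, , k]
      sl[inside & sl > 0] <- spec$sphere_mu
      vals[, , k] <- sl
    }
  }
  volume_image(vals, vol$voxel_size, vol$origin)
}

#' Analytic axial occupancy profile of the moving sphere
#'
#' For a sphere of radius R whose center translates uniformly over an
#' interval of length L along z, the fraction of acquisition time during
#' which an axial position z is inside the sphere is a closed-form
#' piecewise-linear profile (a trapezoid, degenerating to a triangle at
#' L = 2R). Its 10-90% edge width is 0.8 L for 0 < L <= 2R, and 0 for a
#' static sphere. Used as the independent oracle for the motion-blurred
#' cavity edge.
#'
#' @param spec a [phantom_spec()]; only the sphere radius and motion extent
#'   are used.
#' @param dz sampling step of the returned profile (mm).
#' @param margin extra z range beyond the occupied interval (mm).
#' @return A list with `width_mm` (closed-form 10-90% edge width), and
#'   `profile`, a data.frame of `z` (mm) and `occupancy` in `[0, 1]`.
#' @export
occupancy_edge_oracle <- function(spec, dz = 0.1, margin = 10) {
  r <- spec$sphere_diameter / 2
  l <- spec$motion_extent
  if (l > 2 * r)
    stop("oracle defined for motion extent <= sphere diameter")
  zmax <- r + l / 2 + margin
  z <- seq(-zmax, zmax, by = dz)
  occ <- if (l == 0) {
    as.numeric(abs(z) < r)
  } else {
    # sphere center m is uniform on [-l/2, l/2]; z covered iff |z - m| < r
    lo <- pmax(z - r, -l / 2)
    hi <- pmin(z + r, l / 2)
    pmax(0, hi - lo) / l
  }
  width <- if (l == 0) 0 else 0.8 * l
  list(width_mm = width, profile = data.frame(z = z, occupancy = occ))
}
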