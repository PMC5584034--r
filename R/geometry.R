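#' Cone-beam scan geometry
#'
#' Describes a circular cone-beam acquisition: source and flat-panel detector
#' distances, detector grid, optional lateral (cross-line) detector offset,
#' and the gantry angle schedule with acquisition timestamps.
#'
#' Coordinate convention: right-handed, z is the rotation (craniocaudal)
#' axis, the gantry angle is measured from the +y source position, and the
#' detector is flat and perpendicular to the source-isocenter line. The
#' lateral offset shifts the panel within its plane along the cross-line
#' direction, as in offset-detector (M/L field-of-view) acquisitions.
#'
#' @param sad source-to-axis distance in mm.
#' @param sdd source-to-detector distance in mm (must exceed `sad`).
#' @param det_rows,det_cols detector grid size (rows run along z).
#' @param det_pitch detector cell pitch in mm (square cells).
#' @param det_offset lateral detector offset in mm, measured at the detector
#'   (0 for S FOV, 115 for M FOV, 190 for L FOV).
#' @param angles_deg gantry angles in degrees, strictly increasing.
#' @param times_s acquisition timestamps in seconds; if `NULL`, derived from
#'   the angles and `rot_speed` starting at `start_time`.
#' @param rot_speed gantry rotation speed in degrees/second.
#' @param start_time acquisition start time in seconds.
#' @return A `scan_geometry` object.
#' @examples
#' g <- make_geometry(angles_deg = seq(0, 359, by = 1))
#' head(g$times_s)  # 1/6 s intervals at 6 deg/s
#' @export
make_geometry <- function(sad = 1000, sdd = 1536,
                          det_rows = 512, det_cols = 512,
                          det_pitch = 0.8, det_offset = 0,
                          angles_deg, times_s = NULL,
                          rot_speed = 6, start_time = 0) {
  if (!is.numeric(sad) || sad <= 0) stop("configuration error: sad must be > 0")
  if (!is.numeric(sdd) || sdd <= sad)
    stop("configuration error: sdd must exceed sad")
  if (det_rows < 1 || det_cols < 1)
    stop("configuration error: detector grid must be positive")
  if (det_pitch <= 0) stop("configuration error: det_pitch must be > 0")
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) < 1) stop("configuration error: no angles")
  if (is.null(times_s)) {
    if (rot_speed <= 0) stop("configuration error: rot_speed must be > 0")
    times_s <- start_time + (angles_deg - angles_deg[1]) / rot_speed
  }
  times_s <- as.numeric(times_s)
  if (length(times_s) != length(angles_deg))
    stop("configuration error: angles and timestamps differ in length")
  if (any(diff(times_s) <= 0))
    stop("configuration error: timestamps must be strictly increasing")
  structure(list(
    sad = sad, sdd = sdd,
    det_rows = as.integer(det_rows), det_cols = as.integer(det_cols),
    det_pitch = det_pitch, det_offset = det_offset,
    angles_deg = angles_deg, times_s = times_s,
    rot_speed = rot_speed
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "scan_geometry: SAD %g mm, SDD %g mm, detector %dx%d @ %g mm (offset %g mm)\n",
    x$sad, x$sdd, x$det_rows, x$det_cols, x$det_pitch, x$det_offset))
  cat(sprintf("  %d views, angles %.1f..%.1f deg, t = %.2f..%.2f s\n",
              length(x$angles_deg), min(x$angles_deg), max(x$angles_deg),
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Geometry presets for the digital-phantom experiment
#'
#' `"full"` matches the study conditions: 360 one-degree projections over a
#' 60 s rotation with a 512x512, 0.8 mm panel. `"scaled"` and `"mini"` are
#' coarser versions of the same physical acquisition (fewer views, coarser
#' panel) used for desk-scale runs; the phantom, rotation time and distances
#' are unchanged.
#'
#' @param scale one of `"full"`, `"scaled"`, `"mini"`.
#' @param fov `"S"` (centered panel) or `"M"` (115 mm lateral offset).
#' @return A `scan_geometry`.
#' @export
geometry_preset <- function(scale = c("scaled", "full", "mini"),
                            fov = c("S", "M")) {
  scale <- match.arg(scale)
  fov <- match.arg(fov)
  offset <- if (fov == "M") 115 else 0
  p <- switch(scale,
    full   = list(n = 360L, rows = 512L, cols = 512L, pitch = 0.8),
    scaled = list(n = 90L,  rows = 48L,  cols = 168L, pitch = 2.5),
    mini   = list(n = 90L,  rows = 32L,  cols = 104L, pitch = 4.0))
  step <- 360 / p$n
  make_geometry(sad = 1000, sdd = 1536,
                det_rows = p$rows, det_cols = p$cols, det_pitch = p$pitch,
                det_offset = offset,
                angles_deg = seq(0, 360 - step, by = step),
                rot_speed = 6)
}

# Per-view source position and detector basis vectors (3 x nviews matrices).
# Cell (r, c) center (0-based) = det0 + c*eu + r*ev. If `at_isocenter`, the
# detector is rescaled onto the plane through the origin (for FDK).
detector_basis <- function(geometry, view_idx = NULL, at_isocenter = FALSE) {
  g <- geometry
  idx <- view_idx %||% seq_along(g$angles_deg)
  th <- g$angles_deg[idx] * pi / 180
  nv <- length(th)
  src <- rbind(g$sad * sin(th), g$sad * cos(th), rep(0, nv))
  axis <- rbind(-sin(th), -cos(th), rep(0, nv))        # beam direction
  uhat <- rbind(cos(th), -sin(th), rep(0, nv))         # cross-line direction
  vhat <- rbind(rep(0, nv), rep(0, nv), rep(1, nv))    # rows run along +z
  sc <- if (at_isocenter) g$sad / g$sdd else 1
  ddist <- if (at_isocenter) g$sad else g$sdd
  center <- src + ddist * axis
  u0 <- sc * (g$det_offset - (g$det_cols - 1) / 2 * g$det_pitch)
  v0 <- sc * (-(g$det_rows - 1) / 2 * g$det_pitch)
  det0 <- center + rep(u0, each = 3) * uhat + rep(v0, each = 3) * vhat
  list(src = src, det0 = det0,
       eu = sc * g$det_pitch * uhat, ev = sc * g$det_pitch * vhat,
       axis = axis, view_idx = idx)
}

#' 3D attenuation volume
#'
#' A 3D scalar grid of linear attenuation coefficients (1/mm) with voxel size
#' and origin. The grid is cell-centered: `origin` is the position (mm) of
#' the outer corner of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array, all finite and >= 0.
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @param origin grid corner in mm (length 3); defaults to centering the grid
#'   on the rotation axis.
#' @return A `volume_image`.
#' @export
volume_image <- function(values, voxel_size = 1, origin = NULL) {
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(!is.finite(values))) stop("volume values must be finite")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  d <- dim(values)
  origin <- origin %||% (-d * voxel_size / 2)
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("volume_image: %dx%dx%d voxels @ (%g, %g, %g) mm, range [%g, %g]\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Empty volume on a centered grid
#'
#' @param dims grid size (length 3).
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @param center grid center in mm.
#' @return A zero-filled `volume_image`.
#' @export
volume_template <- function(dims, voxel_size = 1, center = c(0, 0, 0)) {
  dims <- as.integer(rep(dims, length.out = 3))
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  origin <- center - dims * voxel_size / 2
  volume_image(array(0, dims), voxel_size, origin)
}

#' Cell-center coordinates of a volume grid
#'
#' @param vol a `volume_image`.
#' @param axis axis index (1 = x, 2 = y, 3 = z).
#' @return Numeric vector of cell-center positions in mm.
#' @export
grid_axis <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_size[axis]
}
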