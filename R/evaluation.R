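#' 10-90% penumbral width of the moving air cavity
#'
#' Measures the temporal-resolution surrogate: the voxel-value profile along
#' the central longitudinal (z) axis is inverted and normalized to `[0, 1]`
#' using the background attenuation and the cavity minimum, and the 0.1 and
#' 0.9 crossings of each cavity edge are located by sub-voxel linear
#' interpolation. The reported width is the mean of the two edge widths
#' (each edge retained in the result); the measure is invariant to global
#' affine rescaling of the volume values.
#'
#' @param volume a `volume_image`, or a data.frame with columns `z` and
#'   `value` giving the profile directly.
#' @param background_mu background (body) attenuation used for
#'   normalization; if `NULL`, estimated as the median of profile samples at
#'   least `exclusion_mm` away from the cavity minimum.
#' @param axis_xy transaxial position (mm) of the profile line.
#' @param exclusion_mm distance from the cavity used by the background
#'   estimate (one sphere diameter by default).
#' @return A `penumbra_result`: `width_mm`, per-edge widths, crossing
#'   positions, and the normalized profile.
#' @export
penumbral_width <- function(volume, background_mu = NULL, axis_xy = c(0, 0),
                            exclusion_mm = 30) {
  if (inherits(volume, "volume_image")) {
    i <- which.min(abs(grid_axis(volume, 1) - axis_xy[1]))
    j <- which.min(abs(grid_axis(volume, 2) - axis_xy[2]))
    z <- grid_axis(volume, 3)
    v <- volume$values[i, j, ]
  } else {
    z <- volume$z
    v <- volume$value
  }
  imin <- which.min(v)
  estimated_bg <- is.null(background_mu)
  if (is.null(background_mu)) {
    far <- abs(z - z[imin]) >= exclusion_mm
    if (!any(far))
      stop("no samples far enough from the cavity; supply background_mu")
    background_mu <- median(v[far])
  }
  depth <- background_mu - v[imin]
  # with an estimated background, additionally require the cavity minimum
  # below half the background level (attenuation-scale check); the explicit-
  # background path stays invariant under affine rescaling of the values
  if (depth <= 0 || (estimated_bg && v[imin] >= 0.5 * background_mu))
    stop("no cavity found on the profile")
  q <- (background_mu - v) / depth
  ipk <- which.max(q)

  cross_from_peak <- function(side, level) {
    # walk from the peak outwards until q drops below `level`, interpolate
    ord <- if (side == "left") seq(ipk, 1) else seq(ipk, length(q))
    below <- which(q[ord] < level)
    if (!length(below)) return(NA_real_)
    a <- ord[below[1]]                 # first sample below the level
    b <- a + if (side == "left") 1 else -1   # neighbour toward the peak
    z[a] + (z[b] - z[a]) * (level - q[a]) / (q[b] - q[a])
  }
  edges <- list(
    left = c(lo = cross_from_peak("left", 0.1), hi = cross_from_peak("left", 0.9)),
    right = c(lo = cross_from_peak("right", 0.1), hi = cross_from_peak("right", 0.9)))
  widths <- vapply(edges, function(e) abs(e["hi"] - e["lo"]), 1)
  if (all(is.na(widths))) stop("no complete cavity edge on the profile")
  structure(list(width_mm = mean(widths, na.rm = TRUE),
                 edge_widths = widths, edge_positions = edges,
                 profile = data.frame(z = z, value = v, normalized = q),
                 background_mu = background_mu),
            class = "penumbra_result")
}

#' @export
print.penumbra_result <- function(x, ...) {
  cat(sprintf("penumbral width: %.2f mm (edges %.2f / %.2f mm)\n",
              x$width_mm, x$edge_widths[1], x$edge_widths[2]))
  invisible(x)
}

#' Circular region of interest
#'
#' A circular ROI on one axial slice, specified by its pixel count: the
#' radius is solved so the rasterized disc (pixel centers inside the
#' radius) contains exactly `pixel_count` pixels (316 by default, radius
#' about 10.03 pixels for an ROI centered on a grid corner, i.e. offset by
#' half a pixel from the pixel centers).
#'
#' @param center ROI center in pixel coordinates (length 2, may be
#'   fractional).
#' @param slice axial slice index.
#' @param pixel_count required number of pixels in the disc.
#' @return A `roi_spec` with the solved `radius_px`.
#' @export
roi_spec <- function(center, slice, pixel_count = 316) {
  center <- as.numeric(center)
  rmax <- ceiling(sqrt(pixel_count)) + 3
  ij <- expand.grid(di = -rmax:rmax, dj = -rmax:rmax)
  d <- sqrt((ij$di + center[1] - round(center[1]))^2 +
            (ij$dj + center[2] - round(center[2]))^2)
  d <- sort(d)
  if (pixel_count > length(d)) stop("pixel_count too large")
  if (d[pixel_count] == d[pixel_count + 1])
    stop("no radius yields exactly ", pixel_count,
         " pixels at this center; offset the center (e.g. by half a pixel)")
  radius <- (d[pixel_count] + d[pixel_count + 1]) / 2
  structure(list(center = center, slice = as.integer(slice),
                 pixel_count = as.integer(pixel_count), radius_px = radius),
            class = "roi_spec")
}

#' Rasterize an ROI disc
#'
#' @param roi a [roi_spec()].
#' @param dims slice dimensions (length 2).
#' @return Logical matrix marking pixels whose centers fall inside the ROI.
#' @export
roi_disc_mask <- function(roi, dims) {
  i <- seq_len(dims[1]); j <- seq_len(dims[2])
  outer((i - roi$center[1])^2, (j - roi$center[2])^2, `+`) <= roi$radius_px^2
}

#' ROI mean-value consistency across phases
#'
#' Root-mean-square deviation of the per-phase ROI mean pixel values from
#' the reference ROI mean, normalized by the reference mean and expressed
#' in percent: `100 * sqrt(mean_t (m_t - m_ref)^2) / m_ref`. Scaling the
#' series and reference together leaves the result unchanged.
#'
#' @param series a [time_series_image()] or list of `volume_image`s.
#' @param reference reference `volume_image` on the same grid.
#' @param roi a [roi_spec()].
#' @return Percent RMSE (scalar); per-phase means as attribute `means`.
#' @export
roi_consistency_rmse <- function(series, reference, roi) {
  phases <- if (inherits(series, "time_series_image")) series$phases else series
  d <- dim(reference$values)
  if (roi$slice < 1 || roi$slice > d[3]) stop("slice outside the volume")
  mask <- roi_disc_mask(roi, d[1:2])
  m_ref <- mean(reference$values[, , roi$slice][mask])
  if (m_ref == 0) stop("reference ROI mean is zero")
  m_t <- vapply(phases, function(p) {
    if (!identical(dim(p$values), d)) stop("grid mismatch")
    mean(p$values[, , roi$slice][mask])
  }, 1)
  out <- 100 * sqrt(mean((m_t - m_ref)^2)) / m_ref
  attr(out, "means") <- m_t
  out
}
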