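# Extension of laterally truncated (offset-detector) projections before
# iterative reconstruction: (1) full-scan FDK of the whole object from the
# truncated projections with offset redundancy weighting, (2) reprojection
# onto a widened virtual detector, (3) mosaic of the measured frames with
# the reprojected peripheral band.

#' Widened virtual detector geometry
#'
#' Builds the geometry of the extended detector used by
#' [extend_projections()]: `extended_cols` columns (800 by default, matching
#' the 512 -> 800 extension of offset-panel acquisitions) at the same pitch,
#' with the panel offset chosen as close to centered as possible while
#' keeping the measured cell centers exactly on the widened column lattice.
#'
#' @param geometry the truncated-acquisition [make_geometry()].
#' @param extended_cols width of the extended frames in columns.
#' @return A list: `geometry` (the widened `scan_geometry`) and
#'   `col_shift` (0-based column offset of the measured panel inside the
#'   widened frame).
#' @export
extended_geometry <- function(geometry, extended_cols = 800) {
  g <- geometry
  if (extended_cols < g$det_cols)
    stop("extended_cols must be >= the measured column count")
  k <- round((extended_cols - g$det_cols) / 2 + g$det_offset / g$det_pitch)
  offset_w <- g$det_offset - g$det_pitch * (k - (extended_cols - g$det_cols) / 2)
  if (k < 0 || k + g$det_cols > extended_cols)
    stop("extended detector does not cover the measured panel")
  gw <- make_geometry(sad = g$sad, sdd = g$sdd, det_rows = g$det_rows,
                      det_cols = extended_cols, det_pitch = g$det_pitch,
                      det_offset = offset_w, angles_deg = g$angles_deg,
                      times_s = g$times_s, rot_speed = g$rot_speed)
  list(geometry = gw, col_shift = as.integer(k))
}

#' Extend truncated offset-detector projections
#'
#' Three-step extension of a full-scan, laterally truncated acquisition:
#' FDK reconstruction of the whole object from all projections (with
#' offset-detector redundancy weighting), reprojection onto a widened
#' virtual detector, and a mosaic that keeps the measured values exactly
#' where the real panel covers and fills the peripheral band with the
#' reprojected values (with a short linear cross-fade on the virtual side
#' of each seam).
#'
#' @param truncated measured [projection_set()] (full 360 degree coverage).
#' @param geometry the matching [make_geometry()] (laterally offset panel).
#' @param grid `volume_image` template for the intermediate FDK volume
#'   (must cover the whole object).
#' @param extended_cols width of the extended frames (columns).
#' @param feather cross-fade length in columns on the virtual side.
#' @return A list: `projections` (extended [projection_set()]),
#'   `geometry` (widened detector geometry), `fdk_volume` (the step-1
#'   reconstruction) and `col_shift`.
#' @export
extend_projections <- function(truncated, geometry, grid,
                               extended_cols = 800, feather = 5) {
  check_frames_match(truncated, geometry)
  ang <- geometry$angles_deg
  span <- max(ang) - min(ang) + mean(diff(ang))
  if (span < 360 - 1e-6)
    stop("projection extension requires full 360 degree coverage")
  step1 <- reconstruct_fdk(truncated, geometry, grid,
                           redundancy = if (abs(geometry$det_offset) >
                                            geometry$det_pitch / 2) "offset"
                                        else "none")
  ext <- extended_geometry(geometry, extended_cols)
  virt <- forward_project(step1, ext$geometry, n0 = truncated$n0)
  frames <- virt$frames
  k <- ext$col_shift
  cols <- geometry$det_cols
  meas <- (k + 1):(k + cols)
  nv <- dim(frames)[3]
  for (vv in seq_len(nv)) {
    fr <- frames[, , vv]
    real <- truncated$frames[, , vv]
    if (feather > 0) {
      for (d in seq_len(feather)) {        # virtual side of the left seam
        c_idx <- k + 1 - d
        if (c_idx >= 1) {
          w <- (feather - d + 1) / (feather + 1)
          fr[, c_idx] <- (1 - w) * fr[, c_idx] + w * real[, 1]
        }
        c_idx <- k + cols + d              # virtual side of the right seam
        if (c_idx <= extended_cols) {
          w <- (feather - d + 1) / (feather + 1)
          fr[, c_idx] <- (1 - w) * fr[, c_idx] + w * real[, cols]
        }
      }
    }
    fr[, meas] <- real                     # measured columns kept exactly
    frames[, , vv] <- fr
  }
  frames[frames < 0] <- 0
  list(projections = projection_set(frames, truncated$angles_deg,
                                    truncated$times_s, truncated$n0),
       geometry = ext$geometry, fdk_volume = step1,
       col_shift = ext$col_shift)
}

#' Zero-padded comparison set for a truncated acquisition
#'
#' Embeds the measured frames in the widened detector with zeros in the
#' peripheral band -- the baseline against which the reprojection-based
#' extension is compared.
#'
#' @inheritParams extend_projections
#' @return As [extend_projections()] (without `fdk_volume`).
#' @export
zero_pad_projections <- function(truncated, geometry, extended_cols = 800) {
  check_frames_match(truncated, geometry)
  ext <- extended_geometry(geometry, extended_cols)
  k <- ext$col_shift
  d <- dim(truncated$frames)
  frames <- array(0, c(d[1], extended_cols, d[3]))
  frames[, (k + 1):(k + d[2]), ] <- truncated$frames
  list(projections = projection_set(frames, truncated$angles_deg,
                                    truncated$times_s, truncated$n0),
       geometry = ext$geometry, col_shift = ext$col_shift)
}
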