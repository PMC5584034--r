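#' Split an acquisition into time phases with angular windows
#'
#' Divides the acquisition into `T` phases with equally spaced centers in
#' time. Each phase is assigned the contiguous set of projections whose
#' gantry angle lies within half the window extent of the phase center angle
#' (right-open interval), clamped to the acquired range, so the first and
#' last phases get asymmetric windows. Adjacent windows may overlap.
#'
#' @param projections a [projection_set()].
#' @param n_phases number of phases T (>= 2 for temporal reconstruction; 1
#'   is allowed for a single-window run).
#' @param window_extent angular window extent in degrees (e.g. 200 for the
#'   TVCS initialization, 90 for PICCS/TCGM refinement).
#' @return A `phase_binning` with phase centers (s and degrees) and per-phase
#'   index windows.
#' @export
assign_phases <- function(projections, n_phases, window_extent) {
  if (window_extent <= 0) stop("window_extent must be > 0")
  if (n_phases < 1) stop("n_phases must be >= 1")
  tms <- projections$times_s
  ang <- projections$angles_deg
  ang_step <- if (length(ang) > 1) mean(diff(ang)) else window_extent
  if (window_extent > max(ang) - min(ang) + ang_step)
    stop("window_extent exceeds the angular range")
  # each projection represents one sampling interval
  t_step <- if (length(tms) > 1) median(diff(tms)) else 0
  total <- max(tms) - min(tms) + t_step
  centers_s <- min(tms) + (seq_len(n_phases) - 0.5) * total / n_phases
  center_ang <- if (length(tms) > 1)
    approx(tms, ang, xout = centers_s, rule = 2)$y
  else rep(ang, n_phases)
  windows <- lapply(center_ang, function(ca) {
    which(ang >= ca - window_extent / 2 & ang < ca + window_extent / 2)
  })
  if (any(vapply(windows, length, 1L) == 0))
    stop("empty phase window")
  structure(list(n_phases = as.integer(n_phases),
                 centers_s = centers_s, center_angles = center_ang,
                 windows = windows, window_extent = window_extent),
            class = "phase_binning")
}

#' @export
print.phase_binning <- function(x, ...) {
  cat(sprintf("phase_binning: %d phases, %g deg windows\n",
              x$n_phases, x$window_extent))
  for (t in seq_len(x$n_phases))
    cat(sprintf("  phase %d: center %.2f s / %.1f deg, views %d..%d (%d)\n",
                t, x$centers_s[t], x$center_angles[t],
                min(x$windows[[t]]), max(x$windows[[t]]),
                length(x$windows[[t]])))
  invisible(x)
}

#' Serialize / restore a phase binning
#'
#' @param binning a [assign_phases()] result.
#' @param path JSON file path.
#' @return `write_binning` returns `path` invisibly; `read_binning` a
#'   `phase_binning`.
#' @export
write_binning <- function(binning, path) {
  obj <- list(n_phases = binning$n_phases, centers_s = binning$centers_s,
              center_angles = binning$center_angles,
              window_extent = binning$window_extent,
              windows = lapply(binning$windows, range))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binning
#' @export
read_binning <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_phases = as.integer(obj$n_phases),
                 centers_s = obj$centers_s, center_angles = obj$center_angles,
                 windows = lapply(seq_len(nrow(obj$windows)), function(i)
                   seq(obj$windows[i, 1], obj$windows[i, 2])),
                 window_extent = obj$window_extent),
            class = "phase_binning")
}
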