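# End-to-end digital-phantom experiment: simulate the moving-sphere scan,
# reconstruct with FDK / TVCS / PICCS / TCGM, and measure the penumbral
# width of the evaluated phase.

#' Phantom preset matched to a geometry scale
#'
#' The phantom itself (220 x 160 mm elliptic cylinder, 0.02/mm body, 3 cm
#' air sphere moving 3 cm along z) is identical at every scale; only the
#' reconstruction grid is coarsened. The `"60s"` speed moves the sphere
#' during the whole 360 degree rotation (0.5 mm/s); `"30s"` moves it during
#' the central 180 degrees, from the 90 to the 270 degree source position
#' (1 mm/s).
#'
#' @param speed `"60s"` or `"30s"` (3 cm of travel in either case).
#' @param scale `"full"`, `"scaled"` or `"mini"` grid preset.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(speed = c("60s", "30s"),
                           scale = c("scaled", "full", "mini")) {
  speed <- match.arg(speed)
  scale <- match.arg(scale)
  grid <- switch(scale,
    full   = list(dims = c(256, 256, 72), vox = c(1, 1, 1)),
    scaled = list(dims = c(128, 128, 56), vox = c(2, 2, 1.25)),
    mini   = list(dims = c(64, 64, 40),  vox = c(3.6, 3.6, 1.875)))
  times <- if (speed == "60s") c(0, 60) else c(15, 45)
  phantom_spec(motion_start_time = times[1], motion_end_time = times[2],
               voxel_size = grid$vox, grid_dims = grid$dims)
}

# background attenuation estimate: median along an axial line inside the
# body but well away from the sphere track (x = 60 mm, y = 0)
estimate_background <- function(volume, x_mm = 60) {
  i <- which.min(abs(grid_axis(volume, 1) - x_mm))
  j <- which.min(abs(grid_axis(volume, 2) - 0))
  median(volume$values[i, j, ])
}

#' Run the moving-sphere phantom experiment
#'
#' Full pipeline for one sphere speed: simulate the scan, reconstruct the
#' full-rotation FDK baseline, initialize nine phases with TVCS on wide
#' windows, refine with PICCS (prior = same-phase TVCS image) and/or TCGM
#' on narrow windows, and measure the 10-90% penumbral width of the
#' evaluated phase on the central axis.
#'
#' @param speed `"60s"` or `"30s"`.
#' @param scale grid/geometry preset (`"scaled"`, `"full"`, `"mini"`).
#' @param methods subset of `c("fdk", "tvcs", "piccs", "tcgm")`; TVCS is
#'   always run when a refinement method needs it.
#' @param n_phases number of time phases.
#' @param tvcs_window,refine_window angular window extents (degrees).
#' @param eval_phase phase whose width is reported (the temporal midpoint,
#'   5 of 9, by default).
#' @param n_iter_init,n_iter_refine outer iterations for the TVCS
#'   initialization and the PICCS/TCGM refinement.
#' @param lambda_balance auto-balancing ratio override; `NULL` (default)
#'   keeps each method preset's own ratio (see [recon_preset()]).
#' @param n0 source photons per element.
#' @param seed integer seed recorded in the configs.
#' @param verbose print stage progress.
#' @return A list: `widths` (data.frame of method, window, speed, width_mm),
#'   `series` (per-method phase-5 volume or full series), `objectives`,
#'   `lambda`, `binnings`, `projections`, `geometry`, `spec`.
#' @export
run_phantom_experiment <- function(speed = c("60s", "30s"),
                                   scale = c("scaled", "full", "mini"),
                                   methods = c("fdk", "tvcs", "piccs", "tcgm"),
                                   n_phases = 9,
                                   tvcs_window = 200, refine_window = 90,
                                   eval_phase = 5,
                                   n_iter_init = 10, n_iter_refine = 24,
                                   lambda_balance = NULL, n0 = 1e5,
                                   seed = 1L, verbose = FALSE) {
  speed <- match.arg(speed)
  scale <- match.arg(scale)
  methods <- match.arg(methods, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  geometry <- geometry_preset(scale)
  spec <- phantom_preset(speed, scale)
  grid <- volume_template(spec$grid_dims, spec$voxel_size)
  say("simulating %s scan (%s)", speed, scale)
  proj <- simulate_phantom_scan(geometry, spec, n0 = n0)

  widths <- data.frame()
  series <- list()
  objectives <- list()
  lambdas <- list()
  add_width <- function(method, window, vol) {
    bg <- estimate_background(vol)
    pw <- penumbral_width(vol, background_mu = bg,
                          exclusion_mm = spec$sphere_diameter)
    widths <<- rbind(widths, data.frame(
      method = method, window_deg = window, speed = speed,
      phase = if (method == "fdk") NA_integer_ else eval_phase,
      width_mm = pw$width_mm))
    pw
  }

  say("FDK baseline")
  fdk_vol <- reconstruct_fdk(proj, geometry, grid)
  if ("fdk" %in% methods) add_width("fdk", 360, fdk_vol)
  series$fdk <- fdk_vol

  need_tvcs <- any(c("tvcs", "piccs", "tcgm") %in% methods)
  if (need_tvcs) {
    bin_wide <- assign_phases(proj, n_phases, tvcs_window)
    bin_narrow <- assign_phases(proj, n_phases, refine_window)
    say("TVCS initialization (%d phases, %g deg)", n_phases, tvcs_window)
    bal <- function() {
      if (is.null(lambda_balance)) list() else
        list(lambda_balance = lambda_balance)
    }
    cfg_tvcs <- do.call(recon_preset, c(list("tvcs",
                             n_iterations = n_iter_init, n0 = n0,
                             seed = seed), bal()))
    tvcs <- reconstruct_iterative(proj, bin_wide, geometry, cfg_tvcs,
                                  initial = rep(list(fdk_vol), n_phases))
    objectives$tvcs <- attr(tvcs, "objective")
    lambdas$tvcs <- attr(tvcs, "lambda")
    series$tvcs <- tvcs
    if ("tvcs" %in% methods) add_width("tvcs", tvcs_window,
                                       tvcs$phases[[eval_phase]])
    if ("piccs" %in% methods) {
      # PICCS phases are independent (fixed per-phase prior, no temporal
      # coupling), so only the evaluated phase needs refining
      say("PICCS refinement (%g deg, phase %d)", refine_window, eval_phase)
      cfg <- do.call(recon_preset, c(list("piccs",
                          n_iterations = n_iter_refine, n0 = n0,
                          seed = seed), bal()))
      bin_one <- bin_narrow
      bin_one$n_phases <- 1L
      bin_one$windows <- bin_narrow$windows[eval_phase]
      bin_one$centers_s <- bin_narrow$centers_s[eval_phase]
      bin_one$center_angles <- bin_narrow$center_angles[eval_phase]
      piccs <- reconstruct_iterative(proj, bin_one, geometry, cfg,
                                     initial = tvcs$phases[eval_phase],
                                     prior = tvcs$phases[eval_phase])
      objectives$piccs <- attr(piccs, "objective")
      lambdas$piccs <- attr(piccs, "lambda")
      series$piccs <- piccs
      add_width("piccs", refine_window, piccs$phases[[1]])
    }
    if ("tcgm" %in% methods) {
      say("TCGM refinement (%g deg)", refine_window)
      cfg <- do.call(recon_preset, c(list("tcgm",
                          n_iterations = n_iter_refine, n0 = n0,
                          seed = seed), bal()))
      tcgm <- reconstruct_iterative(proj, bin_narrow, geometry, cfg,
                                    initial = tvcs$phases)
      objectives$tcgm <- attr(tcgm, "objective")
      lambdas$tcgm <- attr(tcgm, "lambda")
      series$tcgm <- tcgm
      add_width("tcgm", refine_window, tcgm$phases[[eval_phase]])
    }
  }
  binnings <- if (need_tvcs) list(wide = bin_wide, narrow = bin_narrow)
  list(widths = widths, series = series, objectives = objectives,
       lambda = lambdas, binnings = binnings, projections = proj,
       geometry = geometry, spec = spec)
}

#' Relative penumbral-width narrowing
#'
#' Percent by which a method's width is narrower than the reference
#' (TVCS) width: `100 * (w_ref - w) / w_ref`.
#'
#' @param width,width_ref widths in mm.
#' @return percent narrowing.
#' @export
narrowing_percent <- function(width, width_ref) {
  100 * (width_ref - width) / width_ref
}
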