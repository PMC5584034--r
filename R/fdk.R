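# FDK filtered backprojection: cosine weighting, row-wise ramp filtering in
# the frequency domain (Ram-Lak, optional Hann apodization), distance-weighted
# voxel-driven backprojection. Detector coordinates are rescaled onto the
# virtual plane through the isocenter, so the ramp kernel spacing is
# pitch * SAD / SDD.

# Frequency response of the band-limited ramp on spacing du, padded length n,
# with optional Hann apodization. Built from the exact discrete space-domain
# kernel g(0) = 1/(8 du^2), g(odd k) = -1/(2 pi^2 k^2 du^2), g(even k) = 0.
ramp_filter_response <- function(n, du, apodization = c("hann", "ramlak")) {
  apodization <- match.arg(apodization)
  k <- c(0:(n / 2), -(n / 2 - 1):-1)
  g <- numeric(n)
  g[1] <- 1 / (8 * du^2)
  odd <- which(k %% 2 != 0)
  g[odd] <- -1 / (2 * pi^2 * k[odd]^2 * du^2)
  resp <- Re(fft(g))
  if (apodization == "hann") {
    f <- abs(k) / n                      # cycles/sample in [0, 0.5]
    resp <- resp * (0.5 + 0.5 * cos(2 * pi * f))
  }
  resp
}

# Smooth redundancy weight for a laterally offset detector over a full scan
# (Wang-type): conjugate rays at +/-u share weight summing to 1; doubled so
# the full-scan backprojection normalization is preserved.
offset_redundancy_weight <- function(u_iso) {
  umin <- min(u_iso); umax <- max(u_iso)
  if (umin >= 0 || umax <= 0)
    stop("offset weighting requires the panel to straddle the central ray")
  u0 <- min(-umin, umax)
  w <- ifelse(u_iso <= -u0, 0,
       ifelse(u_iso >= u0, 1, sin(pi * (u_iso + u0) / (4 * u0))^2))
  2 * w
}

#' FDK cone-beam reconstruction
#'
#' Analytic reconstruction of a full-scan cone-beam acquisition: cosine
#' pre-weighting, row-wise ramp filtering (Ram-Lak with Hann apodization by
#' default, zero-padded to the next power of two), and distance-weighted
#' backprojection onto the template grid. Operates on line integrals, so the
#' result is independent of the source intensity. Negative values are
#' clipped to zero for downstream use as attenuation.
#'
#' @param projections a [projection_set()] of line integrals.
#' @param geometry the matching [make_geometry()].
#' @param grid a `volume_image` template defining the output grid.
#' @param apodization `"hann"` (default) or `"ramlak"`.
#' @param redundancy `"auto"` applies offset-detector redundancy weighting
#'   when the geometry has a lateral offset; `"none"` / `"offset"` force it.
#' @param clip_negative clip negative output values to 0 (default).
#' @return A `volume_image`.
#' @export
reconstruct_fdk <- function(projections, geometry, grid,
                            apodization = c("hann", "ramlak"),
                            redundancy = c("auto", "none", "offset"),
                            clip_negative = TRUE) {
  apodization <- match.arg(apodization)
  redundancy <- match.arg(redundancy)
  check_frames_match(projections, geometry)
  nv <- dim(projections$frames)[3]
  if (nv == 0) stop("empty projection set")
  idx <- match_views(projections, geometry)
  g <- geometry
  sc <- g$sad / g$sdd
  u <- sc * (g$det_offset + (seq_len(g$det_cols) - (g$det_cols + 1) / 2) * g$det_pitch)
  v <- sc * ((seq_len(g$det_rows) - (g$det_rows + 1) / 2) * g$det_pitch)
  cosw <- g$sad / sqrt(g$sad^2 + outer(v^2, u^2, `+`))   # rows x cols
  use_offset <- redundancy == "offset" ||
    (redundancy == "auto" && abs(g$det_offset) > g$det_pitch / 2)
  if (use_offset)
    cosw <- cosw * matrix(offset_redundancy_weight(u), g$det_rows, g$det_cols,
                          byrow = TRUE)
  du <- sc * g$det_pitch
  npad <- 2^ceiling(log2(2 * g$det_cols))
  resp <- ramp_filter_response(npad, du, apodization)

  # per-view angular weight (radians), one-sided at the schedule ends
  beta <- g$angles_deg[idx] * pi / 180
  dbeta <- if (nv > 1) {
    db <- c(beta[2] - beta[1], diff(beta, lag = 2) / 2, beta[nv] - beta[nv - 1])
    db
  } else 2 * pi

  filtered <- array(0, dim(projections$frames))
  for (k in seq_len(nv)) {
    m <- projections$frames[, , k] * cosw
    padded <- matrix(0, npad, g$det_rows)
    padded[seq_len(g$det_cols), ] <- t(m)
    q <- Re(mvfft(mvfft(padded) * resp, inverse = TRUE)) / npad
    filtered[, , k] <- t(q[seq_len(g$det_cols), ]) * (du * dbeta[k])
  }

  b <- detector_basis(g, idx, at_isocenter = TRUE)
  raw <- cpp_fdk_backproject(as_dbl(filtered), g$det_rows, g$det_cols,
                             dim(grid$values), grid$voxel_size, grid$origin,
                             b$src, b$det0, b$eu, b$ev, b$axis, g$sad)
  out <- grid
  out$values <- array(raw, dim(grid$values))
  if (clip_negative) out$values[out$values < 0] <- 0
  out
}
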