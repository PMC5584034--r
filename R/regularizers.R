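# Smoothed total-variation regularizers. The TV of a volume is the sum over
# voxels of sqrt(dx^2 + dy^2 + dz^2 + eps) of the forward differences, with
# zero differences beyond the far edges (replicate padding); eps > 0 keeps
# the norm differentiable at zero gradient.

# value and gradient via the compiled single-pass kernel; `b`, if given, is
# subtracted from `a` inside the kernel (difference-image TV without an
# intermediate allocation)
tv_value_grad <- function(a, epsilon, gradient = FALSE, b = NULL) {
  r <- cpp_tv(as_dbl(a), if (!is.null(b)) as_dbl(b), dim(a),
              epsilon, gradient)
  if (gradient) r$gradient <- array(r$gradient, dim(a))
  r
}

as_vol_values <- function(x) if (inherits(x, "volume_image")) x$values else x

#' Smoothed total variation of a volume
#'
#' @param volume a `volume_image` or 3D array.
#' @param epsilon smoothing constant inside the square root ((1/mm)^2).
#' @param gradient also return the gradient array.
#' @return The TV value, or a list `(value, gradient)` when
#'   `gradient = TRUE`.
#' @export
tv_norm <- function(volume, epsilon = 1e-6, gradient = FALSE) {
  r <- tv_value_grad(as_vol_values(volume), epsilon, gradient)
  if (gradient) r else r$value
}

#' Prior-image constraint term
#'
#' Total variation of the difference between the current and prior volumes,
#' the PICCS constraint. Gradient is with respect to the current volume.
#'
#' @param volume,prior `volume_image`s or arrays on the same grid.
#' @inheritParams tv_norm
#' @return As [tv_norm()].
#' @export
pic_term <- function(volume, prior, epsilon = 1e-6, gradient = FALSE) {
  a <- as_vol_values(volume); p <- as_vol_values(prior)
  if (!identical(dim(a), dim(p))) stop("grid mismatch between volume and prior")
  r <- tv_value_grad(a, epsilon, gradient, b = p)
  if (gradient) r else r$value
}

#' Time-ordered chain graph (TCGM) term for one phase
#'
#' Couples phase t to its temporal neighbours: for interior phases the sum
#' of the TV norms of the two difference images (t minus previous, t minus
#' next); for the first and last phases the single available difference
#' counted twice. Gradient is with respect to the phase-t volume.
#'
#' @param series a [time_series_image()] or plain list of volumes.
#' @param t phase index in 1..T.
#' @inheritParams tv_norm
#' @return As [tv_norm()].
#' @export
tcgm_term <- function(series, t, epsilon = 1e-6, gradient = FALSE) {
  phases <- if (inherits(series, "time_series_image")) series$phases else series
  T <- length(phases)
  if (T < 2) stop("TCGM term requires at least two phases")
  if (t < 1 || t > T) stop("phase index out of range")
  a <- as_vol_values(phases[[t]])
  neigh <- c(if (t > 1) t - 1, if (t < T) t + 1)
  wts <- if (length(neigh) == 1) 2 else c(1, 1)
  value <- 0
  grad <- if (gradient) array(0, dim(a))
  for (i in seq_along(neigh)) {
    r <- tv_value_grad(a, epsilon, gradient,
                       b = as_vol_values(phases[[neigh[i]]]))
    value <- value + wts[i] * r$value
    if (gradient) grad <- grad + wts[i] * r$gradient
  }
  if (gradient) list(value = value, gradient = grad) else value
}

#' Ordered multi-phase image series
#'
#' An ordered list of phase volumes sharing one grid, with an optional prior
#' volume (or per-phase list of priors) for the PICCS constraint.
#'
#' @param phases list of `volume_image`s on a common grid.
#' @param prior optional `volume_image`, or list of one per phase.
#' @return A `time_series_image`.
#' @export
time_series_image <- function(phases, prior = NULL) {
  if (!length(phases)) stop("empty phase list")
  d <- dim(phases[[1]]$values)
  ok <- vapply(phases, function(p) identical(dim(p$values), d), TRUE)
  if (!all(ok)) stop("all phases must share one grid")
  if (any(vapply(phases, function(p) min(p$values), 1) < 0))
    stop("phase volumes must be nonnegative")
  structure(list(phases = phases, prior = prior), class = "time_series_image")
}

#' @export
print.time_series_image <- function(x, ...) {
  d <- dim(x$phases[[1]]$values)
  cat(sprintf("time_series_image: %d phases of %dx%dx%d%s\n",
              length(x$phases), d[1], d[2], d[3],
              if (is.null(x$prior)) "" else " (+ prior)"))
  invisible(x)
}
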