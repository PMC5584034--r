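#' Reconstruction configuration
#'
#' Regularizer weights and optimizer controls for the MAP engine. The
#' presets reproduce the study settings: `(alpha, beta, gamma)` =
#' `(1, 0, 0)` for TVCS, `(0.1, 0.9, 0)` for PICCS, `(0.1, 0, 0.9)` for
#' TCGM. The global regularization strength `lambda` trades the Poisson
#' data-fidelity term against the regularizer; when `NULL` it is
#' auto-balanced so that `lambda * ||grad R|| = lambda_balance *
#' ||grad data||` at the initial iterate (the chosen value is recorded on
#' the result).
#'
#' @param alpha,beta,gamma TV / prior-image / temporal weights (>= 0).
#' @param lambda global regularization strength, or `NULL` for
#'   auto-balancing.
#' @param lambda_balance target ratio of regularizer to data gradient norms
#'   used by the auto-balancing.
#' @param epsilon TV smoothing constant ((1/mm)^2).
#' @param n0 photons per detector element for the count model.
#' @param n_iterations outer iterations (Gauss-Seidel sweeps over phases).
#' @param n_inner preconditioned gradient steps per phase within one sweep;
#'   neighbours are exchanged between sweeps, so more inner steps drive each
#'   phase sub-problem further per exchange.
#' @param max_backtracks Armijo halvings before a step is declared failed.
#' @param armijo_c sufficient-decrease constant.
#' @param seed integer seed (any stochastic option).
#' @return A `recon_config`.
#' @export
recon_config <- function(alpha = 1, beta = 0, gamma = 0,
                         lambda = NULL, lambda_balance = 0.0625,
                         epsilon = 1e-6, n0 = 1e5,
                         n_iterations = 12, n_inner = 1,
                         max_backtracks = 25,
                         armijo_c = 1e-4, seed = 1L) {
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop("regularizer weights must be >= 0")
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 lambda = lambda, lambda_balance = lambda_balance,
                 epsilon = epsilon, n0 = n0,
                 n_iterations = as.integer(n_iterations),
                 n_inner = as.integer(max(1, n_inner)),
                 max_backtracks = as.integer(max_backtracks),
                 armijo_c = armijo_c, seed = as.integer(seed)),
            class = "recon_config")
}

#' @rdname recon_config
#' @param method `"tvcs"`, `"piccs"` or `"tcgm"`.
#' @param ... overrides passed to [recon_config()].
#' @details The PICCS preset uses a stronger auto-balancing ratio (0.25)
#'   than TVCS/TCGM (0.0625): its prior-difference gradient vanishes at the
#'   initialization (the iterate equals the prior there), so the balance is
#'   measured against a term that only activates away from the prior, and
#'   the larger ratio keeps the prior constraint at the strength the method
#'   intends.
#' @export
recon_preset <- function(method = c("tvcs", "piccs", "tcgm"), ...) {
  method <- match.arg(method)
  w <- switch(method, tvcs = c(1, 0, 0), piccs = c(0.1, 0.9, 0),
              tcgm = c(0.1, 0, 0.9))
  bal <- if (method == "piccs") 0.25 else 0.0625
  do.call(recon_config,
          modifyList(list(alpha = w[1], beta = w[2], gamma = w[3],
                          lambda_balance = bal), list(...)))
}

#' Negative Poisson log-likelihood of the transmission data
#'
#' The mu-dependent part of the negative log-posterior data term,
#' `sum_i (n_i y*_i + n0 exp(-y*_i))` with `y* = A mu` and counts
#' `n_i = n0 exp(-y_i)` derived from the measured line integrals. Its
#' gradient with respect to mu is `A^T (n - n0 exp(-y*))`, which vanishes at
#' the noiseless optimum.
#'
#' @param volume a `volume_image`.
#' @param projections measured [projection_set()].
#' @param geometry the matching [make_geometry()].
#' @param n0 photons per element (defaults to the set's `n0`).
#' @param angle_subset optional view indices restricting the data term.
#' @param gradient also return the gradient volume.
#' @return The scalar value, or `(value, gradient)` when `gradient = TRUE`.
#' @export
neg_log_likelihood <- function(volume, projections, geometry, n0 = NULL,
                               angle_subset = NULL, gradient = FALSE) {
  if (any(!is.finite(projections$frames))) stop("non-finite projections")
  n0 <- n0 %||% projections$n0
  idx <- angle_subset %||% match_views(projections, geometry)
  if (dim(projections$frames)[3] != length(idx))
    stop("projection / view-subset mismatch")
  counts <- n0 * exp(-projections$frames)
  ystar <- forward_project(volume, geometry, idx, n0)$frames
  value <- sum(counts * ystar + n0 * exp(-ystar))
  if (!gradient) return(value)
  ctx <- list(idx = idx, basis = detector_basis(geometry, idx))
  grad <- back_raw(counts - n0 * exp(-ystar), volume, ctx, geometry)
  list(value = value, gradient = grad)
}

# --- internal solver machinery ------------------------------------------

# cached per-phase context: detector basis, counts, n0. `const` is the data
# term evaluated at the measured line integrals (its minimum for noiseless
# counts); subtracting it keeps the objective near zero at the optimum so
# small regularizer differences stay numerically resolvable.
phase_context <- function(projections, geometry, windows, n0) {
  lapply(windows, function(w) {
    y <- projections$frames[, , w, drop = FALSE]
    counts <- n0 * exp(-y)
    list(idx = w,
         basis = detector_basis(geometry, w),
         counts = counts, n0 = n0,
         const = sum(counts * y + n0 * exp(-y)))
  })
}

# Precomputed separable curvature of the Poisson transmission data term
# (paraboloid-surrogate style): D = A^T (n * (A 1)), the classic diagonal
# majorizer of A^T diag(n) A. Floored to its small quantile so voxels with
# little ray coverage still take bounded steps.
data_curvature <- function(ctx, grid, geometry) {
  ones <- array(1, dim(grid$values))
  a1 <- fwd_raw(ones, grid, ctx, geometry)
  d <- back_raw(ctx$counts * a1, grid, ctx, geometry)
  floor_val <- max(d) * 1e-5
  pmax(d, floor_val)
}

fwd_raw <- function(values, grid, ctx, geometry) {
  b <- ctx$basis
  raw <- cpp_siddon_forward(as_dbl(values), dim(values),
                            grid$voxel_size, grid$origin,
                            b$src, b$det0, b$eu, b$ev,
                            geometry$det_rows, geometry$det_cols)
  array(raw, c(geometry$det_rows, geometry$det_cols, length(ctx$idx)))
}

back_raw <- function(resid, grid, ctx, geometry) {
  b <- ctx$basis
  raw <- cpp_siddon_back(as_dbl(resid), dim(grid$values),
                         grid$voxel_size, grid$origin,
                         b$src, b$det0, b$eu, b$ev,
                         geometry$det_rows, geometry$det_cols)
  array(raw, dim(grid$values))
}

data_value <- function(ystar, ctx)
  sum(ctx$counts * ystar + ctx$n0 * exp(-ystar)) - ctx$const

# Pair coefficients of the global TCGM penalty Sum_p c_p TV(mu_p - mu_{p+1}).
# Normalized so interior phases see exactly the one-plus-one neighbour
# weighting of the per-phase chain term; boundary pairs are upweighted 1.5x
# (2x for T = 2), the closest single-potential analogue of the doubled
# one-sided boundary term (which is not the block gradient of any global
# objective on its own).
tcgm_pair_coeff <- function(T) {
  if (T < 2) return(numeric(0))
  p <- seq_len(T - 1)
  ((1 + (p == 1)) + (1 + (p == T - 1))) / 2
}

# regularizer value and gradient for the phase-t block of the global
# objective (neighbours fixed); gamma uses the consistent pair coefficients
reg_block <- function(vals, t, phases_vals, priors, cfg, pair_c) {
  g <- array(0, dim(vals)); val <- 0
  if (cfg$alpha > 0) {
    r <- tv_value_grad(vals, cfg$epsilon, TRUE)
    val <- val + cfg$alpha * r$value
    g <- g + cfg$alpha * r$gradient
  }
  if (cfg$beta > 0) {
    r <- tv_value_grad(vals, cfg$epsilon, TRUE, b = priors[[t]])
    val <- val + cfg$beta * r$value
    g <- g + cfg$beta * r$gradient
  }
  if (cfg$gamma > 0) {
    T <- length(phases_vals)
    if (t > 1) {
      r <- tv_value_grad(vals, cfg$epsilon, TRUE, b = phases_vals[[t - 1]])
      val <- val + cfg$gamma * pair_c[t - 1] * r$value
      g <- g + cfg$gamma * pair_c[t - 1] * r$gradient
    }
    if (t < T) {
      r <- tv_value_grad(vals, cfg$epsilon, TRUE, b = phases_vals[[t + 1]])
      val <- val + cfg$gamma * pair_c[t] * r$value
      g <- g + cfg$gamma * pair_c[t] * r$gradient
    }
  }
  list(value = val, gradient = g)
}

# value-only version used during backtracking
reg_block_value <- function(vals, t, phases_vals, priors, cfg, pair_c) {
  val <- 0
  if (cfg$alpha > 0) val <- val + cfg$alpha * tv_value_grad(vals, cfg$epsilon)$value
  if (cfg$beta > 0)
    val <- val + cfg$beta *
      tv_value_grad(vals, cfg$epsilon, b = priors[[t]])$value
  if (cfg$gamma > 0) {
    T <- length(phases_vals)
    if (t > 1) val <- val + cfg$gamma * pair_c[t - 1] *
        tv_value_grad(vals, cfg$epsilon, b = phases_vals[[t - 1]])$value
    if (t < T) val <- val + cfg$gamma * pair_c[t] *
        tv_value_grad(vals, cfg$epsilon, b = phases_vals[[t + 1]])$value
  }
  val
}

#' MAP iterative multi-phase reconstruction
#'
#' Minimizes, per phase, the Poisson transmission data term plus
#' `lambda * (alpha TV + beta PIC + gamma TCGM)` under a nonnegativity
#' constraint, by diagonally preconditioned projected gradient descent
#' (separable-curvature majorizer of the Poisson data term) with Nesterov
#' momentum, a monotone restart safeguard, and step backtracking. For
#' `gamma > 0` all phases are
#' updated within the same outer iteration (Gauss-Seidel sweep t = 1..T),
#' so each phase is constrained by the latest available neighbour iterates;
#' the temporal penalty uses pair coefficients consistent with a single
#' global objective, whose recorded value is non-increasing across outer
#' iterations. Deterministic for a fixed configuration.
#'
#' @param projections measured [projection_set()] (line integrals).
#' @param binning a [assign_phases()] phase binning.
#' @param geometry the matching [make_geometry()].
#' @param config a [recon_config()].
#' @param initial initial [time_series_image()] or list of `volume_image`s,
#'   one per phase.
#' @param prior prior volume (or per-phase list) required when `beta > 0`.
#' @return A `time_series_image` with attributes `objective` (per-outer-
#'   iteration global objective), `lambda` (strength used) and `converged`
#'   (`FALSE` if any phase exhausted its backtracking budget).
#' @export
reconstruct_iterative <- function(projections, binning, geometry, config,
                                  initial, prior = NULL) {
  cfg <- config
  phases0 <- if (inherits(initial, "time_series_image")) initial$phases else initial
  T <- binning$n_phases
  if (length(phases0) != T) stop("initial series does not match binning")
  if (cfg$beta > 0 && is.null(prior)) stop("beta > 0 requires a prior image")
  grid <- phases0[[1]]
  priors <- if (is.null(prior)) NULL
            else if (inherits(prior, "volume_image"))
              rep(list(prior$values), T)
            else lapply(prior, as_vol_values)
  phases <- lapply(phases0, function(p) pmax(as_vol_values(p), 0))
  ctxs <- phase_context(projections, geometry, binning$windows, cfg$n0)
  pair_c <- tcgm_pair_coeff(T)

  # current forward projections and data values per phase
  ystars <- vector("list", T)
  dvals <- numeric(T)
  for (t in seq_len(T)) {
    ystars[[t]] <- fwd_raw(phases[[t]], grid, ctxs[[t]], geometry)
    dvals[t] <- data_value(ystars[[t]], ctxs[[t]])
  }

  lambda <- cfg$lambda
  if (is.null(lambda)) {
    gd_norm <- gr_norm <- 0
    for (t in seq_len(T)) {
      resid <- ctxs[[t]]$counts - ctxs[[t]]$n0 * exp(-ystars[[t]])
      gd <- back_raw(resid, grid, ctxs[[t]], geometry)
      rb <- reg_block(phases[[t]], t, phases, priors, cfg, pair_c)
      gd_norm <- gd_norm + sqrt(sum(gd^2))
      gr_norm <- gr_norm + sqrt(sum(rb$gradient^2))
    }
    lambda <- if (gr_norm > 0) cfg$lambda_balance * gd_norm / gr_norm else 1
  }

  global_objective <- function() {
    # sum of per-phase tcgm terms == pair_c-weighted pair sum; reg_block_value
    # over all t double-counts pairs exactly by pair_c construction, so
    # evaluate pairs directly
    val <- sum(dvals)
    for (t in seq_len(T)) {
      if (cfg$alpha > 0)
        val <- val + lambda * cfg$alpha * tv_value_grad(phases[[t]], cfg$epsilon)$value
      if (cfg$beta > 0)
        val <- val + lambda * cfg$beta *
          tv_value_grad(phases[[t]], cfg$epsilon, b = priors[[t]])$value
    }
    if (cfg$gamma > 0 && T >= 2)
      for (p in seq_len(T - 1))
        val <- val + lambda * cfg$gamma * pair_c[p] *
          tv_value_grad(phases[[p]], cfg$epsilon, b = phases[[p + 1]])$value
    val
  }

  obj_log <- numeric(0)
  converged <- TRUE
  # diagonal preconditioner: data curvature (one fwd/back per phase) plus
  # the majorizer curvature of the smoothed-TV terms (each voxel enters at
  # most 6 difference terms of curvature <= 1/sqrt(eps) per unit weight)
  precond <- lapply(seq_len(T), function(t) {
    gamma_w <- 0
    if (cfg$gamma > 0 && T >= 2) {
      if (t > 1) gamma_w <- gamma_w + pair_c[t - 1]
      if (t < T) gamma_w <- gamma_w + pair_c[t]
    }
    reg_curv <- lambda * 6 * (cfg$alpha + cfg$beta + cfg$gamma * gamma_w) /
      sqrt(cfg$epsilon)
    data_curvature(ctxs[[t]], grid, geometry) + reg_curv
  })
  steps <- rep(1, T)                     # ~Newton scale under the majorizer
  mu_prev <- phases                      # momentum memory
  tks <- rep(1, T)

  for (it in seq_len(cfg$n_iterations)) {
    # the last 10% of sweeps run without momentum so the coupled
    # Gauss-Seidel iteration settles instead of carrying velocity
    settling <- it > 0.9 * cfg$n_iterations
    for (t in seq_len(T)) {
      for (inner in seq_len(cfg$n_inner)) {
        ctx <- ctxs[[t]]
        mu <- phases[[t]]
        f_mu <- dvals[t] +
          lambda * reg_block_value(mu, t, phases, priors, cfg, pair_c)

        # heavy-ball step: preconditioned gradient at the current iterate
        # (forward projection cached) plus a momentum term, with a monotone
        # safeguard that first drops the momentum, then backtracks the step
        g <- back_raw(ctx$counts - ctx$n0 * exp(-ystars[[t]]), grid, ctx,
                      geometry) +
          lambda * reg_block(mu, t, phases, priors, cfg, pair_c)$gradient
        if (max(abs(g)) == 0) next
        dirn <- g / precond[[t]]
        if (settling) tks[t] <- 1
        tkn <- (1 + sqrt(1 + 4 * tks[t]^2)) / 2
        beta <- (tks[t] - 1) / tkn
        vel <- if (beta > 0) beta * (mu - mu_prev[[t]]) else 0

        s <- min(2 * steps[t], 4)        # grow the warm-started step
        accepted <- FALSE
        momentum_on <- beta > 0
        for (bt in seq_len(cfg$max_backtracks)) {
          trial <- pmax(mu - s * dirn + (if (momentum_on) vel else 0), 0)
          if (max(abs(trial - mu)) == 0) { accepted <- TRUE; break }
          ytrial <- fwd_raw(trial, grid, ctx, geometry)
          ftrial <- data_value(ytrial, ctx) +
            lambda * reg_block_value(trial, t, phases, priors, cfg, pair_c)
          if (ftrial < f_mu) {           # monotone safeguard
            mu_prev[[t]] <- mu
            phases[[t]] <- trial
            ystars[[t]] <- ytrial
            dvals[t] <- data_value(ytrial, ctx)
            steps[t] <- s
            tks[t] <- if (momentum_on) tkn else 1
            accepted <- TRUE
            break
          }
          if (momentum_on) momentum_on <- FALSE else s <- s / 2
        }
        if (!accepted) {
          converged <- FALSE             # keep last iterate for this phase
          tks[t] <- 1
        }
      }
    }
    obj_log <- c(obj_log, global_objective())
  }

  out_phases <- lapply(phases, function(v) {
    p <- grid; p$values <- v; p
  })
  res <- time_series_image(out_phases,
                           prior = if (!is.null(priors)) {
                             p <- grid; p$values <- priors[[1]]; p
                           })
  attr(res, "objective") <- obj_log
  attr(res, "lambda") <- lambda
  attr(res, "converged") <- converged
  res
}

#' Phase-block MAP objective and gradient
#'
#' Value and gradient, with respect to the phase-`t` volume, of the global
#' MAP objective restricted to that block (data term of the phase window
#' plus `lambda * (alpha TV + beta PIC + gamma x temporal pairs)` with the
#' neighbours held fixed). Primarily a diagnostic for gradient checking.
#'
#' @inheritParams reconstruct_iterative
#' @param series current [time_series_image()] or list of volumes.
#' @param t phase index.
#' @param lambda regularization strength (no auto-balancing here).
#' @return A list `(value, gradient)`.
#' @export
map_objective <- function(series, t, projections, binning, geometry, config,
                          prior = NULL, lambda = 1) {
  cfg <- config
  phases <- if (inherits(series, "time_series_image")) series$phases else series
  phases <- lapply(phases, as_vol_values)
  T <- binning$n_phases
  grid <- if (inherits(series, "time_series_image")) series$phases[[1]]
          else series[[1]]
  priors <- if (is.null(prior)) NULL
            else if (inherits(prior, "volume_image")) rep(list(prior$values), T)
            else lapply(prior, as_vol_values)
  ctx <- phase_context(projections, geometry, binning$windows, cfg$n0)[[t]]
  pair_c <- tcgm_pair_coeff(T)
  ystar <- fwd_raw(phases[[t]], grid, ctx, geometry)
  resid <- ctx$counts - ctx$n0 * exp(-ystar)
  gd <- back_raw(resid, grid, ctx, geometry)
  rb <- reg_block(phases[[t]], t, phases, priors, cfg, pair_c)
  list(value = data_value(ystar, ctx) + lambda * rb$value,
       gradient = gd + lambda * rb$gradient)
}
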