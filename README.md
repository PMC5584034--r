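# tcgm4d

Time-ordered 4D cone-beam CT (CBCT) reconstruction for **non-periodic**
organ motion, with the comparator methods needed to evaluate it.

Slow-rotating, linac-mounted CBCT cannot phase-sort non-periodic motion
(rectal gas, peristalsis, baseline drift): each time phase of the single
rotation contributes only a narrow angular arc, far below the 180° + fan
angle needed by analytic reconstruction. `tcgm4d` reconstructs such phase
series by maximum-a-posteriori (MAP) Poisson transmission tomography,

```
mu_t = argmin_{mu >= 0}  sum_i [ n_i y*_i + n0 e^{-y*_i} ]  +  lambda R(mu_t),
y* = A mu,   n_i = n0 e^{-y_i},
```

with three interchangeable regularizers:

| method | R(mu) | window |
|--------|-------|--------|
| TVCS   | `alpha ‖Ψ mu‖₁` | 200° |
| PICCS  | `alpha ‖Ψ mu‖₁ + beta ‖Ψ(mu − mu_prior)‖₁` | 90° |
| TCGM   | `alpha ‖Ψ mu‖₁ + gamma (‖Ψ(mu_t − mu_{t−1})‖₁ + ‖Ψ(mu_t − mu_{t+1})‖₁)` | 90° |

`Ψ` is the smoothed total-variation transform. The **time-ordered chain
graph model (TCGM)** couples every phase to its temporal neighbours and
updates all phases concurrently (Gauss–Seidel sweeps), so the constraint
follows the evolving reconstruction instead of a fixed prior; boundary
phases count their single neighbour twice. Weights are
`(alpha, beta, gamma)` = (1, 0, 0), (0.1, 0.9, 0), (0.1, 0, 0.9).

The package also provides: a Siddon ray-driven cone-beam projector with
exact adjoint (Rcpp), FDK filtered backprojection, contiguous-window phase
binning, a moving-sphere digital phantom simulator, offset-detector
projection extension (the 512 → 800 column mosaic procedure), and the two
evaluation metrics — the 10–90% penumbral width of the moving air cavity
(a temporal-resolution surrogate) and ROI mean-value consistency RMSE.

## Worked example

Reconstruct the moving-sphere phantom (3 cm air sphere travelling 3 cm
along the rotation axis during a 60 s scan) at the mini problem size and
compare temporal resolution:

```r
library(tcgm4d)
res <- run_phantom_experiment(speed = "60s", scale = "mini", seed = 1)
res$widths[, c("method", "window_deg", "width_mm")]
```

```
  method window_deg width_mm
1    fdk        360 23.07380
2   tvcs        200 18.27580
3  piccs         90 16.59862
4   tcgm         90 12.86847
```

The full-rotation FDK image blurs the cavity edge to about the analytic
time-occupancy width (0.8 × 30 mm = 24 mm, less edge effects); TVCS
narrows it to roughly the 200°-window blur; PICCS (90° data, TVCS prior)
is slightly narrower; TCGM, whose constraint tracks the moving neighbours
instead of a static prior, is narrowest — the ordering that motivates the
method. `narrowing_percent()` expresses the improvement relative to TVCS.

Lower-level pieces compose explicitly:

```r
g    <- geometry_preset("scaled")            # 90 views, 48x168 panel
spec <- phantom_preset("60s", "scaled")      # 128x128x56 grid
proj <- simulate_phantom_scan(g, spec)       # noiseless line integrals
fdk  <- reconstruct_fdk(proj, g, volume_template(spec$grid_dims, spec$voxel_size))
bins <- assign_phases(proj, n_phases = 9, window_extent = 90)
cfg  <- recon_preset("tcgm")
ser  <- reconstruct_iterative(proj, bins, g, cfg,
                              initial = rep(list(fdk), 9))
penumbral_width(ser$phases[[5]], background_mu = 0.02)
```

A thin command-line front end (`exec/tcgm4d`) exposes the verbs
`simulate`, `fdk`, `bin`, `extend`, `tvcs`, `piccs`, `tcgm`, `evaluate`
and `run` (YAML-configured pipeline; see
`inst/extdata/phantom_scaled.yaml`).

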