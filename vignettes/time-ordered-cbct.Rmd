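---
title: "Time-ordered 4D cone-beam CT reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-ordered 4D cone-beam CT reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cone-beam CT scanners mounted on radiotherapy gantries rotate slowly (about
6°/s, one minute per revolution). Anatomy that moves *non-periodically*
during the scan — rectal gas, peristalsis, a drifting tumour baseline —
cannot be handled by respiratory-style phase sorting, because no motion
signal exists and no projection angle is ever revisited. The only way to
resolve such motion is to split the single rotation into consecutive time
phases and reconstruct each phase from the narrow angular arc acquired
during it. An arc far below 180° plus the fan angle (about 200° here) is
hopelessly underdetermined for analytic reconstruction, so the missing
information must come from a prior.

`tcgm4d` implements and compares three choices of that prior inside one
maximum-a-posteriori (MAP) framework:

* **TVCS** — total-variation compressed sensing: the phase image itself is
  assumed piecewise smooth, `R(mu) = ||Psi mu||_1`, where `Psi` is the local
  spatial gradient and the l1-norm is the smoothed TV.
* **PICCS** — prior-image constrained compressed sensing:
  `R(mu) = alpha ||Psi mu||_1 + beta ||Psi(mu - mu_prior)||_1`, with a fixed
  prior image reconstructed beforehand from a wide arc.
* **TCGM** — the time-ordered chain graph model: each phase is coupled to
  its temporal neighbours,
  `R(mu_t) = alpha ||Psi mu_t||_1 + gamma (||Psi(mu_t - mu_{t-1})||_1 +
  ||Psi(mu_t - mu_{t+1})||_1)`, and all phases are updated concurrently so
  the coupling always refers to the latest iterates. At the first and last
  phases the single available difference is counted twice.

The weights are `(alpha, beta, gamma) = (1, 0, 0)`, `(0.1, 0.9, 0)` and
`(0.1, 0, 0.9)` for TVCS, PICCS and TCGM respectively.

## Data model and objective

Measured line integrals `y` relate to photon counts by `n_i = n0 e^{-y_i}`,
and the expected counts under an image `mu` are `n*_i = n0 e^{-y*_i}` with
`y* = A mu`, where `A` is the system matrix of exact ray/voxel intersection
lengths (single ray to each detector cell center, Siddon traversal, exact
adjoint). Counts are Poisson, so up to `mu`-independent constants the
negative log-posterior is

```
F(mu) = sum_i [ n_i y*_i + n0 e^{-y*_i} ]  +  lambda R(mu),   mu >= 0.
```

Each method minimizes this per phase over its angular window.

## Optimizer

The source publications of these regularizers leave the optimizer
unspecified; this package uses diagonally preconditioned projected gradient
descent with Nesterov momentum and a monotone safeguard. The
preconditioner is the classic separable (paraboloid-surrogate) majorizer
of the Poisson data Hessian, `D = A^T (n * (A 1))`, plus the majorizer
curvature of the smoothed-TV terms (each voxel enters at most six
difference terms of curvature `1/sqrt(epsilon)` per unit weight); with it,
unit steps are near-Newton for the data term. A momentum step that fails
to decrease the block objective triggers a restart and a backtracked plain
step, so the recorded objective is non-increasing by construction; the
final 10% of sweeps run without extrapolation so the coupled phases settle
rather than carry momentum velocity. The TV smoothing constant `epsilon`
(default `1e-6 (1/mm)^2`, about `(0.05 body_mu)^2` per voxel difference)
keeps the objective differentiable without making the flat-region
curvature needlessly stiff.

Two details deserve a note:

* **A consistent global TCGM objective.** The per-phase chain term with its
  doubled boundary rule is not the block gradient of any single potential:
  phase 1 weights the (1,2) difference twice while phase 2 weights it once.
  The optimizer therefore minimizes a single global pairwise penalty
  `sum_p c_p ||Psi(mu_p - mu_{p+1})||_1`, with the coefficients normalized
  so interior phases see exactly the one-plus-one neighbour weighting of
  the chain term: `c = (1.5, 1, ..., 1, 1.5)` (and `c = 2` for two
  phases), i.e. boundary pairs are upweighted as the closest
  single-potential analogue of the doubled one-sided boundary term. Each
  Gauss–Seidel block update performs safeguarded descent on its exact
  restriction of this global objective, so the logged objective decreases
  monotonically — an invariant the test suite asserts on every run. The
  exported `tcgm_term()` keeps the per-phase definition; only the solver
  uses the pair coefficients.
* **Sweep order.** Phases are updated `t = 1..T` within each outer
  iteration, so each phase sees the already-updated previous phase and the
  not-yet-updated next phase; this propagates temporal information fastest
  and is deterministic.

`lambda` is likewise unstated in the source work. By default it is
auto-balanced against the data gradient at the initial iterate:
`lambda * ||grad R|| = ratio * ||grad F_data||` (mean over phases). The
default ratio is 1/16 for TVCS and TCGM — noiseless data should dominate,
with the regularizer resolving the null space of the narrow arc — and 1/4
for PICCS, whose prior-difference gradient vanishes identically at the
initialization (the iterate equals the prior there), so its balance is
measured against a term that only activates away from the prior and a
larger ratio is needed to keep the prior constraint at the strength the
method intends. These ratios were calibrated once by a sensitivity scan on
the 3 cm/60 s phantom (the strong-coupling regime visibly fuses the phase
chain into a time-average, the weak-prior regime turns PICCS into plain
narrow-arc reconstruction; both extremes contradict the methods'
construction). The chosen `lambda` is recorded on every result
(`attr(res, "lambda")`) and can be overridden.

## The digital phantom

`phantom_spec()` describes an elliptic cylinder (semi-axes 110 × 80 mm,
attenuation 0.02/mm, consistent with the display window 0.019–0.022/mm
used for such images) containing a 3 cm air sphere that translates 3 cm
along the rotation axis at constant speed. Two speeds are provided:
3 cm/60 s (motion during the whole rotation, 0.5 mm/s) and 3 cm/30 s
(motion between the 90° and 270° source positions, 1 mm/s). Projections
are noiseless line integrals on a 360° schedule; scatter, spectra,
detector aperture and deformation are deliberately outside the model, so
passing tests demonstrate correctness of the reconstruction chain, not
robustness to clinical physics.

Voxelization is by center sampling, which keeps the projector the exact
oracle for the simulation. The simulator computes the static-body
projections once and adds the projection of the sphere-difference
sub-volume per view — exact by linearity, and verified against the direct
per-view voxelization in the tests.

Geometry defaults (never stated with the phantom in the source
description) are SAD = 1000 mm, SDD = 1536 mm, 512 × 512 detector at
0.8 mm pitch — typical values for the Elekta XVI family the acquisition
schedule mimics — with lateral panel offsets of 0/115/190 mm for the
S/M/L fields of view.

## Temporal-resolution metric

The blurred edge of the moving cavity is quantified by the 10–90%
penumbral width of the inverted, normalized voxel profile along the
central axis, with sub-voxel linear interpolation of the crossings. A
cavity has two edges; the package reports their mean and retains both. The
closed-form time-occupancy of the moving sphere gives an independent
oracle: uniform motion over extent `L <= 2R` produces a trapezoidal
occupancy profile whose 10–90% width is exactly `0.8 L` (24 mm for the
3 cm / full-rotation case), which the full-rotation FDK reconstruction
must approach.

The ROI consistency metric for multi-phase series is the RMS deviation of
per-phase ROI means from a reference ROI mean, in percent of the
reference. ROIs are rasterized discs specified by pixel count (316 pixels
at radius ≈ 10.03 px for a corner-centered disc).

## Problem sizes

Three presets share the same physics and differ only in sampling:

| preset | grid (voxels) | voxel (mm) | detector | views |
|--------|---------------|------------|----------|-------|
| `full` | 256×256×72 | 1×1×1 | 512×512 @ 0.8 mm | 360 × 1° |
| `scaled` | 128×128×56 | 2×2×1.25 | 48×168 @ 2.5 mm | 90 × 4° |
| `mini` | 64×64×40 | 3.6×3.6×1.875 | 32×104 @ 4.0 mm | 90 × 4° |

The default experiment, the acceptance script and the end-to-end ordering
checks in the test suite use `scaled` (`mini` reproduces the orderings for
the slow sphere but its 90°-window data are too coarse to erase the
initialization's motion tails in the fast-sphere case); `full` is used for
the analytic FDK blur check and available for the complete experiment. One deliberate deviation from the 60-slice
source grid: all grids extend about 70 mm axially, because the 3 cm sphere
moving 3 cm blurs the cavity across exactly ±30 mm, putting the 10%
crossings (±27 mm) inside the cone-beam edge-artifact zone of a 60 mm
grid; the extra slices keep the measurement region artifact-free without
touching any other condition.

Default iteration counts (10 TVCS initialization, 24 refinement sweeps)
were set where the objective decrease and the measured widths approach
their plateau at the default problem sizes with the preconditioned
momentum solver; both are configurable, and slow-motion cases benefit from
more refinement sweeps.

## Truncated (offset-detector) acquisitions

Offset-panel scans truncate every projection on one side. Before TVCS
initialization such data are extended in three steps: (1) full-scan FDK of
the whole object from the truncated projections, using a smooth Wang-type
redundancy weight over the doubly-sampled central band; (2) reprojection
of that volume onto a widened virtual panel (800 columns for the 512-column
clinical panel); (3) a mosaic keeping measured values bit-exactly where the
real panel covers and reprojected values in the peripheral band, with a
5-column linear cross-fade on the virtual side of each seam. The seam
treatment and the step-1 redundancy weight are this package's choices; the
three-step structure is fixed.

## Numerical choices and degenerate inputs

* Ramp filtering uses the exact band-limited discrete kernel, zero-padded
  to the next power of two, with Hann apodization by default (the source
  work states no filter; widths shift by about one voxel between Hann and
  pure Ram-Lak).
* Siddon corner ties advance the axis with the smaller parametric step
  (x before y before z on exact equality) — deterministic.
* A backtracking line search that exhausts its budget leaves the phase at
  its last iterate and flags the run (`attr(res, "converged") = FALSE`);
  the objective never increases.
* Negative FDK values are clipped to zero before use as attenuation or as
  an iterative initializer.
* `beta > 0` without a prior image, non-monotonic timestamps, SDD ≤ SAD,
  spheres that do not fit the cylinder, and windows wider than the
  acquisition all raise configuration errors.

## Known limitations

* The PICCS prior here is the same-phase TVCS image (a per-phase prior
  list), matching the two-step workflow the comparator methods describe;
  a single global prior volume is also accepted.
* Reported phantom widths at the `scaled` size carry discretization blur
  of roughly one voxel plus detector aperture; they are compared against
  the analytic oracle and for their ordering, not digit-for-digit.
* Hyperparameters (`lambda`, iterations) materially affect absolute
  widths; the relative ordering TCGM < PICCS < TVCS < FDK is the robust
  observable.
* No scatter, beam hardening, detector blur or deformable motion — by
  design.
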