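---
title: "Hyoid kinematics and two-group functional regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyoid kinematics and two-group functional regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During a swallow the hyoid bone moves backward-upward, then forward-upward,
then returns — a loop whose horizontal (anterior) extent opens the upper
esophageal sphincter. In post-stroke dysphagia, reduced forward hyoid motion
and an altered early motion direction are candidate markers of poor
swallowing recovery. The package implements the full quantitative pathway
from raw videofluoroscopy (VFSS) landmark tracks to that comparison:

1. **geometry** — pixel landmarks to millimetres in an anatomical frame;
2. **kinematics** — swallow-window detection, temporal normalization,
   velocity, direction angle, discrete summary parameters;
3. **fda** — penalized B-spline smoothing with GCV selection;
4. **flr** — two-group function-on-scalar regression with pointwise bands;
5. **cohort_stats** — conventional two-sample and categorical tests;
6. **synthetic** — a calibrated cohort generator providing ground truth.

Because no per-subject trajectory data are publicly deposited for this
design, the synthetic generator *is* the study population here: every
empirical claim in the tests is a claim about pipeline behaviour on that
generator, not about patients.

## Anatomical frame and scaling

Each frame's transform maps the C4 anteroinferior vertex to the origin and
the C2 anteroinferior vertex onto the positive vertical (superior) axis; the
anterior (+x) side is resolved from a hint point (the first hyoid sample,
which lies anterior to the vertebrae in a lateral view) and that chirality
is then held fixed for the whole recording. Building the transform *per
frame* removes rigid neck motion image by image; the package verifies
invariance of the output to arbitrary per-frame rigid motions of all three
landmarks jointly (to 1e-9 mm) and to uniform pixel rescaling matched by the
coin calibration (23.5 mm reference coin; `mm_per_px = coin_mm / coin_px`).
Pixel y-axis convention is declared per file (default image-down) because
fluoroscopy exports differ. A `reference_frame` option applies one fixed
transform instead, for data where per-frame vertebral tracking is
unreliable.

## Swallow window

The start of the swallow is the point where the hyoid leaves its lowest
pre-peak resting position; the end is the termination of motion after the
swallow. With landmark jitter, frame-to-frame *speed* near onset is
dominated by noise, so detection uses the displacement envelope instead:
positions are lightly smoothed (3-point moving average), the start is the
last pre-motion frame whose displacement from the resting point stays within
the estimated jitter floor (a robust MAD estimate from the pre-motion
segment), and the end is the first post-swallow frame whose displacement
from the final resting position falls back under that floor. The
`speed_threshold` (default 10 mm/s) still gates whether any motion exists
(detection fails with an instruction to annotate manually), and a `manual`
window always wins. Two consequences are documented rather than hidden:
onset is intrinsically undetectable while true motion is below the jitter
floor, so detected windows exclude a short sub-noise ramp at both ends, and
detected durations are accordingly slightly shorter than the generator's
nominal swallow durations.

## Normalization, velocity, direction angle

The window is linearly interpolated onto the percentile grid 0, 1, ..., 100
(101 points), after rebasing so the start point is exactly (0, 0). Velocity
uses the symmetric difference quotient, `v(t) = (d(t+1) - d(t-1)) / 2`, with
one-sided differences at the endpoints; units are mm per percentile of
normalized swallow time. The direction angle is the two-argument arctangent
of `(vel_y, vel_x)` in degrees on `[0, 360)`; where the speed is below a
floor (1e-6 mm/percentile — zero velocity has no direction) the angle is
undefined and excluded from averages. The early phase is the 5th–20th
percentile; its mean angle uses the arithmetic mean by default, because
early-phase motion is confined to the backward-upward quadrant where the
arithmetic and circular means agree; a circular option exists. Summary
extrema (signed maximal displacements and velocities and their grid times)
break ties toward the earliest grid point and are computed from the *raw*
gridded profiles; the smoothed representation is used for the functional
regression. Discrete summaries from noisy raw profiles carry a small upward
max-bias (max over jittered points), quantified below.

## Penalized smoothing and GCV

Profiles are represented as `X(t) = sum_k c_k phi_k(t)` over order-4
(cubic) B-splines with equally spaced interior knots, fitted by minimizing
`sum_j [W(t_j) - X(t_j)]^2 + lambda * int X''(t)^2 dt`. The penalty matrix
is computed exactly by Gauss–Legendre quadrature per knot span; coefficients
come from QR on the penalty-augmented least-squares system (stable even for
a saturated basis at `lambda = 0`, which interpolates; `lambda -> Inf`
yields the least-squares straight line, the penalty's null space). GCV is
`n * RSS / (n - df)^2` with `df` the smoothing-matrix trace; a saturated fit
returns an infinite sentinel. One `(K, lambda)` pair per signal type is
chosen cohort-wide by mean GCV over the default grids `K in {8, 12, 16, 20}`
and `lambda` log-spaced 1e-4..1e6 (11 points), ties broken toward the
smoother model (larger lambda, then smaller K). Selected values are logged
per signal; on the default synthetic cohort the selection is typically
`K = 20` with `lambda` between 1 and 100.

## Two-group functional regression

With reference coding (good prognosis as reference) the model
`y_i(t) = Z_i1 beta_ref(t) + Z_i2 beta_diff(t) + eps_i(t)` is fitted by OLS
at each grid point; in this one-way layout `beta_diff(t)` equals the
pointwise poor-minus-good mean difference exactly, which the tests use as an
oracle. The residual variance function is `RSS(t) / (n - 2)` and the 95%
band uses the normal critical value 1.96 by default (a `use_t` switch gives
`t(n - p)` quantiles). Significant intervals are maximal runs of grid points
whose band excludes zero; no multiplicity correction is applied across the
grid — the bands are deliberately pointwise, not family-wise, and runs as
short as one or two grid points are reported. Under the null (both groups
from one smooth mean plus iid noise) the flagged fraction of the grid
averages about 5.5% over 500 simulated cohorts, against the 5% nominal
pointwise rate.

## The synthetic cohort generator

Each subject's trajectory is a three-bump template in the anatomical frame:
`x(t) = -B g(t; 16, 6) + F g(t; 49, 16)` and `y(t) = U g(t; 34, 8)` on the
percentile axis, with `g` a Gaussian bump tapered to zero at 0 and 100 by a
C2 smoothstep (a chord-subtracted Gaussian was rejected because its negative
lobe corrupts amplitude calibration). Bump centers sit at the reference cohort's
group-mean times to maximal backward/forward/upward displacement; widths
were calibrated once, before any acceptance measurement, so that the
noise-free group templates reproduce the reference early-phase direction
angles (119.2 degrees good, 96.5 poor), and then frozen.

Group distributions (mean/SD, truncated at zero) follow the reference
cohort: forward amplitude 12.43/4.81 mm good vs 9.22/3.95 poor; upward
15.37/7.14 vs 16.81/7.10; swallow duration 1.76/0.45 s vs 1.89/0.47;
30 frames/s; 0.3 s quiescent lead-in and tail. The one deliberately
uncalibrated moment is the poor group's backward amplitude: the
direction-angle contrast is induced by scaling backward motion down relative
to vertical (mean 1.02 mm, SD 1.14, preserving the coefficient of
variation), so the poor group's realized backward displacement (about
-1.2 mm) deviates from the reference -3.01 mm. With the shared forward-bump
tail overlapping the backward phase, the good group's realized maximal
backward displacement is about -2.2 mm rather than -3.49. Rendering places
C2/C4 at fixed anatomical offsets (35 mm vertebral axis), applies a slow
rigid neck drift (rotation/translation random walks, 0.05 deg and 0.2 px
per frame), converts to image pixels (y down, 0.5 mm/px) and adds iid
Gaussian landmark jitter (0.5 px). All draws are deterministic under the
config seed, and the same standard-normal stream is consumed regardless of
noise settings, so noise-on and noise-off cohorts are pathwise comparable.

What the generator does *not* emulate: per-subject phase-timing jitter (all
subjects share the template bump centers; reference time-to-max SDs arise
only through noise and window variation), bolus-property variation,
correlated tracking error (real tracking drift is smooth, not iid), and any
biomechanics. Passing tests therefore show pipeline correctness and
calibration recovery, not clinical validity.

## Known numerical behaviour and limitations

- Linear interpolation of 30 fps samples onto the percentile grid quantizes
  the sharpest template phase at the ~0.2 mm level; ground-truth recovery is
  therefore asserted at machine precision against the frame-level noise-free
  path and at 0.25 mm against the gridded template.
- The raw-path maximal forward displacement carries a ~+0.3 mm max-bias
  under default jitter; across 200 replicate cohorts the recovered
  good-group mean is about 12.9 mm against the calibrated 12.43.
- Raw-path early-phase direction angles are noise-dominated when true early
  speeds are small (especially the poor group, whose backward motion is
  weak); angle means are pulled toward 180 degrees relative to the
  noise-free template values. The smoothed path (used by the functional
  regression) is the reliable route for direction-angle contrasts.
- Amplitude truncation at zero slightly raises realized means for
  low-mean/high-SD draws (material only for the poor group's backward
  amplitude).

## Problem sizes used by the test suite

Simulation-based checks use 18 subjects per group (the matched design),
500 replicate cohorts for null coverage, 200 for contrast recovery, 100
randomized trials for the geometric invariances, and 50 random cohorts for
the regression oracle identity; these sizes give Monte-Carlo standard
errors comfortably inside the asserted margins.
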