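# hyoidkin

Kinematic analysis of hyoid bone motion in videofluoroscopic swallowing
studies (VFSS), built for comparing two prognosis groups of post-stroke
dysphagia patients. The package takes per-frame pixel coordinates of three
tracked landmarks — the hyoid bone and the anteroinferior vertices of the
C2 and C4 vertebrae — plus a coin calibration, and carries them through:

1. **Anatomical frame**: a per-frame rigid transform with origin at C4 and
   vertical axis through C2 removes neck motion; a 23.5 mm reference coin
   scales pixels to millimetres.
2. **Kinematic profiles**: swallow-window detection, rebasing to the start
   point, temporal normalization onto the 0–100 percentile grid,
   symmetric-difference-quotient velocity `v(t) = (d(t+1) − d(t−1))/2`
   (mm/percentile), and the hyoid direction angle
   `atan2(v_y, v_x)` in degrees on [0, 360).
3. **Functional representation**: penalized B-spline smoothing
   `min Σ_j [W(t_j) − X(t_j)]² + λ∫X''(t)²dt` with `(K, λ)` selected by
   generalized cross-validation, `GCV = n·RSS/(n − df)²`.
4. **Function-on-scalar regression**:
   `y_i(t) = Z_i1 β_ref(t) + Z_i2 β_diff(t) + ε_i(t)` with reference coding
   (good prognosis = reference), pointwise 95% confidence bands for
   `β_diff(t)`, and extraction of the percentile intervals where the band
   excludes zero.
5. **Cohort tables**: group mean ± SD with independent-sample t or
   Mann–Whitney U tests for continuous summaries, chi-square or Fisher
   exact tests for categorical variables.

Since no raw patient trajectories are publicly available for this design, a
calibrated synthetic-cohort generator (three-bump swallow template, group
moments matched to the reference cohort statistics, rigid neck drift,
landmark jitter) provides inputs and ground truth for every stage.

## Worked example

The `analysis/` scripts run the full workflow on a synthetic cohort of
18 + 18 subjects (seed 1) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract_kinematics.R
Rscript analysis/03_functional_regression.R
Rscript analysis/04_group_tables.R
```

which prints, among other lines:

```
  good: max forward 13.55 +/- 4.12 mm, duration 1.87 s
  poor: max forward 9.41 +/- 3.82 mm, duration 1.74 s
disp_x  K = 20, lambda = 1        significant: 4-22, 41-84
disp_y  K = 20, lambda = 1        significant: 5-26
angle   K = 20, lambda = 100      significant: 4-14
Recommended tube feeding (1/18 vs 14/18): Fisher p = 2e-05
        parameter mean_good sd_good mean_poor sd_poor        p        test
    max_forward_x    13.549  4.1218     9.411  3.8174 0.003623           t
```

Reading this: the poor-prognosis group's maximal forward (anterior) hyoid
displacement is reduced by ~4 mm (p = 0.004 by pooled t-test on this
replicate), and the horizontal-displacement coefficient function is
significantly below zero across the forward-motion percentiles (41–84),
with a second early interval (4–22) reflecting the groups' different
backward-phase geometry. The tube-feeding contingency test reproduces the
strong association between initial tube-feeding recommendation and poor
prognosis. Exact numbers vary with the simulation seed; the calibrated
targets are a 12.43 vs 9.22 mm forward contrast and early-phase direction
angles near 119° vs 96°.

The same machinery is available programmatically:

```r
library(hyoidkin)
co  <- generate_cohort(synthetic_cohort_config(seed = 1))
ex  <- run_extract(co)                 # geometry -> profiles -> summaries
an  <- run_analyze(ex)                 # smoothing, FLR, summary table
an$flr$disp_x                          # pointwise fit + significant intervals
```

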