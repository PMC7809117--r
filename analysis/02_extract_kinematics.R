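#!/usr/bin/env Rscript
# Stage 2: from raw landmark pixels to kinematic profiles. Each recording is
# converted to the C2-C4 anatomical frame (per-frame transform, coin scale),
# the swallow window is detected, displacement is rebased to the start point
# and normalized onto the 0-100 percentile grid, and velocity / direction
# angle / summary parameters are derived. Outputs one kinematics CSV per
# subject plus the cohort summary under results/kinematics/.

library(hyoidkin)

ex <- run_extract("results/cohort/manifest.csv",
                  out_dir = "results/kinematics")

cat("Extracted", sum(!vapply(ex$profiles, is.null, logical(1))),
    "of", length(ex$profiles), "subjects\n")
if (length(ex$errors)) {
  cat("  failures:\n")
  for (id in names(ex$errors)) cat("   ", id, "-", ex$errors[[id]], "\n")
}
s <- ex$summaries
for (g in unique(s$group)) {
  cat(sprintf("  %s: max forward %.2f +/- %.2f mm, duration %.2f s\n", g,
              mean(s$max_forward_x[s$group == g]),
              stats::sd(s$max_forward_x[s$group == g]),
              mean(s$duration_s[s$group == g])))
}
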