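#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study cohorts.
#
# Generates (a) a single-scan training cohort with a 1:2 benign:malignant
# ratio mirroring the study's class imbalance, and (b) a two-scan
# longitudinal cohort in which the benign class's texture noise drifts
# upward over follow-up. Writes the patient/ROI metadata under
# results/cohort/ and, when the tiff package is available, the ROI images
# as 16-bit grayscale TIFFs.

suppressPackageStartupMessages(library(curvecad))

seed <- 20260921L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cat("Simulating training cohort (14 benign, 26 malignant patients)...\n")
cohort <- gen_cohort(14, 26, rois_per_patient = c(3, 5), seed = seed)
cat(sprintf("  %d patients, %d ROIs\n", nrow(cohort$patients), nrow(cohort$rois)))

cat("Simulating longitudinal cohort (20 + 20 patients, 2 scans each)...\n")
lcohort <- gen_longitudinal_cohort(20, scans_per_patient = 2,
                                   seed = seed + 1L)
cat(sprintf("  %d patients, %d ROIs across repeat scans\n",
            nrow(lcohort$patients), nrow(lcohort$rois)))

if (requireNamespace("tiff", quietly = TRUE)) {
  write_cohort(cohort, file.path(out, "training"))
  write_cohort(lcohort, file.path(out, "longitudinal"))
  cat("Wrote images + metadata under", out, "\n")
} else {
  write.csv(cohort$patients, file.path(out, "training_patients.csv"),
            row.names = FALSE)
  write.csv(lcohort$patients, file.path(out, "longitudinal_patients.csv"),
            row.names = FALSE)
  cat("tiff package unavailable; wrote metadata only under", out, "\n")
}

cat("\nClass-conditional covariate summary (training cohort):\n")
pts <- cohort$patients
for (cls in c("benign", "malignant")) {
  sub <- pts[pts$label == cls, ]
  cat(sprintf("  %-9s n=%2d  age %.1f (sd %.1f)  smoking %.0f%%  male %.0f%%\n",
              cls, nrow(sub), mean(sub$age), sd(sub$age),
              100 * mean(sub$smoking), 100 * mean(sub$sex)))
}
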