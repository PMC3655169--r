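#!/usr/bin/env Rscript
# Stage 3: SMOTE class balancing.
#
# The simulated training table has roughly twice as many malignant as
# benign ROIs (the study's 2:1 imbalance). This stage over-samples the
# benign minority with synthetic interpolated rows until the classes are
# 1:1 and writes the balanced table with a provenance column.

suppressPackageStartupMessages(library(curvecad))

feat <- read.csv("results/training_features.csv")
meta <- c("roi_id", "patient_id", "scan_index", "label")
X <- as.matrix(feat[, setdiff(names(feat), meta)])

cat("Class counts before balancing:\n")
print(table(feat$label))

bal <- balance_dataset(X, feat$label, target = "match_majority", k = 5,
                       seed = 20260922L)

cat("Class counts after balancing:\n")
print(table(bal$y))
cat(sprintf("  %d original rows kept untouched, %d synthetic rows added\n",
            sum(bal$provenance == "original"),
            sum(bal$provenance == "synthetic")))

out <- data.frame(label = bal$y, provenance = bal$provenance,
                  as.data.frame(bal$X), check.names = FALSE)
write.csv(out, "results/balanced_features.csv", row.names = FALSE)
cat("Wrote results/balanced_features.csv\n")
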