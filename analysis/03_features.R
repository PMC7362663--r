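#!/usr/bin/env Rscript
# Stage 3: voxel-wise feature engineering.
#
# Builds the 110-column feature matrix (18 relative-DTI + 90 windowed
# histogram + 2 Mahalanobis placeholder columns) for every eligible voxel
# of both cohorts and writes them as CSV with the label column.

library(penumbra)

for (nm in c("lownoise", "contrast")) {
  proc <- readRDS(sprintf("results/processed_%s.rds", nm))
  feats <- assemble_feature_matrix(proc)
  utils::write.csv(feats, sprintf("results/features_%s.csv", nm),
                   row.names = FALSE)
  cat(sprintf("\n-- %s: %d voxels x %d features --\n", nm, nrow(feats),
              ncol(feats) - 5L))
  print(table(feats$label))
}
cat("\nwrote results/features_{lownoise,contrast}.csv\n")
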