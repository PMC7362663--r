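#!/usr/bin/env Rscript
# Stage 4: leave-one-out cross-validated two-level classification.
#
# One fold per rat on the low-noise cohort: level 1 (IC vs non-IC, 18 DTI
# features), then level 2 (IP vs NT, all 110 features with Mahalanobis
# distances against the training core distribution). Reports per-fold and
# pooled accuracy and pooled AUCs.

library(penumbra)

feats <- utils::read.csv("results/features_lownoise.csv", check.names = FALSE)
rep <- evaluate_loocv(feats, backend = "svm", seed = 1L,
                      max_train_voxels = 4000L)
utils::write.csv(rep$folds, "results/loocv_folds.csv", row.names = FALSE)
utils::write.csv(rep$predictions, "results/loocv_predictions.csv",
                 row.names = FALSE)

cat("\n-- per-fold metrics --\n")
print(rep$folds, digits = 3)
cat("\n-- pooled --\n")
str(rep$pooled)
cat("\nwrote results/loocv_folds.csv, results/loocv_predictions.csv\n")
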