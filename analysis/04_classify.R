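#!/usr/bin/env Rscript
# Step 4: MSI status prediction with conformal confidence.
#
# Encodes per-sample call profiles as gene-level features, estimates
# cross-validated sensitivity/specificity of the 100-tree random forest,
# checks Mondrian conformal validity at several significance levels, and
# trains the final model on all labelled samples.

suppressMessages({
  library(msisweep)
  library(data.table)
})

coh <- readRDS("scratch/cohort.rds")
cm <- build_cohort_matrix(coh$calls, coh$metadata, coh$catalogue)
x <- encode_features(cm)
message(sprintf("feature matrix: %d samples x %d features",
                nrow(x), ncol(x)))

## cross-validated performance --------------------------------------------
cv <- cross_validate(x, cm$samples$msi_label, k = 10,
                     epsilons = c(0.05, 0.1, 0.25), seed = 42)
fwrite(cv$predictions, "results/cv_predictions.tsv", sep = "\t")
fwrite(cv$conformal, "results/cv_conformal.tsv", sep = "\t")
message(sprintf("10-fold CV: sensitivity %.1f%%, specificity %.1f%%",
                100 * cv$sensitivity, 100 * cv$specificity))
message("conformal verdicts and class-conditional errors by epsilon:")
print(cv$conformal)

## final model and example predictions ------------------------------------
model <- train_msi_model(x, cm$samples$msi_label, seed = 42)
pred <- predict(model, x, epsilon = 0.25)     # confidence level 0.75
fwrite(pred, "results/final_model_predictions.tsv", sep = "\t")
message("verdicts at confidence 0.75 (training cohort):")
print(table(pred$verdict))
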