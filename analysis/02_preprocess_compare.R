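#!/usr/bin/env Rscript
# Step 2 — compare the spectral pretreatments (RAW, SNV, MSC, SG-7) on the
# full-channel poly-SVM models, 2-class and 6-class, after one 2:1
# stratified split.
#
# Writes: results/table_preprocessing_two_class.csv
#         results/table_preprocessing_six_class.csv

library(fluortea)
dir.create("results", showWarnings = FALSE)

seed <- 1
set <- simulate_set(default_config(seed))
grid <- run_grid(run_config(set, selectors = "none", global_seed = seed))

report_table(grid, "two-class",
             path = "results/table_preprocessing_two_class.csv")
report_table(grid, "six-class",
             path = "results/table_preprocessing_six_class.csv")

two <- grid[grid$mode == "two-class" & grid$partition == "prediction", ]
cat("two-class prediction accuracy by pretreatment:\n")
print(two[, c("preprocess", "sensitivity", "specificity", "accuracy")],
      row.names = FALSE)
six <- grid[grid$mode == "six-class" & grid$partition == "prediction", ]
cat("\nsix-class overall prediction accuracy by pretreatment:\n")
print(six[, c("preprocess", "accuracy")], row.names = FALSE)
cat("\nNote the 2-class task saturates while the 6-class task separates the",
    "pretreatments — the degree task is the harder one.\n")
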