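#!/usr/bin/env Rscript
# Step 4 — the full model grid: 4 pretreatments x {all channels, SPA,
# CARS, random frog, UVE} x poly-SVM, for both the 2-class
# (pure vs adulterated) and the 6-class (adulteration degree) tasks.
#
# Writes: results/table_two_class.csv
#         results/table_six_class.csv

library(fluortea)
dir.create("results", showWarnings = FALSE)

seed <- 1
set <- simulate_set(default_config(seed))
grid <- run_grid(run_config(set, global_seed = seed))

report_table(grid, "two-class", path = "results/table_two_class.csv")
report_table(grid, "six-class", path = "results/table_six_class.csv")

pred <- grid[grid$partition == "prediction" & !grid$failed, ]
best2 <- pred[pred$mode == "two-class", ]
best2 <- best2[order(-best2$accuracy, best2$n_selected), ][1, ]
best6 <- pred[pred$mode == "six-class", ]
best6 <- best6[order(-best6$accuracy, best6$n_selected), ][1, ]

cat(sprintf("best 2-class model: %s + %s (%d channels), accuracy %.2f%%\n",
            best2$preprocess, best2$selector, best2$n_selected,
            100 * best2$accuracy))
cat(sprintf("best 6-class model: %s + %s (%d channels), accuracy %.2f%%\n",
            best6$preprocess, best6$selector, best6$n_selected,
            100 * best6$accuracy))
cat(sprintf("weakest class accuracy in the best 6-class model: %.2f%%\n",
            100 * min(unlist(best6[paste0("acc_class_", 0:5)]))))
cat("wrote results/table_two_class.csv and results/table_six_class.csv\n")
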