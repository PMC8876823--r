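#!/usr/bin/env Rscript
# Step 3 — characteristic-wavelength selection on the SG-7-smoothed
# calibration partition: SPA, CARS, random frog and UVE, with the 2-class
# response. Reports how many of the 104 channels each method keeps and
# where they sit.
#
# Writes: results/selection_sg_two_class.json

library(fluortea)
suppressMessages(library(jsonlite))
dir.create("results", showWarnings = FALSE)

seed <- 1
set <- simulate_set(default_config(seed))
parts <- stratified_split(set, split_spec(seed = seed))
cal <- sg_smooth(parts$calibration)
X <- cal$intensities
y <- as.numeric(cal$labels != 0L)
w <- cal$grid$wavelengths_nm
cv <- cv_spec(shuffle_seed = seed)

sels <- list(
  SPA = spa_select(X, y, max_k = 25, cv = cv),
  CARS = cars_select(X, y, cars_config(cv = cv), rng_seed = seed),
  RF = random_frog_select(X, y, cv = cv, rng_seed = seed),
  UVE = uve_select(X, y, rng_seed = seed))

out <- lapply(sels, function(s) list(
  n_selected = s$n_selected,
  channel_idx = s$selected,
  wavelengths_nm = round(w[s$selected], 1)))
write_json(out, "results/selection_sg_two_class.json",
           auto_unbox = TRUE, pretty = TRUE)

for (nm in names(sels)) {
  s <- sels[[nm]]
  cat(sprintf("%-4s kept %2d / 104 channels, spanning %.0f-%.0f nm\n",
              nm, s$n_selected, min(w[s$selected]), max(w[s$selected])))
}
cat("wrote results/selection_sg_two_class.json\n")
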