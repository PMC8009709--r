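#!/usr/bin/env Rscript
# Step 5 — assemble the accuracy report: trueness and precision (x10^3),
# replicate index RMS, surface RMS with 95% confidence intervals, and
# Kruskal-Wallis comparisons across the simulated systems.

library(scanmetry)

spec <- read_model_spec("results/model_spec.cfg")
gold <- list(mesh = NULL,
             reference_values = spec_indices(spec), spec = spec)
class(gold) <- "gold_standard"

indices <- read.csv("results/indices.csv")
rms <- read.csv("results/rms.csv")

systems <- sort(unique(indices$system))
measurements <- lapply(systems, function(s) {
  indices[indices$system == s, c("R1", "R2", "L1", "L2", "L3", "theta")]
})
names(measurements) <- systems
rms_values <- lapply(systems, function(s) rms$rms[rms$system == s])
names(rms_values) <- systems

report <- evaluate_study(gold, measurements, rms_values)

write.csv(report$trueness, "results/trueness.csv", row.names = FALSE)
write.csv(report$precision, "results/precision.csv", row.names = FALSE)
write.csv(report$index_rms, "results/index_rms.csv", row.names = FALSE)
write.csv(report$surface_rms, "results/surface_rms.csv", row.names = FALSE)
write.csv(report$kruskal_wallis, "results/kruskal_wallis.csv",
          row.names = FALSE)

print(report)
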