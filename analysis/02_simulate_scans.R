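#!/usr/bin/env Rscript
# Step 2 — simulate the replicate scans.
#
# Three simulated scan systems stand in for the two intraoral scanners and
# the extraoral scanner of a physical study: each combines along-normal
# Gaussian depth noise, a smooth low-frequency drift field (the stitching
# error analogue), a random handheld pose and mild decimation. Error
# magnitudes are chosen to produce surface RMS values of a few tens of
# micrometres. Ten replicates per system keep this demonstration quick; the
# acceptance checks in the test suite run the n = 30 calibrations.

library(scanmetry)

spec <- read_model_spec("results/model_spec.cfg")
gold_mesh <- read_stl("scratch/gold_standard.stl")

profiles <- default_profiles(base_seed = 20210321L %% 1000000L)
n_rep <- 10L

study <- simulate_study(gold_mesh, profiles, n_replicates = n_rep,
                        out_dir = "scratch/scans")

manifest <- do.call(rbind, lapply(profiles, function(p) {
  as.data.frame(unclass(p))
}))
manifest$n_replicates <- n_rep
write.csv(manifest, "results/scan_manifest.csv", row.names = FALSE)

cat("Simulated", length(attr(study, "files")), "scans into scratch/scans/\n")
for (p in profiles) print(p)
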