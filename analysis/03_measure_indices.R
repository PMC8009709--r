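#!/usr/bin/env Rscript
# Step 3 — recover the six indices from every simulated scan.
#
# Each scan is segmented and the six indices are measured by primitive
# fitting, exactly as a reverse-engineering operator would probe radii,
# step heights and the occlusal angle on a digital impression.

library(scanmetry)

files <- list.files("scratch/scans", pattern = "\\.stl$", recursive = TRUE,
                    full.names = TRUE)
stopifnot(length(files) > 0L)

rows <- lapply(files, function(f) {
  mesh <- read_stl(f)
  mi <- measure_indices(mesh)
  cbind(data.frame(system = basename(dirname(f)), scan = basename(f)),
        as.data.frame(mi))
})
indices <- do.call(rbind, rows)
write.csv(indices, "results/indices.csv", row.names = FALSE)

cat("Measured", nrow(indices), "scans\n")
agg <- aggregate(indices[, c("R1", "R2", "L1", "L2", "L3", "theta")],
                 by = indices["system"], FUN = mean)
cat("Per-system mean indices:\n")
print(agg, digits = 5, row.names = FALSE)
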