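#!/usr/bin/env Rscript
# Stage 1 — simulate the study dataset.
#
# Builds the default synthetic hemisphere (96 x 96 cortical sheet with a
# V1-like patch, a 296-vertex hMT/MST-like region and a 95-vertex pFST-like
# crescent on its anterior/inferior flank) and writes the ground truth plus
# BIDS-style events tables for the full 16-scan protocol: 2 x 2D-motion
# localizer, 1 x stereomotion localizer, 1 x opponent motion, 12 x pRF
# mapping. Time-series and aperture binaries are bulky and regenerated on
# demand by later stages, so they are not exported here (set write_ts = TRUE
# below to dump them).

library(fstloc)

out <- "results/simulated_dataset"
cfg <- default_config(seed = 1)
write_config(cfg, file.path("results", "run_config.json"))

manifest <- sim_dataset(cfg, out, write_ts = FALSE)
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)

hemi <- make_hemisphere(seed = cfg$seed)
cat(sprintf("\nSimulated hemisphere: %d x %d vertices\n",
            hemi$shape[1], hemi$shape[2]))
print(table(hemi$region))
cat(sprintf("Protocol: %d scans (%s)\n", nrow(build_protocol(cfg)),
            paste(names(table(build_protocol(cfg)$type)),
                  table(build_protocol(cfg)$type), collapse = ", ", sep = "=")))
cat(sprintf("Ground truth and events written under %s\n", out))
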