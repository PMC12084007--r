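#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screen the rest of the workflow analyzes.
#
# The generator emulates the structure of a multi-site Cell Painting screen:
# 384-well plates with test compounds in columns 1-22 and DMSO/nocodazole/
# tetrandrine controls in columns 23-24, four replicate plates per library
# plate, sparse compound effects, depressed cell counts for toxic compounds,
# plate drift and rim artifacts. At this desk scale we use 500 compounds on
# two plates with 200 features; the full-screen defaults (2,464 compounds,
# seven plates) run the same way, just longer.

library(paintqc)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

gen <- synthetic_config(n_compounds = 500, n_plates = 2, n_features = 200,
                        seed = 42)
sim <- simulate_profiles(gen)

write_profiles(sim$profiles, file.path(out_dir, "profiles_raw.csv"))
write_layout(sim$layouts, file.path(out_dir, "plate_layout.csv"))
write.csv(sim$truth$compounds, file.path(out_dir, "ground_truth_compounds.csv"),
          row.names = FALSE)

message(sprintf(
  "simulated %d wells (%d plates x %d replicates), %d features; %d toxic, %d low-active compounds",
  nrow(sim$profiles), gen$n_plates, gen$n_replicates, gen$n_features,
  sum(sim$truth$compounds$is_toxic), sum(sim$truth$compounds$is_low_active)
))
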