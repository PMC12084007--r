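#!/usr/bin/env Rscript
# Stage 3: normalization, feature selection, consensus.
#
# Profiles are normalized per physical plate against the DMSO wells
# ((x - median) / (MAD + 1e-6)), features pass the four-stage screen
# (NaN -> near-zero variance -> |value| > 100 -> |r| > 0.9), and replicate
# wells collapse to per-compound median consensus profiles.

library(paintqc)

profiles <- read_profiles("results/profiles_raw.csv")
config <- pipeline_config()

norm <- mad_robustize(profiles, config)
sel <- select_features(norm$profiles, config)
cons <- consensus_profiles(sel$profiles, include_controls = FALSE)

write_profiles(sel$profiles, "results/profiles_normalized_selected.csv")
write.csv(sel$report, "results/feature_selection_report.csv", row.names = FALSE)
write.csv(cons, "results/consensus_profiles.csv", row.names = FALSE)

dropped <- table(sel$report$stage)
message(sprintf(
  "normalized %d wells on %d physical plates; features: %d -> %d kept (%s)",
  nrow(profiles), nrow(unique(profiles[c("plate_id", "replicate")])),
  nrow(sel$report), sum(sel$report$stage == "kept"),
  paste(sprintf("%s %d", names(dropped), dropped), collapse = ", ")
))
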