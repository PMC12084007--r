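#!/usr/bin/env Rscript
# Stage 6: plate QC heatmaps, control-replicate correlation, senescence scan.
#
# Heatmap CSVs use the screen's fixed scaling rules: object counts anchored
# at red 0 / yellow global median / blue global max (rounded up to two
# significant digits); intensity features as per-plate median ratios
# anchored at 0.5 / 1.0 / 1.5.

library(paintqc)

profiles <- read_profiles("results/profiles_raw.csv")
norm <- mad_robustize(profiles)$profiles
dir.create("results/qc", showWarnings = FALSE)

for (plate in unique(profiles$plate_id)) {
  hm <- object_count_heatmap(profiles, plate)
  write_heatmap(hm, sprintf("results/qc/count_heatmap_%s.csv", plate))
  ih <- intensity_heatmap(profiles, plate, feature_cols(profiles)[1])
  write_heatmap(ih, sprintf("results/qc/intensity_heatmap_%s.csv", plate))
  rm_ <- replicate_median_heatmap(profiles, plate, feature_cols(profiles)[1])
  write_heatmap(rm_, sprintf("results/qc/replicate_median_heatmap_%s.csv", plate))
}

cc <- control_replicate_correlation(norm)
write.csv(cc, "results/qc/control_replicate_correlation.csv", row.names = FALSE)

message("control-replicate correlation (median pairwise r):")
for (i in seq_len(nrow(cc))) {
  message(sprintf("  %s %-28s %5.2f (%d wells)", cc$plate_id[i], cc$control[i],
                  cc$median_r[i], cc$n_wells[i]))
}
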