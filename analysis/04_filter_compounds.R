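#!/usr/bin/env Rscript
# Stage 4: compound toxicity and activity filtering.
#
# Toxic compounds depress the consensus cell count below
# median - 2.5 SD of the test-compound population; low-active compounds
# have fewer than 5% of selected features deviating more than 3 DMSO MADs
# in the normalized consensus profile. Filters apply sequentially so the
# categories are disjoint.

library(paintqc)

cons <- read.csv("results/consensus_profiles.csv")
cons <- tibble::as_tibble(cons)
config <- pipeline_config()

flags <- compound_flags(cons, config)
write.csv(flags, "results/compound_flags.csv", row.names = FALSE)

truth <- read.csv("results/ground_truth_compounds.csv")
m <- merge(flags, truth, by = "compound_id", suffixes = c("_hat", "_true"))
message(sprintf(
  "of %d compounds: %d toxic (truth %d), %d low-active (truth %d)",
  nrow(flags), sum(flags$is_toxic), sum(m$is_toxic_true),
  sum(flags$is_low_active), sum(m$is_low_active_true)
))
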