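#!/usr/bin/env Rscript
# Stage 5: reproducibility metrics with permutation nulls.
#
# Percent replicating: per surviving compound, the median pairwise Pearson
# correlation of its four replicate profiles, against the 95th percentile
# of 10,000 random non-replicate quadruplets. The filter accounting rolls
# the sequential toxicity -> activity -> reproducibility removals into the
# per-dataset bookkeeping table.

library(paintqc)

profiles <- read_profiles("results/profiles_normalized_selected.csv")
flags <- read.csv("results/compound_flags.csv")
config <- pipeline_config(replicating = list(n_null = 10000L, seed = 42L))

surviving <- flags$compound_id[!flags$is_toxic & !flags$is_low_active]
eval_profiles <- profiles[!is.na(profiles$compound_id) &
                            profiles$compound_id %in% surviving &
                            profiles$role == "test", ]
rep_res <- percent_replicating(eval_profiles, config)
write.csv(rep_res$scores, "results/replicate_correlations.csv", row.names = FALSE)

acc <- filter_accounting(
  n_total = nrow(flags),
  n_toxic = sum(flags$is_toxic),
  n_low_active = sum(flags$is_low_active),
  n_non_replicating = rep_res$n_evaluated - rep_res$n_passing
)
write.csv(acc, "results/filter_accounting.csv", row.names = FALSE)

print(rep_res)
message(sprintf(
  "accounting: %d total | %d toxic (%d%%) | %d low-active (%d%%) | %d non-replicating (%d%%) | %d retained",
  acc$n_total, acc$n_toxic, acc$pct_toxic, acc$n_low_active,
  acc$pct_low_active, acc$n_non_replicating, acc$pct_non_replicating,
  acc$n_retained
))
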