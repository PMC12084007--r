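#!/usr/bin/env Rscript
# Stage 2: single-cell cleaning demonstrated on one simulated plate.
#
# Raw single-cell tables are filtered in two passes before any aggregation:
# cells with missing or infinite feature values are dropped row-wise, then a
# histogram-based outlier score (HBOS) fit on the whole plate removes the
# highest-scoring 10% of cells (segmentation artifacts, debris, dead cells).
# The cleaned cells are aggregated to per-well median profiles with counts.

library(paintqc)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

gen <- synthetic_config(n_compounds = 352, n_plates = 1, n_features = 40,
                        baseline_cell_count = 300, seed = 42)
layout <- build_layout(1, sprintf("CPD%05d", 1:352))
sc <- simulate_single_cells(layout, gen)

res <- process_plate_cells(sc$cells, layout, pipeline_config())
write_profiles(res$profiles, file.path(out_dir, "profiles_from_cells.csv"))
write.csv(res$filter_log, file.path(out_dir, "cell_filter_log.csv"),
          row.names = FALSE)

dead <- classify_dead_cells(sc$cells)
message(sprintf(
  "plate of %d cells: %d removed for invalid values, %d by HBOS; %d wells aggregated; %s%% classified dead",
  res$n_input, res$filter_log$removed[1], res$filter_log$removed[2],
  nrow(res$profiles), dead_cell_summary(sum(dead), length(dead))
))
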