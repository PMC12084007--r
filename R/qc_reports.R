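# Plate-heatmap QC matrices, control-replicate correlation QC, and the
# senescence readout.
#
# Heatmaps are 16 x 24 matrices (rows A-P, columns 1-24) plus three scale
# anchors with fixed color roles (red = anchor_low, yellow = anchor_mid,
# blue = anchor_high). Rendering is left to the caller (the matrices export
# to CSV and plot directly with image() or ggplot2); the tested contract is
# the matrix and its anchors.

plate_matrix <- function(wells, values) {
  m <- matrix(NA_real_, nrow = 16, ncol = 24,
              dimnames = list(PLATE_ROWS, as.character(PLATE_COLS)))
  m[cbind(match(well_row(wells), PLATE_ROWS), well_col(wells))] <- values
  m
}

new_heatmap <- function(plate_id, feature, mat, low, mid, high) {
  structure(list(plate_id = plate_id, feature = feature, matrix = mat,
                 scale = list(anchor_low = low, anchor_mid = mid,
                              anchor_high = high)),
            class = "plate_heatmap")
}

#' Object-count plate heatmap
#'
#' Matrix of per-well cell counts for one plate. Anchors are shared across
#' the whole dataset so plates are comparable: red at 0, yellow at the
#' global median count, blue at the global maximum, the latter two rounded
#' up to two significant digits. Missing wells (no row in the table) show
#' as `NA`; a well recorded with zero cells shows 0 at the red anchor.
#'
#' @param profiles A well-level profile tibble (all plates of the dataset;
#'   anchors are computed globally).
#' @param plate_id Which plate to map.
#' @param replicate Which replicate of the plate (default 1).
#' @return A `plate_heatmap`.
#' @export
object_count_heatmap <- function(profiles, plate_id, replicate = 1L) {
  validate_profile_table(profiles)
  if (!plate_id %in% profiles$plate_id) {
    abort_paintqc(sprintf("unknown plate '%s'", plate_id), "paintqc_schema_error")
  }
  sel <- profiles$plate_id == plate_id & profiles$replicate == replicate
  mat <- plate_matrix(profiles$well[sel], profiles$cell_count[sel])
  new_heatmap(plate_id, "cell_count", mat,
              low = 0,
              mid = ceiling_signif2(stats::median(profiles$cell_count)),
              high = ceiling_signif2(max(profiles$cell_count)))
}

#' Median-normalized intensity plate heatmap
#'
#' Per-well feature value divided by the plate median of that feature
#' (within the chosen replicate), with fixed anchors red = 0.5, yellow =
#' 1.0, blue = 1.5 — a scale for spotting dispense gradients without
#' feature-specific controls.
#'
#' @param profiles A well-level profile tibble.
#' @param plate_id Which plate to map.
#' @param feature Feature column to visualize.
#' @param replicate Which replicate (default 1).
#' @return A `plate_heatmap`.
#' @export
intensity_heatmap <- function(profiles, plate_id, feature, replicate = 1L) {
  validate_profile_table(profiles)
  if (!feature %in% names(profiles)) {
    abort_paintqc(sprintf("unknown feature '%s'", feature), "paintqc_schema_error")
  }
  sel <- profiles$plate_id == plate_id & profiles$replicate == replicate
  vals <- profiles[[feature]][sel]
  med <- stats::median(vals)
  if (!is.finite(med) || med == 0) {
    abort_paintqc(
      sprintf("plate '%s' median of '%s' is zero; ratio scale undefined",
              plate_id, feature),
      "paintqc_degenerate_scale_error"
    )
  }
  mat <- plate_matrix(profiles$well[sel], vals / med)
  new_heatmap(plate_id, feature, mat, low = 0.5, mid = 1.0, high = 1.5)
}

#' Replicate-median plate heatmap
#'
#' Per well, the median across technical replicates of the per-plate
#' median-normalized feature value — the "fifth heatmap" that shows whether
#' taking the replicate median suppresses artifacts visible on individual
#' replicates. Missing replicates are tolerated (median over available).
#'
#' @param profiles A well-level profile tibble.
#' @param plate_id Library plate to map.
#' @param feature Feature column.
#' @return A `plate_heatmap` with the intensity anchors (0.5, 1, 1.5).
#' @export
replicate_median_heatmap <- function(profiles, plate_id, feature) {
  validate_profile_table(profiles)
  sel <- profiles$plate_id == plate_id
  if (!any(sel)) {
    abort_paintqc(sprintf("unknown plate '%s'", plate_id), "paintqc_schema_error")
  }
  sub <- profiles[sel, ]
  normv <- numeric(nrow(sub))
  for (ix in split(seq_len(nrow(sub)), sub$replicate)) {
    med <- stats::median(sub[[feature]][ix])
    if (!is.finite(med) || med == 0) {
      abort_paintqc(sprintf("replicate median of '%s' is zero", feature),
                    "paintqc_degenerate_scale_error")
    }
    normv[ix] <- sub[[feature]][ix] / med
  }
  sub$.norm <- normv
  agg <- sub |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(value = stats::median(.data$.norm), .groups = "drop")
  mat <- plate_matrix(agg$well, agg$value)
  new_heatmap(plate_id, feature, mat, low = 0.5, mid = 1.0, high = 1.5)
}

#' Export a plate heatmap as CSV
#'
#' Writes the 16 x 24 matrix with row-letter and column headers; the scale
#' anchors go to a JSON sidecar of the same stem when `anchors = TRUE`.
#'
#' @param heatmap A `plate_heatmap`.
#' @param path Output CSV path.
#' @param anchors Also write `<stem>_scale.json`.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(heatmap, path, anchors = TRUE) {
  df <- data.frame(row = rownames(heatmap$matrix), heatmap$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (anchors) {
    side <- sub("\\.csv$", "_scale.json", path)
    jsonlite::write_json(
      c(list(plate_id = heatmap$plate_id, feature = heatmap$feature),
        heatmap$scale),
      side, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Control-replicate correlation QC
#'
#' For each plate and each positive control, the median pairwise Pearson
#' correlation of that control's well profiles across all replicates of
#' the plate; DMSO wells are summarized likewise as the low-correlation
#' baseline. Combinations with fewer than two wells are skipped with a
#' note.
#'
#' @param profiles A (normalized) well-level profile tibble.
#' @return A tibble: `plate_id`, `control`, `n_wells`, `median_r` (`NA`
#'   with a `note` when skipped).
#' @export
control_replicate_correlation <- function(profiles) {
  validate_profile_table(profiles)
  feats <- feature_cols(profiles)
  ctrl <- profiles[grepl("control", profiles$role), ]
  combos <- unique(ctrl[c("plate_id", "role")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- ctrl[ctrl$plate_id == combos$plate_id[i] & ctrl$role == combos$role[i], ]
    if (nrow(sub) < 2) {
      return(tibble::tibble(plate_id = combos$plate_id[i], control = combos$role[i],
                            n_wells = nrow(sub), median_r = NA_real_,
                            note = "fewer than 2 wells"))
    }
    r <- tryCatch(median_pairwise_correlation(as.matrix(sub[feats])),
                  paintqc_metric_error = function(e) NA_real_)
    tibble::tibble(plate_id = combos$plate_id[i], control = combos$role[i],
                   n_wells = nrow(sub), median_r = r, note = "")
  })
  dplyr::bind_rows(rows)
}

#' Senescence readout from cell area and nuclear intensity
#'
#' Per plate (and replicate), z-scores each well's cell-area and
#' nuclear-intensity features against the median and raw MAD of the entire
#' plate; per compound the replicate-median z is taken. A compound is
#' flagged senescence-like when its area z exceeds `senescence$area_z` and
#' its nuclear-intensity z is below `-senescence$intensity_z` (enlarged
#' cells with decreased nuclear signal density).
#'
#' @param profiles A well-level profile tibble carrying the two features.
#' @param config A [pipeline_config()]; uses the `senescence` group.
#' @param area_feature,intensity_feature Column names of the two readouts.
#' @return A tibble: `compound_id`, `area_z`, `nuc_intensity_z`, `flagged`.
#' @export
senescence_scores <- function(profiles, config = pipeline_config(),
                              area_feature = "cell_area",
                              intensity_feature = "nuclear_mean_intensity") {
  validate_profile_table(profiles)
  for (f in c(area_feature, intensity_feature)) {
    if (!f %in% names(profiles)) {
      abort_paintqc(sprintf("feature '%s' not present", f), "paintqc_schema_error")
    }
  }
  zscore <- function(x) {
    m <- stats::median(x)
    s <- raw_mad(x)
    if (s == 0) {
      abort_paintqc("zero plate MAD; z-scale degenerate",
                    "paintqc_degenerate_scale_error")
    }
    (x - m) / s
  }
  sub <- profiles[!is.na(profiles$compound_id), ]
  key <- paste(sub$plate_id, sub$replicate)
  az <- iz <- numeric(nrow(sub))
  for (k in unique(key)) {
    ix <- key == k
    az[ix] <- zscore(sub[[area_feature]][ix])
    iz[ix] <- zscore(sub[[intensity_feature]][ix])
  }
  sub$.az <- az
  sub$.iz <- iz
  out <- sub |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(area_z = stats::median(.data$.az),
                     nuc_intensity_z = stats::median(.data$.iz),
                     .groups = "drop")
  out$flagged <- out$area_z > config$senescence$area_z &
    out$nuc_intensity_z < -config$senescence$intensity_z
  out
}
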