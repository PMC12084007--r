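# Single-cell cleaning: invalid-value filter, histogram-based outlier score
# (HBOS), dead-cell classification, and median aggregation to well profiles.
#
# HBOS ranks cells by summing, over features, the log-inverse height of the
# histogram bin each feature value falls in. Histograms are equal-width with
# a fixed bin number, fit on the whole plate, and max-normalized per feature
# so the modal bin has height 1. The filter removes a fixed fraction
# (contamination) of the highest-scoring cells.

#' Remove cells with missing or non-finite feature values
#'
#' Row-wise: a cell is dropped if any of its feature values is `NA`, `NaN`,
#' `Inf` or `-Inf`. Metadata columns are not inspected. Row order is
#' preserved.
#'
#' @param cells A single-cell tibble.
#' @return A list with `cells` (the cleaned table) and `removed_count`.
#' @examples
#' tab <- tibble::tibble(plate_id = "p", well = "A01", field = 1L,
#'                       object_id = 1:3, f1 = c(1, NA, Inf))
#' drop_invalid_cells(tab)$removed_count
#' @export
drop_invalid_cells <- function(cells) {
  validate_cell_table(cells)
  feats <- feature_cols(cells)
  if (length(feats) == 0 || nrow(cells) == 0) {
    return(list(cells = cells, removed_count = 0L))
  }
  mat <- as.matrix(cells[feats])
  ok <- rowSums(!is.finite(mat)) == 0
  list(cells = cells[ok, , drop = FALSE], removed_count = sum(!ok))
}

#' Fit a histogram-based outlier score (HBOS) model
#'
#' Per feature, builds an equal-width histogram with `n_bins` bins spanning
#' the observed min--max of the fitting population (conventionally one whole
#' plate), and normalizes bin heights so the tallest bin has height 1. A
#' constant feature occupies a single degenerate bin of height 1 and
#' contributes equally to every cell's score.
#'
#' @param cells A single-cell tibble with all-finite feature values.
#' @param config A [pipeline_config()]; uses the `hbos` group.
#' @return An `hbos_model` list: per-feature `breaks` and max-normalized
#'   `heights`, plus `alpha` and `tol`.
#' @export
fit_hbos <- function(cells, config = pipeline_config()) {
  feats <- feature_cols(cells)
  if (nrow(cells) == 0) {
    abort_paintqc("cannot fit HBOS on an empty table", "paintqc_fit_error")
  }
  n_bins <- config$hbos$n_bins
  model <- lapply(cells[feats], function(x) {
    lo <- min(x)
    hi <- max(x)
    if (lo == hi) {
      return(list(breaks = c(lo, hi), heights = 1, degenerate = TRUE))
    }
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
    counts <- tabulate(bin_index(x, lo, hi, n_bins), nbins = n_bins)
    list(breaks = breaks, heights = counts / max(counts), degenerate = FALSE)
  })
  structure(list(features = model, alpha = config$hbos$alpha,
                 tol = config$hbos$tol, n_bins = n_bins),
            class = "hbos_model")
}

# Equal-width bin index with the rightmost bin closed (value == max falls in
# bin n_bins); interior edges belong to the right-hand bin.
bin_index <- function(x, lo, hi, n_bins) {
  idx <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  pmin.int(pmax.int(idx, 1L), n_bins)
}

#' Score cells with a fitted HBOS model
#'
#' `score(cell) = sum over features of log(1 / (height + alpha))`, where
#' `height` is the normalized height of the bin the cell's value falls in.
#' Higher scores are more outlying. Values up to `tol * bin_width` outside
#' the fitted range are clamped to the nearest edge bin; values farther out
#' are assigned the feature's minimal bin height.
#'
#' @param model An `hbos_model` from [fit_hbos()].
#' @param cells A single-cell tibble whose features include the model's.
#' @return Numeric vector of per-cell scores.
#' @export
hbos_score <- function(model, cells) {
  stopifnot(inherits(model, "hbos_model"))
  missing <- setdiff(names(model$features), names(cells))
  if (length(missing)) {
    abort_paintqc(
      sprintf("table lacks model feature(s): %s", paste(missing, collapse = ", ")),
      "paintqc_schema_error"
    )
  }
  scores <- numeric(nrow(cells))
  for (nm in names(model$features)) {
    fm <- model$features[[nm]]
    x <- cells[[nm]]
    if (isTRUE(fm$degenerate)) {
      h <- ifelse(x == fm$breaks[1], 1, min(fm$heights))
    } else {
      lo <- fm$breaks[1]
      hi <- fm$breaks[length(fm$breaks)]
      width <- (hi - lo) / model$n_bins
      h <- numeric(length(x))
      inside <- x >= lo - model$tol * width & x <= hi + model$tol * width
      h[inside] <- fm$heights[bin_index(x[inside], lo, hi, model$n_bins)]
      h[!inside] <- min(fm$heights)
    }
    scores <- scores + log(1 / (h + model$alpha))
  }
  scores
}

#' HBOS outlier filter
#'
#' Fits HBOS on the table (one plate's population, by convention), scores
#' every cell, and removes the `ceiling(contamination * n)` highest-scoring
#' cells. Ties at the cut are broken deterministically by (score
#' descending, plate_id, well, object_id descending), so with equal scores
#' the higher `object_id` is removed first.
#'
#' @param cells A single-cell tibble with all-finite feature values.
#' @param config A [pipeline_config()]; uses the `hbos` group.
#' @return A list with `cells` (kept rows, input order), `removed` (removed
#'   rows) and `scores` (per-input-row scores).
#' @export
hbos_filter <- function(cells, config = pipeline_config()) {
  n <- nrow(cells)
  if (n == 0) {
    return(list(cells = cells, removed = cells[0, ], scores = numeric(0)))
  }
  model <- fit_hbos(cells, config)
  scores <- hbos_score(model, cells)
  n_remove <- ceiling(config$hbos$contamination * n)
  ord <- order(-scores, cells$plate_id, cells$well, -cells$object_id)
  removed_idx <- sort(ord[seq_len(n_remove)])
  keep <- setdiff(seq_len(n), removed_idx)
  list(cells = cells[keep, , drop = FALSE],
       removed = cells[removed_idx, , drop = FALSE],
       scores = scores)
}

#' Classify dead cells from area and roundness
#'
#' A cell is called dead when its area is strictly below `area_max`
#' (default 1000 um^2) and its width/length ratio strictly above
#' `ratio_min` (default 0.83) — the small-and-round phenotype of dying
#' cells.
#'
#' @param cells A single-cell tibble with `cell_area` and
#'   `cell_width_length_ratio` columns.
#' @param config A [pipeline_config()]; uses the `dead_cell` group.
#' @return Logical vector, one element per cell.
#' @examples
#' tab <- tibble::tibble(plate_id = "p", well = "A01", field = 1L,
#'                       object_id = 1:2,
#'                       cell_area = c(900, 1000),
#'                       cell_width_length_ratio = c(0.9, 0.9))
#' classify_dead_cells(tab)
#' @export
classify_dead_cells <- function(cells, config = pipeline_config()) {
  needed <- c("cell_area", "cell_width_length_ratio")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) {
    abort_paintqc(
      sprintf("dead-cell classifier needs column(s): %s",
              paste(missing, collapse = ", ")),
      "paintqc_schema_error"
    )
  }
  cells$cell_area < config$dead_cell$area_max &
    cells$cell_width_length_ratio > config$dead_cell$ratio_min
}

#' Dead-cell percentage, one decimal
#'
#' `100 * n_dead / n_total` rounded half-even to one decimal — the form the
#' per-treatment dead-cell summaries are reported in.
#'
#' @param n_dead,n_total Counts, `0 <= n_dead <= n_total`, `n_total > 0`.
#' @return A single number.
#' @examples
#' dead_cell_summary(1516, 8206)
#' @export
dead_cell_summary <- function(n_dead, n_total) {
  if (n_total <= 0) {
    abort_paintqc("n_total must be positive", "paintqc_domain_error")
  }
  if (n_dead < 0 || n_dead > n_total) {
    abort_paintqc("n_dead must be between 0 and n_total", "paintqc_domain_error")
  }
  round_half_even(100 * n_dead / n_total, 1)
}

#' Aggregate a cleaned single-cell table to well-level median profiles
#'
#' One output row per well present in the table: each feature is the median
#' over all remaining cells of that well (fields pooled), `cell_count` the
#' number of remaining cells. Wells in the layout with zero remaining cells
#' are omitted from the table and listed in `empty_wells`.
#'
#' @param cells A cleaned single-cell tibble (invalid + HBOS filters applied).
#' @param layout The plate's layout rows ([build_layout()]).
#' @param replicate Replicate number stamped on the output rows.
#' @param site,cell_line Metadata labels for the output.
#' @return A list with `profiles` (profile tibble) and `empty_wells`
#'   (character vector of well addresses with no cells).
#' @export
aggregate_to_wells <- function(cells, layout, replicate = 1L,
                               site = "site", cell_line = "cell_line") {
  validate_cell_table(cells)
  validate_layout(layout)
  unknown <- setdiff(unique(cells$well), layout$well)
  if (length(unknown)) {
    abort_paintqc(
      sprintf("cells reference well(s) absent from layout: %s",
              paste(unknown, collapse = ", ")),
      "paintqc_consistency_error"
    )
  }
  feats <- feature_cols(cells)
  agg <- cells |>
    dplyr::group_by(.data$plate_id, .data$well) |>
    dplyr::summarise(
      cell_count = dplyr::n(),
      dplyr::across(dplyr::all_of(feats), stats::median),
      .groups = "drop"
    )
  meta <- layout[match(agg$well, layout$well),
                 c("compound_id", "role", "concentration_uM")]
  profiles <- dplyr::bind_cols(
    tibble::tibble(
      site = site, cell_line = cell_line,
      plate_id = agg$plate_id, replicate = as.integer(replicate),
      well = agg$well,
      compound_id = meta$compound_id, role = meta$role,
      concentration_uM = meta$concentration_uM,
      cell_count = as.integer(agg$cell_count)
    ),
    agg[feats]
  ) |>
    dplyr::arrange(.data$well)
  filled <- layout$well[layout$role != "empty"]
  list(profiles = profiles, empty_wells = setdiff(filled, profiles$well))
}

#' Run the full single-cell cleaning chain for one plate
#'
#' Invalid-value filter, then HBOS fit/score/removal on the whole plate,
#' then median aggregation; returns the per-stage removal log alongside the
#' well profiles.
#'
#' @inheritParams aggregate_to_wells
#' @param config A [pipeline_config()].
#' @return A list with `profiles`, `empty_wells` and `filter_log` (tibble:
#'   stage, removed, remaining).
#' @export
process_plate_cells <- function(cells, layout, config = pipeline_config(),
                                replicate = 1L, site = "site",
                                cell_line = "cell_line") {
  n0 <- nrow(cells)
  step1 <- drop_invalid_cells(cells)
  step2 <- hbos_filter(step1$cells, config)
  agg <- aggregate_to_wells(step2$cells, layout, replicate, site, cell_line)
  log <- tibble::tibble(
    stage = c("invalid_values", "hbos"),
    removed = c(step1$removed_count, nrow(step2$removed)),
    remaining = c(nrow(step1$cells), nrow(step2$cells))
  )
  c(agg, list(filter_log = log, n_input = n0))
}
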