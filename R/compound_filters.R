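# Compound-level filtering: toxicity by consensus cell count, activity by
# induction score, and the stage-by-stage accounting of how many compounds
# each filter removes.

#' Toxicity filter on consensus cell counts
#'
#' A compound is toxic when its consensus cell count falls strictly below
#' `median(counts) - sd_multiplier * SD(counts)`, where both statistics are
#' taken over the consensus counts of all test compounds in the dataset
#' (controls excluded unless `toxicity$include_controls`). The SD is the
#' population standard deviation (denominator n). Compounds with no
#' surviving cells in any replicate (consensus count 0 from empty wells)
#' fall below any positive threshold and are toxic by construction.
#'
#' @param consensus A consensus tibble ([consensus_profiles()]).
#' @param config A [pipeline_config()]; uses the `toxicity` group.
#' @return A list with `is_toxic` (named logical, one per compound row),
#'   `threshold`, `median` and `sd`.
#' @examples
#' cons <- tibble::tibble(compound_id = letters[1:10], role = "test",
#'                        consensus_cell_count = c(rep(100, 9), 0))
#' toxicity_filter(cons)$threshold
#' @export
toxicity_filter <- function(consensus, config = pipeline_config()) {
  stopifnot("consensus_cell_count" %in% names(consensus))
  pop <- if (isTRUE(config$toxicity$include_controls) || !"role" %in% names(consensus)) {
    consensus
  } else {
    consensus[consensus$role == "test", ]
  }
  counts <- pop$consensus_cell_count
  if (length(counts) < 2) {
    abort_paintqc("toxicity filter needs at least 2 compounds", "paintqc_filter_error")
  }
  med <- stats::median(counts)
  sd_pop <- sqrt(mean((counts - mean(counts))^2))
  threshold <- med - config$toxicity$sd_multiplier * sd_pop
  flags <- consensus$consensus_cell_count < threshold
  names(flags) <- consensus$compound_id
  list(is_toxic = flags, threshold = threshold, median = med, sd = sd_pop)
}

#' Induction score: fraction of responding features
#'
#' A feature responds when the consensus value deviates from the DMSO
#' median by more than `mad_multiplier` DMSO MADs. On profiles that were
#' normalized with [mad_robustize()] the DMSO median is 0 and the MAD 1 per
#' construction, so the criterion reduces to `|z| > mad_multiplier`
#' (default 3). The score is the responding fraction of the selected
#' feature set.
#'
#' @param consensus A consensus tibble computed on normalized, selected
#'   features.
#' @param config A [pipeline_config()]; uses the `induction` group.
#' @param dmso_median,dmso_mad Center and scale per feature (scalars or
#'   vectors over features); defaults 0 and 1 for normalized profiles.
#' @return Named numeric vector of scores in [0, 1], one per compound row.
#' @export
induction_score <- function(consensus, config = pipeline_config(),
                            dmso_median = 0, dmso_mad = 1) {
  feats <- setdiff(names(consensus),
                   c("compound_id", "role", "consensus_cell_count"))
  feats <- feats[vapply(consensus[feats], is.numeric, logical(1))]
  if (length(feats) == 0) {
    abort_paintqc("induction score needs at least one selected feature",
                  "paintqc_filter_error")
  }
  mat <- as.matrix(consensus[feats])
  dev <- abs(sweep(mat, 2, rep_len(dmso_median, ncol(mat))))
  lim <- rep_len(config$induction$mad_multiplier * dmso_mad, ncol(mat))
  responding <- sweep(dev, 2, lim, `>`)
  scores <- rowMeans(responding)
  names(scores) <- consensus$compound_id
  scores
}

#' Activity filter on induction scores
#'
#' A compound is low-active when its induction score is strictly below
#' `active_fraction` (default 0.05, i.e. fewer than 5% of features
#' responding).
#'
#' @param scores Named numeric vector from [induction_score()].
#' @param config A [pipeline_config()]; uses the `induction` group.
#' @return Named logical vector (`TRUE` = low-active).
#' @export
activity_filter <- function(scores, config = pipeline_config()) {
  stopifnot(all(scores >= 0 & scores <= 1))
  scores < config$induction$active_fraction
}

#' Filter accounting
#'
#' Sequential compound accounting: toxicity first, then activity on the
#' non-toxic compounds, then reproducibility on the active ones, so the
#' categories are disjoint and `n_retained = n_total - n_toxic -
#' n_low_active - n_non_replicating`. Percentages are of `n_total`, rounded
#' half-even to integer.
#'
#' @param n_total,n_toxic,n_low_active,n_non_replicating Counts.
#' @return A one-row tibble: counts, integer percentages and `n_retained`.
#' @examples
#' filter_accounting(2467, 103, 1503, 72)$n_retained
#' @export
filter_accounting <- function(n_total, n_toxic, n_low_active, n_non_replicating) {
  counts <- c(n_total, n_toxic, n_low_active, n_non_replicating)
  if (any(counts < 0) || n_toxic + n_low_active + n_non_replicating > n_total) {
    abort_paintqc("inconsistent filter counts", "paintqc_accounting_error")
  }
  pct <- function(k) round_half_even(100 * k / n_total, 0)
  tibble::tibble(
    n_total = n_total,
    n_toxic = n_toxic, pct_toxic = pct(n_toxic),
    n_low_active = n_low_active, pct_low_active = pct(n_low_active),
    n_non_replicating = n_non_replicating,
    pct_non_replicating = pct(n_non_replicating),
    n_retained = n_total - n_toxic - n_low_active - n_non_replicating
  )
}

#' Run toxicity then activity filters on a consensus table
#'
#' Applies the two filters sequentially: every compound gets a toxicity
#' call; the induction score is computed for all compounds but the
#' low-active category only contains non-toxic compounds (disjoint with
#' toxic).
#'
#' @param consensus A consensus tibble of test compounds on normalized,
#'   selected features.
#' @param config A [pipeline_config()].
#' @return A tibble: `compound_id`, `consensus_cell_count`, `is_toxic`,
#'   `induction_score`, `is_low_active` (FALSE wherever `is_toxic`).
#' @export
compound_flags <- function(consensus, config = pipeline_config()) {
  tox <- toxicity_filter(consensus, config)
  scores <- induction_score(consensus, config)
  low <- activity_filter(scores, config) & !tox$is_toxic
  tibble::tibble(
    compound_id = consensus$compound_id,
    consensus_cell_count = consensus$consensus_cell_count,
    is_toxic = unname(tox$is_toxic),
    induction_score = unname(scores),
    is_low_active = unname(low)
  )
}
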