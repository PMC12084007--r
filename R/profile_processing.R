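# Profile processing: plate-wise robust normalization against DMSO wells,
# staged feature selection, and per-compound consensus aggregation.

#' Plate-wise robust normalization against DMSO controls
#'
#' Per plate and feature: `x' = (x - median_DMSO) / (MAD_DMSO + epsilon)`,
#' where the median and MAD are computed over that plate's negative-control
#' (DMSO) wells only and applied to every well of the plate. A "plate" here
#' is a physical plate — one (plate_id, replicate) combination — since each
#' replicate is a separately seeded, treated and imaged plate with its own
#' controls. The MAD is the raw median absolute deviation (no 1.4826
#' consistency factor) unless `normalization$mad_consistency` is set. A
#' constant DMSO feature (MAD 0) maps DMSO wells to 0 and other wells to
#' their deviation divided by `epsilon` — finite, but large.
#'
#' @param profiles A well-level profile tibble (all plates to normalize).
#' @param config A [pipeline_config()]; uses the `normalization` group.
#' @return A list with `profiles` (normalized, same shape) and `stats`
#'   (tibble: plate_id, feature, dmso_median, dmso_mad).
#' @examples
#' sim <- simulate_profiles(synthetic_config(
#'   n_compounds = 8, n_plates = 1, n_features = 5
#' ))
#' norm <- mad_robustize(sim$profiles)
#' @export
mad_robustize <- function(profiles, config = pipeline_config()) {
  validate_profile_table(profiles)
  feats <- feature_cols(profiles)
  eps <- config$normalization$epsilon
  consistency <- if (isTRUE(config$normalization$mad_consistency)) 1.4826 else 1
  out <- profiles
  stats_rows <- list()
  key <- paste(profiles$plate_id, profiles$replicate, sep = "\r")
  for (k in unique(key)) {
    rows <- which(key == k)
    plate <- profiles$plate_id[rows[1]]
    rep_ <- profiles$replicate[rows[1]]
    dmso <- rows[profiles$role[rows] == "negative_control"]
    if (length(dmso) < 2) {
      abort_paintqc(
        sprintf("plate '%s' replicate %s has %d DMSO wells; need at least 2 for normalization",
                plate, rep_, length(dmso)),
        "paintqc_normalization_error"
      )
    }
    mat <- as.matrix(profiles[rows, feats])
    ref <- mat[match(dmso, rows), , drop = FALSE]
    med <- unname(apply(ref, 2, stats::median))
    mad_ <- unname(apply(ref, 2, raw_mad)) * consistency
    out[rows, feats] <- sweep(sweep(mat, 2, med), 2, mad_ + eps, `/`)
    stats_rows[[k]] <- tibble::tibble(
      plate_id = plate, replicate = rep_, feature = feats,
      dmso_median = med, dmso_mad = mad_
    )
  }
  list(profiles = out, stats = dplyr::bind_rows(stats_rows))
}

#' Staged feature selection
#'
#' Applies four stages in fixed order and records which features each one
#' drops:
#' \enumerate{
#'   \item `na` — features with any missing value;
#'   \item `low_variance` — near-zero-variance screen: drop when the
#'     frequency ratio of the most common to the second most common value
#'     exceeds `1 / freq_cut` AND the fraction of unique values is below
#'     `unique_cut`; zero-variance features are always dropped;
#'   \item `outlier` — features whose maximum absolute value exceeds
#'     `outlier_cutoff`;
#'   \item `correlated` — while any surviving pair has `|Pearson r|` above
#'     `corr_threshold`, resolve the pair with the largest `|r|` by dropping
#'     its member with the larger mean absolute correlation to all remaining
#'     features (ties: drop the lexicographically later name).
#' }
#'
#' @param profiles A normalized well-level profile tibble.
#' @param config A [pipeline_config()]; uses the `feature_selection` group.
#' @return A list with `profiles` (surviving features only) and `report`
#'   (tibble: feature, stage dropped at, or `kept`).
#' @export
select_features <- function(profiles, config = pipeline_config()) {
  validate_profile_table(profiles)
  p <- config$feature_selection
  feats <- feature_cols(profiles)
  mat <- as.matrix(profiles[feats])
  dropped <- stats::setNames(rep(NA_character_, length(feats)), feats)

  has_na <- colSums(is.na(mat)) > 0
  dropped[has_na] <- "na"

  alive <- names(dropped)[is.na(dropped)]
  for (nm in alive) {
    x <- mat[, nm]
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1) {
      dropped[nm] <- "low_variance"
      next
    }
    freq_ratio <- as.numeric(tab[1]) / as.numeric(tab[2])
    unique_frac <- length(tab) / length(x)
    if (freq_ratio > 1 / p$freq_cut && unique_frac < p$unique_cut) {
      dropped[nm] <- "low_variance"
    }
  }

  alive <- names(dropped)[is.na(dropped)]
  for (nm in alive) {
    if (max(abs(mat[, nm])) > p$outlier_cutoff) dropped[nm] <- "outlier"
  }

  alive <- names(dropped)[is.na(dropped)]
  if (length(alive) >= 2) {
    cmat <- abs(stats::cor(mat[, alive, drop = FALSE]))
    diag(cmat) <- 0
    while (length(alive) >= 2 && max(cmat) > p$corr_threshold) {
      worst <- which(cmat == max(cmat), arr.ind = TRUE)[1, ]
      pair <- c(rownames(cmat)[worst[1]], colnames(cmat)[worst[2]])
      mean_abs <- rowMeans(cmat[pair, , drop = FALSE])
      victim <- if (mean_abs[1] > mean_abs[2]) {
        pair[1]
      } else if (mean_abs[2] > mean_abs[1]) {
        pair[2]
      } else {
        sort(pair)[2]
      }
      dropped[victim] <- "correlated"
      alive <- setdiff(alive, victim)
      cmat <- cmat[alive, alive, drop = FALSE]
    }
  }

  survivors <- names(dropped)[is.na(dropped)]
  if (length(survivors) == 0) {
    abort_paintqc("feature selection dropped every feature", "paintqc_selection_error")
  }
  report <- tibble::tibble(
    feature = names(dropped),
    stage = ifelse(is.na(dropped), "kept", unname(dropped))
  )
  keep_cols <- c(profile_metadata_cols(), survivors)
  list(profiles = profiles[keep_cols], report = report)
}

#' Consensus profiles over replicates
#'
#' Per compound: the element-wise median feature vector over its replicate
#' wells, and `consensus_cell_count` as the median of the replicate cell
#' counts. Missing replicates are tolerated (the median runs over whatever
#' wells are present). Wells without a compound id (empty wells) are
#' ignored; control wells aggregate like compounds under their control ids.
#'
#' @param profiles A well-level profile tibble with replicate labels.
#' @param include_controls Keep control-well consensus rows (`TRUE`) or only
#'   test compounds.
#' @return A consensus tibble: `compound_id`, `role`,
#'   `consensus_cell_count`, then one column per feature.
#' @export
consensus_profiles <- function(profiles, include_controls = TRUE) {
  validate_profile_table(profiles)
  feats <- feature_cols(profiles)
  keep <- !is.na(profiles$compound_id)
  if (!include_controls) keep <- keep & profiles$role == "test"
  profiles[keep, ] |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      role = .data$role[1],
      consensus_cell_count = stats::median(.data$cell_count),
      dplyr::across(dplyr::all_of(feats), stats::median),
      .groups = "drop"
    )
}
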