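#' Pipeline configuration
#'
#' Collects every numeric constant the pipeline uses, grouped by stage.
#' Defaults are the values used throughout high-content Cell Painting
#' processing of the EU-OPENSCREEN bioactives style of screen:
#'
#' * `hbos`: single-cell outlier scoring — 10 equal-width bins, smoothing
#'   `alpha` 0.1 added inside the log-inverse density, boundary flexibility
#'   `tol` 0.5 (samples within `tol` bin-widths outside the fitted range are
#'   clamped to the edge bin), `contamination` 0.1 (fraction of cells removed).
#' * `normalization`: `epsilon` 1e-06 added to the DMSO MAD denominator;
#'   `mad_consistency` multiplies the MAD by 1.4826 when `TRUE` (default
#'   `FALSE`: raw MAD).
#' * `feature_selection`: near-zero-variance frequency cut 0.1 and unique-value
#'   cut 0.1, absolute-value outlier cutoff 100, correlation threshold 0.9.
#' * `toxicity`: consensus cell-count threshold at median minus
#'   `sd_multiplier` (2.5) population standard deviations;
#'   `include_controls` keeps control wells out of the population by default.
#' * `induction`: a feature responds at more than `mad_multiplier` (3) DMSO
#'   MADs from the DMSO median; compounds with a responding fraction below
#'   `active_fraction` (0.05) are low-active.
#' * `replicating`: permutation null of `n_null` (10000) random groups of
#'   `group_size` (4) non-replicate profiles; pass threshold at the
#'   `percentile` (95) of the null.
#' * `matching`: MOA groups need at least `min_moa_occurrences` (3) members.
#' * `dead_cell`: dead when cell area strictly below `area_max` (1000 um^2)
#'   and width/length ratio strictly above `ratio_min` (0.83).
#' * `senescence`: flagged when cell-area plate z-score exceeds `area_z` (5)
#'   and nuclear-intensity plate z-score is below `-intensity_z` (-5).
#'
#' @param ... Named overrides; each argument named after a group must be a
#'   named list of fields to replace (e.g. `hbos = list(n_bins = 20)`).
#' @return A named nested list with class `paintqc_config`.
#' @examples
#' cfg <- pipeline_config(toxicity = list(sd_multiplier = 3))
#' cfg$toxicity$sd_multiplier
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    hbos = list(n_bins = 10L, alpha = 0.1, tol = 0.5, contamination = 0.1),
    normalization = list(epsilon = 1e-06, mad_consistency = FALSE),
    feature_selection = list(
      freq_cut = 0.1, unique_cut = 0.1,
      outlier_cutoff = 100, corr_threshold = 0.9
    ),
    toxicity = list(sd_multiplier = 2.5, include_controls = FALSE),
    induction = list(mad_multiplier = 3, active_fraction = 0.05),
    replicating = list(n_null = 10000L, group_size = 4L, percentile = 95, seed = 1L),
    matching = list(min_moa_occurrences = 3L),
    dead_cell = list(area_max = 1000, ratio_min = 0.83),
    senescence = list(area_z = 5, intensity_z = 5)
  )
  overrides <- list(...)
  for (grp in names(overrides)) {
    if (!grp %in% names(cfg)) {
      abort_paintqc(sprintf("unknown config group '%s'", grp), "paintqc_config_error")
    }
    for (fld in names(overrides[[grp]])) {
      if (!fld %in% names(cfg[[grp]])) {
        abort_paintqc(
          sprintf("unknown config field '%s$%s'", grp, fld),
          "paintqc_config_error"
        )
      }
      cfg[[grp]][[fld]] <- overrides[[grp]][[fld]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "paintqc_config")
}

validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$hbos$n_bins >= 1, "hbos$n_bins must be >= 1")
  chk(cfg$hbos$contamination > 0 && cfg$hbos$contamination < 1,
      "hbos$contamination must be in (0,1)")
  chk(cfg$hbos$alpha > 0, "hbos$alpha must be > 0")
  chk(cfg$hbos$tol >= 0, "hbos$tol must be >= 0")
  chk(cfg$normalization$epsilon > 0, "normalization$epsilon must be > 0")
  chk(cfg$feature_selection$freq_cut > 0, "feature_selection$freq_cut must be > 0")
  chk(cfg$feature_selection$unique_cut > 0, "feature_selection$unique_cut must be > 0")
  chk(cfg$feature_selection$outlier_cutoff > 0, "feature_selection$outlier_cutoff must be > 0")
  chk(cfg$feature_selection$corr_threshold > 0, "feature_selection$corr_threshold must be > 0")
  chk(cfg$toxicity$sd_multiplier > 0, "toxicity$sd_multiplier must be > 0")
  chk(cfg$induction$mad_multiplier > 0, "induction$mad_multiplier must be > 0")
  chk(cfg$induction$active_fraction > 0, "induction$active_fraction must be > 0")
  chk(cfg$replicating$percentile > 0 && cfg$replicating$percentile < 100,
      "replicating$percentile must be in (0,100)")
  chk(cfg$replicating$n_null >= 1, "replicating$n_null must be >= 1")
  chk(cfg$replicating$group_size >= 2, "replicating$group_size must be >= 2")
  chk(cfg$matching$min_moa_occurrences >= 2, "matching$min_moa_occurrences must be >= 2")
  chk(cfg$dead_cell$area_max > 0, "dead_cell$area_max must be > 0")
  chk(cfg$dead_cell$ratio_min > 0, "dead_cell$ratio_min must be > 0")
  chk(cfg$senescence$area_z > 0, "senescence$area_z must be > 0")
  chk(cfg$senescence$intensity_z > 0, "senescence$intensity_z must be > 0")
  if (length(problems)) {
    abort_paintqc(
      paste0("invalid configuration:\n", paste("-", problems, collapse = "\n")),
      "paintqc_config_error"
    )
  }
  invisible(cfg)
}

#' Read and write pipeline configuration as YAML
#'
#' The YAML file mirrors the nested structure of [pipeline_config()]; fields
#' absent from the file keep their defaults.
#'
#' @param path File path.
#' @param config A `paintqc_config` object.
#' @return `read_config()` returns a validated `paintqc_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
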