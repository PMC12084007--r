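# Synthetic 384-well Cell Painting screen generator.
#
# Emulates the statistical structure the downstream analysis assumes: plates
# with test compounds in columns 1-22 and controls in 23-24, replicated
# layouts, sparse additive compound effects expressed in DMSO-MAD units,
# overdispersed cell counts with depressed counts for toxic compounds, plate
# drift and rim artifacts, and (at the single-cell level) dead cells,
# feature-space outlier cells and invalid values. All generators are pure
# functions of (config, seed); per-plate substreams are derived from the one
# global seed so plate subsets are independently reproducible.

#' Configuration for the synthetic screen generator
#'
#' Defaults describe the screen this pipeline is sized for: 2,464 test
#' compounds on seven 384-well plates, four replicates, 2,000 seeded cells
#' per well (a Hep G2-like density; use 700 for a U-2 OS-like plate).
#' Compound effects are additive in normalized-feature space with magnitudes
#' in DMSO-MAD units, so `effect_scale_active = 5` means an affected feature
#' sits about five robust z-units from the DMSO center after plate
#' normalization — comfortably past the induction threshold of 3 — while
#' `effect_scale_low = 1` stays inside it.
#'
#' @param n_features Number of image features to synthesize.
#' @param n_compounds Number of test compounds.
#' @param n_plates Number of library plates (capacity 352 compounds each).
#' @param n_replicates Technical replicates (independent plate copies).
#' @param effect_sparsity Fraction of features perturbed per active compound.
#' @param effect_scale_active,effect_scale_low Effect magnitude for active /
#'   low-active compounds, in DMSO-MAD units.
#' @param frac_toxic,frac_low_active Fractions of compounds that are toxic /
#'   low-active; label counts are `round(frac * n_compounds)` exactly.
#' @param baseline_cell_count Expected cells per untreated well.
#' @param count_dispersion Negative-binomial size parameter for well counts
#'   (smaller = more overdispersed).
#' @param toxic_count_factor Multiplier (< 1) on expected count for toxic
#'   compounds; nocodazole and tetrandrine control wells use `0.3` and `0.6`
#'   of baseline respectively.
#' @param plate_drift_amplitude Amplitude of smooth row/column gradients,
#'   per feature, in raw feature units.
#' @param rim_effect_amplitude Additive offset applied to edge wells (rows
#'   A/P, columns 1 and 23--24) on the first 10% of features.
#' @param dead_cell_frac_base,dead_cell_frac_toxic Dead-cell fraction per
#'   well for ordinary and toxic/nocodazole wells (single-cell generator).
#' @param outlier_cell_frac Fraction of cells drawn from a shifted
#'   distribution in a random feature subset.
#' @param invalid_cell_frac Fraction of cells carrying a missing or infinite
#'   feature value.
#' @param noise_sd Well-to-well (and cell-to-cell) Gaussian noise SD in raw
#'   feature units.
#' @param site,cell_line Metadata labels stamped on generated profiles.
#' @param seed Global seed; all substreams derive from it.
#' @return A validated `synthetic_config` list.
#' @examples
#' cfg <- synthetic_config(n_compounds = 20, n_plates = 1, n_features = 30)
#' @export
synthetic_config <- function(n_features = 300L,
                             n_compounds = 2464L,
                             n_plates = 7L,
                             n_replicates = 4L,
                             effect_sparsity = 0.1,
                             effect_scale_active = 5,
                             effect_scale_low = 1,
                             frac_toxic = 0.05,
                             frac_low_active = 0.3,
                             baseline_cell_count = 2000L,
                             count_dispersion = 20,
                             toxic_count_factor = 0.2,
                             plate_drift_amplitude = 0.2,
                             rim_effect_amplitude = 0.5,
                             dead_cell_frac_base = 0.02,
                             dead_cell_frac_toxic = 0.3,
                             outlier_cell_frac = 0.05,
                             invalid_cell_frac = 0.01,
                             noise_sd = 1,
                             site = "synthetic_site",
                             cell_line = "HepG2-like",
                             seed = 42L) {
  cfg <- list(
    n_features = as.integer(n_features), n_compounds = as.integer(n_compounds),
    n_plates = as.integer(n_plates), n_replicates = as.integer(n_replicates),
    effect_sparsity = effect_sparsity,
    effect_scale_active = effect_scale_active, effect_scale_low = effect_scale_low,
    frac_toxic = frac_toxic, frac_low_active = frac_low_active,
    baseline_cell_count = as.integer(baseline_cell_count),
    count_dispersion = count_dispersion, toxic_count_factor = toxic_count_factor,
    plate_drift_amplitude = plate_drift_amplitude,
    rim_effect_amplitude = rim_effect_amplitude,
    dead_cell_frac_base = dead_cell_frac_base,
    dead_cell_frac_toxic = dead_cell_frac_toxic,
    outlier_cell_frac = outlier_cell_frac,
    invalid_cell_frac = invalid_cell_frac,
    noise_sd = noise_sd, site = site, cell_line = cell_line,
    seed = as.integer(seed)
  )
  fracs <- c("effect_sparsity", "frac_toxic", "frac_low_active",
             "dead_cell_frac_base", "dead_cell_frac_toxic",
             "outlier_cell_frac", "invalid_cell_frac")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort_paintqc(sprintf("%s must be in [0,1]", f), "paintqc_config_error")
    }
  }
  if (cfg$frac_toxic + cfg$frac_low_active > 1) {
    abort_paintqc("frac_toxic + frac_low_active must be <= 1", "paintqc_config_error")
  }
  if (cfg$n_replicates < 2) {
    abort_paintqc("n_replicates must be >= 2", "paintqc_config_error")
  }
  if (cfg$toxic_count_factor >= 1 || cfg$toxic_count_factor <= 0) {
    abort_paintqc("toxic_count_factor must be in (0,1)", "paintqc_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

# One raw-unit step per DMSO-MAD: the MAD of N(0, sd) noise is qnorm(0.75)*sd.
mad_unit <- function(config) stats::qnorm(0.75) * config$noise_sd

compound_ids <- function(config) sprintf("CPD%05d", seq_len(config$n_compounds))

# Per-feature baselines, shared by every plate; drawn once from the seed.
feature_baselines <- function(config) {
  with_seed(derive_seed(config$seed, "baselines"),
            stats::rnorm(config$n_features, mean = 10, sd = 2))
}

feature_names <- function(config) sprintf("feat_%04d", seq_len(config$n_features))

rim_feature_idx <- function(config) {
  seq_len(max(1L, round(0.1 * config$n_features)))
}

# Ground-truth compound labels: exact counts, randomized assignment.
draw_labels <- function(config) {
  n <- config$n_compounds
  n_toxic <- round(config$frac_toxic * n)
  n_low <- round(config$frac_low_active * n)
  with_seed(derive_seed(config$seed, "labels"), {
    ord <- sample.int(n)
    is_toxic <- logical(n)
    is_low <- logical(n)
    is_toxic[ord[seq_len(n_toxic)]] <- TRUE
    if (n_low > 0) is_low[ord[n_toxic + seq_len(n_low)]] <- TRUE
    tibble::tibble(compound_id = compound_ids(config),
                   is_toxic = is_toxic, is_low_active = is_low)
  })
}

# Sparse effect matrix (rows: compounds + controls, cols: features), raw units.
draw_effects <- function(config, labels, stream = "effects") {
  n_feat <- config$n_features
  k <- max(1L, round(config$effect_sparsity * n_feat))
  unit <- mad_unit(config)
  with_seed(derive_seed(config$seed, stream), {
    eff <- matrix(0, nrow = config$n_compounds + 3L, ncol = n_feat,
                  dimnames = list(c(compound_ids(config),
                                    "nocodazole", "tetrandrine", "DMSO"),
                                  feature_names(config)))
    for (i in seq_len(config$n_compounds)) {
      scale <- if (labels$is_low_active[i]) {
        config$effect_scale_low
      } else {
        config$effect_scale_active
      }
      idx <- sample.int(n_feat, k)
      eff[i, idx] <- sample(c(-1, 1), k, replace = TRUE) * scale * unit
    }
    # positive controls: strong, distinctive phenotypes
    k_ctrl <- max(1L, round(0.2 * n_feat))
    for (ctrl in c("nocodazole", "tetrandrine")) {
      idx <- sample.int(n_feat, k_ctrl)
      eff[ctrl, idx] <- sample(c(-1, 1), k_ctrl, replace = TRUE) *
        1.5 * config$effect_scale_active * unit
    }
    eff
  })
}

count_mu <- function(role, compound_id, labels, config) {
  base <- config$baseline_cell_count
  mu <- rep(base, length(role))
  toxic_ids <- labels$compound_id[labels$is_toxic]
  mu[compound_id %in% toxic_ids] <- base * config$toxic_count_factor
  mu[role == "positive_control_nocodazole"] <- base * 0.3
  mu[role == "positive_control_tetrandrine"] <- base * 0.6
  mu
}

# Smooth within-plate gradient in [-1, 1] per well.
drift_gradient <- function(wells) {
  r <- match(well_row(wells), PLATE_ROWS)
  cc <- well_col(wells)
  ((r - 8.5) / 7.5 + (cc - 12.5) / 11.5) / 2
}

is_rim_well <- function(wells) {
  well_row(wells) %in% c("A", "P") | well_col(wells) %in% c(1L, 23L, 24L)
}

sim_plate_replicate <- function(layout_plate, effects, labels, config,
                                replicate, stream) {
  filled <- layout_plate[layout_plate$role != "empty", ]
  n_wells <- nrow(filled)
  n_feat <- config$n_features
  base <- feature_baselines(config)
  with_seed(derive_seed(config$seed, stream, layout_plate$plate_id[1], replicate), {
    # per-(plate, replicate) drift direction per feature
    drift_coef <- stats::runif(n_feat, -1, 1)
    grad <- drift_gradient(filled$well)
    mat <- matrix(stats::rnorm(n_wells * n_feat, sd = config$noise_sd),
                  nrow = n_wells)
    mat <- sweep(mat, 2, base, `+`)
    mat <- mat + outer(grad, config$plate_drift_amplitude * drift_coef)
    rim <- which(is_rim_well(filled$well))
    if (length(rim) && config$rim_effect_amplitude != 0) {
      mat[rim, rim_feature_idx(config)] <-
        mat[rim, rim_feature_idx(config)] + config$rim_effect_amplitude
    }
    mat <- mat + effects[filled$compound_id, , drop = FALSE]
    mu <- count_mu(filled$role, filled$compound_id, labels, config)
    counts <- stats::rnbinom(n_wells, size = config$count_dispersion, mu = mu)
    colnames(mat) <- feature_names(config)
    dplyr::bind_cols(
      tibble::tibble(
        site = config$site, cell_line = config$cell_line,
        plate_id = filled$plate_id, replicate = as.integer(replicate),
        well = filled$well, compound_id = filled$compound_id,
        role = filled$role, concentration_uM = filled$concentration_uM,
        cell_count = as.integer(counts)
      ),
      tibble::as_tibble(mat)
    )
  })
}

#' Simulate a replicated multi-plate screen at the well level
#'
#' Generates a well-level profile table directly (one row per plate x
#' replicate x filled well): DMSO wells are feature noise around per-feature
#' baselines plus plate drift and rim offsets; compound wells add their
#' sparse ground-truth effect vector; toxic compounds (and the positive
#' controls) have depressed negative-binomial cell counts. The compound to
#' well assignment is identical across replicates; every replicate is an
#' independently drifting physical plate.
#'
#' @param config A [synthetic_config()].
#' @param effects Optional effect matrix overriding the default sparse draw
#'   (rows: compound ids plus `nocodazole`, `tetrandrine`, `DMSO`; columns:
#'   features, raw units) — used e.g. after [assign_moas()] to give MOA
#'   members shared effect vectors. Ground-truth labels are a deterministic
#'   function of `config` and are unchanged by this override.
#' @return A list with `profiles` (profile tibble), `truth` (list:
#'   `compounds` label tibble, `effects` matrix in raw feature units),
#'   and `layouts` (the [build_layout()] tibble).
#' @examples
#' sim <- simulate_profiles(synthetic_config(
#'   n_compounds = 20, n_plates = 1, n_features = 30
#' ))
#' dim(sim$profiles)
#' @export
simulate_profiles <- function(config, effects = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  layouts <- build_layout(config$n_plates, compound_ids(config))
  labels <- draw_labels(config)
  if (is.null(effects)) effects <- draw_effects(config, labels)
  sim_profiles_from_effects(layouts, effects, labels, config, stream = "wells")
}

sim_profiles_from_effects <- function(layouts, effects, labels, config, stream) {
  plate_ids <- unique(layouts$plate_id)
  rows <- list()
  for (p in plate_ids) {
    lp <- layouts[layouts$plate_id == p, ]
    for (r in seq_len(config$n_replicates)) {
      rows[[length(rows) + 1L]] <- sim_plate_replicate(lp, effects, labels,
                                                       config, r, stream)
    }
  }
  profiles <- dplyr::bind_rows(rows)
  list(profiles = profiles,
       truth = list(compounds = labels, effects = effects),
       layouts = layouts)
}

#' Simulate a single-cell feature table for one plate
#'
#' Per filled well, draws a negative-binomial number of cells spread over
#' fields 1--9. Live cells carry Gaussian generic features around the global
#' baselines plus the three classifier features (`cell_area` ~ N(2500, 500)
#' um^2, `cell_width_length_ratio` uniform on (0.2, 0.8),
#' `nuclear_mean_intensity` ~ N(100, 15)). Dead cells are small and round
#' with a bright nucleus (`cell_area` uniform on (200, 900),
#' ratio uniform on (0.85, 0.995), intensity ~ N(220, 20)), so they satisfy
#' the dead-cell classifier by construction. Outlier cells are shifted by 8
#' noise SDs in a random quarter of the generic features. A fraction of
#' cells carries one missing or infinite feature value. Per-well label
#' counts are `round(fraction * n)` exactly.
#'
#' @param layout A single plate's rows from [build_layout()].
#' @param config A [synthetic_config()]; `baseline_cell_count` sets the
#'   per-well expected cell number.
#' @param toxic_compounds Compound ids whose wells use
#'   `dead_cell_frac_toxic` and depressed counts (nocodazole wells do too).
#' @return A list with `cells` (single-cell tibble) and `truth` (per-cell
#'   tibble: `plate_id, well, object_id, is_dead, is_outlier, is_invalid`).
#' @export
simulate_single_cells <- function(layout, config, toxic_compounds = character(0)) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_layout(layout)
  plate <- layout$plate_id[1]
  filled <- layout[layout$role != "empty", ]
  base <- feature_baselines(config)
  n_feat <- config$n_features
  fnames <- feature_names(config)
  cells_list <- vector("list", nrow(filled))
  truth_list <- vector("list", nrow(filled))
  with_seed(derive_seed(config$seed, "cells", plate), {
    next_id <- 1L
    for (i in seq_len(nrow(filled))) {
      role <- filled$role[i]
      toxicish <- filled$compound_id[i] %in% toxic_compounds ||
        role == "positive_control_nocodazole"
      mu <- if (toxicish) {
        config$baseline_cell_count * config$toxic_count_factor
      } else {
        config$baseline_cell_count
      }
      n <- stats::rnbinom(1, size = config$count_dispersion, mu = mu)
      if (n == 0) next
      dead_frac <- if (toxicish) config$dead_cell_frac_toxic else config$dead_cell_frac_base
      n_dead <- round(dead_frac * n)
      n_out <- round(config$outlier_cell_frac * n)
      n_inv <- round(config$invalid_cell_frac * n)
      is_dead <- seq_len(n) <= n_dead
      is_out <- logical(n)
      if (n_out > 0) is_out[sample(which(!is_dead), min(n_out, sum(!is_dead)))] <- TRUE
      mat <- matrix(stats::rnorm(n * n_feat, sd = config$noise_sd), nrow = n)
      mat <- sweep(mat, 2, base, `+`)
      mat <- mat + effect_row_for_cells(filled$compound_id[i], config)
      if (any(is_out)) {
        k <- max(1L, round(0.25 * n_feat))
        for (j in which(is_out)) {
          idx <- sample.int(n_feat, k)
          mat[j, idx] <- mat[j, idx] + 8 * config$noise_sd
        }
      }
      area <- stats::rnorm(n, 2500, 500)
      ratio <- stats::runif(n, 0.2, 0.8)
      nuc <- stats::rnorm(n, 100, 15)
      if (n_dead > 0) {
        area[is_dead] <- stats::runif(n_dead, 200, 900)
        ratio[is_dead] <- stats::runif(n_dead, 0.85, 0.995)
        nuc[is_dead] <- stats::rnorm(n_dead, 220, 20)
      }
      is_inv <- logical(n)
      if (n_inv > 0) {
        inv_idx <- sample.int(n, n_inv)
        is_inv[inv_idx] <- TRUE
        for (j in inv_idx) {
          mat[j, sample.int(n_feat, 1)] <- sample(c(NA_real_, Inf, -Inf), 1)
        }
      }
      ids <- next_id - 1L + seq_len(n)
      next_id <- next_id + n
      tab <- tibble::tibble(
        plate_id = plate, well = filled$well[i],
        field = as.integer((ids %% 9L) + 1L), object_id = ids,
        cell_area = area, cell_width_length_ratio = ratio,
        nuclear_mean_intensity = nuc
      )
      feat_tab <- tibble::as_tibble(mat, .name_repair = "minimal")
      names(feat_tab) <- fnames
      cells_list[[i]] <- dplyr::bind_cols(tab, feat_tab)
      truth_list[[i]] <- tibble::tibble(
        plate_id = plate, well = filled$well[i], object_id = ids,
        is_dead = is_dead, is_outlier = is_out, is_invalid = is_inv
      )
    }
  })
  list(cells = dplyr::bind_rows(cells_list),
       truth = dplyr::bind_rows(truth_list))
}

# Single-cell tables carry no sparse compound effect (well-level structure is
# what the profile generator owns); controls keep zero offset too. Kept as a
# hook so a cell-level effect could be added in one place.
effect_row_for_cells <- function(compound_id, config) 0

#' Simulate two screens of the same compounds with a set cross-site correlation
#'
#' Builds two datasets sharing compounds, layouts and labels whose
#' per-compound effect vectors correlate at `cross_site_correlation`
#' (`rho`): dataset B's effect vector is `rho * E_A + sqrt(1-rho^2) * E'`
#' with `E'` an independent draw of the same scale. For this generator the
#' effect vectors are dense Gaussian (scale matched to the sparse
#' generator's total effect energy) so that the correlation level is exact
#' in expectation. Noise and plate effects are independent between datasets.
#'
#' @param config A [synthetic_config()].
#' @param cross_site_correlation Target effect-vector correlation in [0, 1].
#' @return A list with `profiles_a`, `profiles_b`, `truth`, `layouts`.
#' @export
simulate_paired_datasets <- function(config, cross_site_correlation) {
  stopifnot(inherits(config, "synthetic_config"))
  if (cross_site_correlation < 0 || cross_site_correlation > 1) {
    abort_paintqc("cross_site_correlation must be in [0,1]", "paintqc_config_error")
  }
  rho <- cross_site_correlation
  layouts <- build_layout(config$n_plates, compound_ids(config))
  labels <- draw_labels(config)
  n_feat <- config$n_features
  n_row <- config$n_compounds + 3L
  tau <- config$effect_scale_active * mad_unit(config) * sqrt(config$effect_sparsity)
  dn <- list(c(compound_ids(config), "nocodazole", "tetrandrine", "DMSO"),
             feature_names(config))
  eff <- with_seed(derive_seed(config$seed, "paired_effects"), {
    ea <- matrix(stats::rnorm(n_row * n_feat, sd = tau), nrow = n_row, dimnames = dn)
    ep <- matrix(stats::rnorm(n_row * n_feat, sd = tau), nrow = n_row, dimnames = dn)
    ea["DMSO", ] <- 0
    ep["DMSO", ] <- 0
    low <- labels$compound_id[labels$is_low_active]
    shrink <- config$effect_scale_low / config$effect_scale_active
    ea[low, ] <- ea[low, ] * shrink
    ep[low, ] <- ep[low, ] * shrink
    list(a = ea, b = rho * ea + sqrt(1 - rho^2) * ep)
  })
  sim_a <- sim_profiles_from_effects(layouts, eff$a, labels, config, stream = "siteA")
  sim_b <- sim_profiles_from_effects(layouts, eff$b, labels, config, stream = "siteB")
  sim_b$profiles$site <- paste0(config$site, "_b")
  list(profiles_a = sim_a$profiles, profiles_b = sim_b$profiles,
       truth = list(compounds = labels, effects_a = eff$a, effects_b = eff$b),
       layouts = layouts)
}

#' Assign mechanism-of-action annotations to synthetic compounds
#'
#' Groups the first `n_moas * moa_size` non-toxic, non-low-active compounds
#' into MOA classes and, optionally, rewrites their effect vectors so that
#' members of one MOA share a common effect direction (what the matching
#' metric is meant to detect). Remaining compounds get no annotation.
#'
#' @param truth The `truth` element of [simulate_profiles()].
#' @param config The generating [synthetic_config()].
#' @param n_moas Number of MOA classes.
#' @param moa_size Members per class.
#' @param share_effects If `TRUE`, members of an MOA get identical
#'   ground-truth effect vectors (plus nothing else); the returned `effects`
#'   matrix replaces the one in `truth`.
#' @return A list with `annotations` (tibble: compound_id, targets, moas)
#'   and `effects` (possibly rewritten matrix).
#' @export
assign_moas <- function(truth, config, n_moas = 25L, moa_size = 4L,
                        share_effects = TRUE) {
  labels <- truth$compounds
  eligible <- labels$compound_id[!labels$is_toxic & !labels$is_low_active]
  need <- n_moas * moa_size
  if (length(eligible) < need) {
    abort_paintqc(sprintf(
      "need %d active compounds for %d MOAs of size %d, have %d",
      need, n_moas, moa_size, length(eligible)), "paintqc_config_error")
  }
  members <- eligible[seq_len(need)]
  moa_of <- rep(sprintf("MOA%03d", seq_len(n_moas)), each = moa_size)
  effects <- truth$effects
  if (share_effects) {
    for (m in unique(moa_of)) {
      ids <- members[moa_of == m]
      proto <- effects[ids[1], ]
      for (id in ids[-1]) effects[id, ] <- proto
    }
  }
  ann <- tibble::tibble(
    compound_id = labels$compound_id,
    targets = lapply(labels$compound_id, function(x) character(0)),
    moas = lapply(labels$compound_id, function(id) {
      i <- match(id, members)
      if (is.na(i)) character(0) else moa_of[i]
    })
  )
  list(annotations = ann, effects = effects)
}
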