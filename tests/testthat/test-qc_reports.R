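make_plate_profiles <- function(counts_by_well = NULL, feature_vals = NULL,
                                n_reps = 1L) {
  lay <- build_layout(1, sprintf("CPD%05d", 1:352))
  reps <- lapply(seq_len(n_reps), function(r) {
    tibble::tibble(
      site = "s", cell_line = "c", plate_id = lay$plate_id,
      replicate = as.integer(r), well = lay$well,
      compound_id = lay$compound_id, role = lay$role,
      concentration_uM = lay$concentration_uM,
      cell_count = if (is.null(counts_by_well)) 100L else counts_by_well,
      intensity = if (is.null(feature_vals)) 10 else feature_vals
    )
  })
  dplyr::bind_rows(reps)
}

test_that("object-count heatmap maps wells bijectively with global anchors", {
  prof <- make_plate_profiles()
  hm <- object_count_heatmap(prof, "plate01")
  expect_equal(dim(hm$matrix), c(16, 24))
  expect_true(all(hm$matrix == 100))
  expect_equal(hm$scale$anchor_low, 0)
  expect_equal(hm$scale$anchor_mid, 100)
  expect_equal(hm$scale$anchor_high, 100)
  expect_error(object_count_heatmap(prof, "nope"), class = "paintqc_schema_error")
})

test_that("count anchors round up to two significant digits", {
  counts <- rep(100L, 384)
  counts[1] <- 0L
  counts[2] <- 1234L    # global max -> 1300
  counts[3] <- 847L
  prof <- make_plate_profiles(counts_by_well = counts)
  hm <- object_count_heatmap(prof, "plate01")
  expect_equal(hm$scale$anchor_high, 1300)
  expect_equal(hm$matrix["A", "1"], 0)    # empty well sits at the red anchor
  # permutation invariance of the matrix
  hm2 <- object_count_heatmap(prof[sample.int(nrow(prof)), ], "plate01")
  expect_identical(hm2$matrix, hm$matrix)
})

test_that("intensity heatmap divides by the plate median with fixed anchors", {
  vals <- rep(10, 384)
  vals[5] <- 15
  prof <- make_plate_profiles(feature_vals = vals)
  hm <- intensity_heatmap(prof, "plate01", "intensity")
  expect_equal(unname(hm$scale), list(0.5, 1.0, 1.5), ignore_attr = TRUE)
  expect_equal(sum(hm$matrix == 1.5, na.rm = TRUE), 1L)
  expect_equal(median(hm$matrix, na.rm = TRUE), 1.0)
  zero <- make_plate_profiles(feature_vals = rep(0, 384))
  expect_error(intensity_heatmap(zero, "plate01", "intensity"),
               class = "paintqc_degenerate_scale_error")
  expect_error(intensity_heatmap(prof, "plate01", "absent"),
               class = "paintqc_schema_error")
})

test_that("replicate-median heatmap attenuates single-replicate artifacts", {
  prof <- make_plate_profiles(n_reps = 4L)
  # artifact: one replicate's well A01 is 10x
  hit <- prof$replicate == 4 & prof$well == "A01"
  prof$intensity[hit] <- 100
  hm <- replicate_median_heatmap(prof, "plate01", "intensity")
  # median over (1,1,1,~10) normalized replicates stays at 1
  expect_equal(hm$matrix["A", "1"], 1.0, tolerance = 0.05)
  # identical replicates reproduce each replicate's normalized map
  clean <- make_plate_profiles(n_reps = 3L)
  hm2 <- replicate_median_heatmap(clean, "plate01", "intensity")
  expect_true(all(abs(hm2$matrix - 1) < 1e-12, na.rm = TRUE))
  # replicate values (1, 2, 3, 100) in one well -> median 2.5 before scaling;
  # plate medians are 1 each so the map shows median of normalized values
  prof2 <- make_plate_profiles(n_reps = 4L, feature_vals = rep(1, 384))
  prof2$intensity[prof2$well == "B02"] <- c(1, 2, 3, 100)
  hm3 <- replicate_median_heatmap(prof2, "plate01", "intensity")
  expect_equal(hm3$matrix["B", "2"], 2.5)
})

test_that("rim-affected synthetic plates show edge/interior contrast", {
  cfg <- tiny_synth(n_compounds = 352, rim_effect_amplitude = 2,
                    plate_drift_amplitude = 0)
  sim <- simulate_profiles(cfg)
  hm <- intensity_heatmap(sim$profiles, "plate01", "feat_0001")
  edge <- hm$matrix[c("A", "P"), ]
  interior <- hm$matrix[3:14, 2:22]
  expect_gt(mean(edge, na.rm = TRUE), mean(interior, na.rm = TRUE))
})

test_that("heatmap CSV export writes a 16x24 grid with a scale sidecar", {
  prof <- make_plate_profiles()
  hm <- object_count_heatmap(prof, "plate01")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_heatmap(hm, tf)
  grid <- utils::read.csv(tf, check.names = FALSE)
  expect_equal(dim(grid), c(16, 25))
  scale <- jsonlite::read_json(sub("\\.csv$", "_scale.json", tf))
  expect_equal(scale$anchor_mid, 100)
})

test_that("control-replicate correlation covers every plate/control pair", {
  sim <- simulate_profiles(tiny_synth(n_compounds = 30, n_plates = 2))
  norm <- mad_robustize(sim$profiles)$profiles
  cc <- control_replicate_correlation(norm)
  expect_equal(nrow(cc), 2 * 3)   # 2 plates x {DMSO, nocodazole, tetrandrine}
  pos <- cc[grepl("positive", cc$control), ]
  neg <- cc[cc$control == "negative_control", ]
  # strong shared phenotypes correlate; DMSO is the low baseline
  expect_true(all(pos$median_r > 0.5))
  expect_true(all(neg$median_r < min(pos$median_r)))
})

test_that("identical control profiles give correlation 1, noise near 0", {
  mat <- matrix(rep(c(3, 1, 4, 1, 5), 6), nrow = 6, byrow = TRUE) +
    matrix(rnorm(30, sd = 1e-6), 6)
  prof <- toy_profiles(mat, roles = rep("positive_control_nocodazole", 6),
                       compounds = rep("nocodazole", 6))
  cc <- control_replicate_correlation(prof)
  expect_equal(cc$median_r, 1, tolerance = 1e-6)
})

test_that("senescence flags need both extreme area and low nuclear intensity", {
  set.seed(33)
  n <- 64
  area <- rnorm(n, 100, 1)
  nuc <- rnorm(n, 50, 1)
  # compound 1: big cells, dim nuclei; 2: big only; 3: dim only
  area[1] <- 100 + 10 * median(abs(area - median(area)))
  nuc[1] <- 50 - 10 * median(abs(nuc - median(nuc)))
  area[2] <- area[1]
  nuc[3] <- nuc[1]
  prof <- toy_profiles(cbind(cell_area = area, nuclear_mean_intensity = nuc),
                       roles = rep("test", n))
  names(prof)[10:11] <- c("cell_area", "nuclear_mean_intensity")
  sen <- senescence_scores(prof)
  flagged <- sen$compound_id[sen$flagged]
  expect_equal(flagged, "cpd01")
  expect_gt(sen$area_z[sen$compound_id == "cpd02"], 5)
  expect_false(sen$flagged[sen$compound_id == "cpd02"])
  expect_false(sen$flagged[sen$compound_id == "cpd03"])
})

test_that("senescence flag is monotone in both z-scores", {
  cfg <- pipeline_config()
  grid <- expand.grid(az = c(4, 5.01, 8), iz = c(-4, -5.01, -8))
  flag <- grid$az > cfg$senescence$area_z & grid$iz < -cfg$senescence$intensity_z
  # increasing area-z or decreasing intensity-z never unflags
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      if (grid$az[j] >= grid$az[i] && grid$iz[j] <= grid$iz[i]) {
        expect_true(!flag[i] || flag[j])
      }
    }
  }
})
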