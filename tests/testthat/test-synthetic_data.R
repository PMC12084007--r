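test_that("generators are bitwise reproducible from the seed", {
  cfg <- tiny_synth()
  expect_identical(simulate_profiles(cfg)$profiles, simulate_profiles(cfg)$profiles)
  lay <- build_layout(1, sprintf("CPD%05d", 1:10))
  cfg2 <- tiny_synth(n_compounds = 10, n_features = 6, baseline_cell_count = 40)
  expect_identical(simulate_single_cells(lay, cfg2)$cells,
                   simulate_single_cells(lay, cfg2)$cells)
  expect_identical(simulate_paired_datasets(cfg, 0.5)$profiles_b,
                   simulate_paired_datasets(cfg, 0.5)$profiles_b)
})

test_that("ground-truth label counts match the configured fractions exactly", {
  cfg <- tiny_synth(n_compounds = 37, frac_toxic = 0.1, frac_low_active = 0.25)
  truth <- simulate_profiles(cfg)$truth$compounds
  expect_equal(sum(truth$is_toxic), round(0.1 * 37))
  expect_equal(sum(truth$is_low_active), round(0.25 * 37))
  expect_false(any(truth$is_toxic & truth$is_low_active))
})

test_that("with frac_toxic = 0 no compound's expected count is depressed", {
  cfg <- tiny_synth(frac_toxic = 0, count_dispersion = 1e6)
  sim <- simulate_profiles(cfg)
  test_wells <- sim$profiles[sim$profiles$role == "test", ]
  # near-deterministic counts: every test well sits at the baseline, far
  # above baseline * toxic_count_factor
  expect_true(all(test_wells$cell_count >
                    cfg$baseline_cell_count * cfg$toxic_count_factor))
})

test_that("with zero effects, compound wells are indistinguishable from DMSO", {
  cfg <- tiny_synth(n_compounds = 100, n_features = 20,
                    effect_scale_active = 0, effect_scale_low = 0,
                    plate_drift_amplitude = 0, rim_effect_amplitude = 0,
                    noise_sd = 1, seed = 202)
  sim <- simulate_profiles(cfg)
  prof <- sim$profiles
  feats <- feature_cols(prof)
  pvals <- vapply(feats, function(f) {
    stats::t.test(prof[[f]][prof$role == "test"],
                  prof[[f]][prof$role == "negative_control"])$p.value
  }, numeric(1))
  # aggregate behavior: at alpha = 0.05 about 5% of 20 features reject
  expect_lt(sum(pvals < 0.05), 5)
})

test_that("single-cell dead fraction matches the configured rate", {
  lay <- build_layout(1, sprintf("CPD%05d", 1:44))
  cfg <- tiny_synth(n_compounds = 44, n_features = 5, frac_toxic = 0,
                    baseline_cell_count = 140, dead_cell_frac_base = 0.2,
                    outlier_cell_frac = 0, invalid_cell_frac = 0)
  sc <- simulate_single_cells(lay, cfg)
  n <- nrow(sc$cells)
  expect_gt(n, 5000)
  frac <- sum(sc$truth$is_dead) / n
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n) + 0.01)
  flagged <- classify_dead_cells(sc$cells)
  # dead cells satisfy the classifier by construction
  expect_true(all(flagged[sc$truth$is_dead]))
})

test_that("with all artifact fractions at zero nothing is flagged or dropped", {
  lay <- build_layout(1, sprintf("CPD%05d", 1:10))
  cfg <- tiny_synth(n_compounds = 10, n_features = 5, frac_toxic = 0,
                    baseline_cell_count = 50, dead_cell_frac_base = 0,
                    dead_cell_frac_toxic = 0, outlier_cell_frac = 0,
                    invalid_cell_frac = 0)
  sc <- simulate_single_cells(lay, cfg)
  expect_equal(sum(classify_dead_cells(sc$cells)), 0L)
  expect_equal(drop_invalid_cells(sc$cells)$removed_count, 0L)
})

test_that("paired datasets at correlation 1 and negligible noise pair perfectly", {
  cfg <- tiny_synth(n_compounds = 30, n_features = 40, frac_toxic = 0,
                    frac_low_active = 0, noise_sd = 0.02,
                    plate_drift_amplitude = 0, rim_effect_amplitude = 0)
  pd <- simulate_paired_datasets(cfg, 1)
  ca <- consensus_profiles(mad_robustize(pd$profiles_a)$profiles, include_controls = FALSE)
  cb <- consensus_profiles(mad_robustize(pd$profiles_b)$profiles, include_controls = FALSE)
  res <- percent_pairing(ca, cb, fast_config())
  expect_equal(res$value, 100)
})

test_that("paired effect vectors correlate near the requested level", {
  cfg <- tiny_synth(n_compounds = 60, n_features = 200)
  pd <- simulate_paired_datasets(cfg, 0.7)
  active <- pd$truth$compounds$compound_id[!pd$truth$compounds$is_low_active]
  rs <- vapply(active, function(id) {
    cor(pd$truth$effects_a[id, ], pd$truth$effects_b[id, ])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.7), 0.05)
})

test_that("invalid generator fractions are rejected", {
  expect_error(tiny_synth(frac_toxic = 0.6, frac_low_active = 0.6),
               class = "paintqc_config_error")
  expect_error(tiny_synth(dead_cell_frac_base = -0.1),
               class = "paintqc_config_error")
  expect_error(simulate_paired_datasets(tiny_synth(), 1.2),
               class = "paintqc_config_error")
})
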