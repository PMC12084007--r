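test_that("drop_invalid_cells removes exactly the rows with NA or infinite values", {
  mat <- matrix(rnorm(300), ncol = 3)
  mat[5, 2] <- NA
  mat[17, 1] <- Inf
  mat[60, 3] <- -Inf
  cells <- toy_cells(mat)
  out <- drop_invalid_cells(cells)
  expect_equal(out$removed_count, 3L)
  expect_equal(out$cells$object_id, setdiff(1:100, c(5, 17, 60)))

  clean <- toy_cells(matrix(rnorm(30), ncol = 3))
  out2 <- drop_invalid_cells(clean)
  expect_identical(out2$cells, clean)
  expect_equal(out2$removed_count, 0L)
})

test_that("HBOS histograms: uniform fill gives equal heights, constants degenerate", {
  x <- rep(seq(0.5, 9.5, by = 1), each = 40)   # exactly 40 per bin on [0,10)
  cells <- toy_cells(cbind(u = x, k = rep(1, length(x))))
  model <- fit_hbos(cells)
  expect_equal(model$features$u$heights, rep(1, 10))
  expect_true(model$features$k$degenerate)
  # constant feature contributes the same to every score
  s <- hbos_score(model, cells)
  expect_equal(diff(range(s)), 0)
  expect_identical(fit_hbos(cells), model)
})

test_that("HBOS scores match the brute-force histogram-density oracle", {
  set.seed(9)
  for (case in 1:3) {
    mat <- matrix(rnorm(1000 * 10, sd = case), ncol = 10)
    mat[, 1] <- rexp(1000)              # skewed feature
    mat[1:5, 2] <- mat[1:5, 2] + 20     # gross outliers
    cells <- toy_cells(mat)
    model <- fit_hbos(cells)
    expect_lt(max(abs(hbos_score(model, cells) -
                        oracle_hbos_scores(mat))), 1e-9)
  }
})

test_that("a lone extreme value gets the unique maximal HBOS score", {
  mat <- cbind(f = c(rep(0, 9), 10))
  cells <- toy_cells(mat)
  s <- hbos_score(fit_hbos(cells), cells)
  expect_equal(which.max(s), 10L)
  expect_gt(s[10], max(s[1:9]))
})

test_that("HBOS score is invariant under feature-column permutation", {
  mat <- matrix(rnorm(500), ncol = 5, dimnames = list(NULL, paste0("f", 1:5)))
  cells <- toy_cells(mat)
  s1 <- hbos_score(fit_hbos(cells), cells)
  shuffled <- cells[c(cell_metadata_cols(), paste0("f", c(3, 1, 5, 2, 4)))]
  s2 <- hbos_score(fit_hbos(shuffled), shuffled)
  expect_equal(s1, s2)
})

test_that("boundary tolerance clamps near-range scores and floors far ones", {
  train <- toy_cells(cbind(f = as.numeric(1:100)))
  model <- fit_hbos(train)   # range [1,100], bin width 9.9, tol 0.5
  probe <- toy_cells(cbind(f = c(0.9, 100.5, -50)))
  s <- hbos_score(model, probe)
  edge_height <- model$features$f$heights[1]
  expect_equal(s[1], log(1 / (edge_height + 0.1)))
  expect_equal(s[3], log(1 / (min(model$features$f$heights) + 0.1)))
})

test_that("hbos_filter removes exactly ceiling(contamination * n) cells", {
  for (n in c(7, 100, 501)) {
    cells <- toy_cells(matrix(rnorm(n * 3), ncol = 3))
    out <- hbos_filter(cells)
    expect_equal(nrow(out$removed), ceiling(0.1 * n))
    expect_equal(nrow(out$cells) + nrow(out$removed), n)
    # kept and removed partition the input
    expect_setequal(c(out$cells$object_id, out$removed$object_id),
                    cells$object_id)
  }
  # contamination below 1/n still removes one cell
  cells <- toy_cells(matrix(rnorm(30), ncol = 3))
  out <- hbos_filter(cells, pipeline_config(hbos = list(contamination = 0.001)))
  expect_equal(nrow(out$removed), 1L)
})

test_that("hbos_filter recovers injected outlier cells", {
  lay <- build_layout(1, sprintf("CPD%05d", 1:20))
  cfg <- tiny_synth(n_compounds = 20, n_features = 30, frac_toxic = 0,
                    baseline_cell_count = 150, dead_cell_frac_base = 0,
                    dead_cell_frac_toxic = 0, outlier_cell_frac = 0.1,
                    invalid_cell_frac = 0)
  sc <- simulate_single_cells(lay, cfg)
  out <- hbos_filter(sc$cells)
  truth_key <- paste(sc$truth$well, sc$truth$object_id)
  removed_key <- paste(out$removed$well, out$removed$object_id)
  hit <- mean(removed_key %in% truth_key[sc$truth$is_outlier])
  expect_gte(hit, 0.9)
})

test_that("dead-cell classifier uses strict thresholds and is monotone", {
  probe <- tibble::tibble(
    plate_id = "p", well = "A01", field = 1L, object_id = 1:4,
    cell_area = c(900, 1000, 900, 999.99),
    cell_width_length_ratio = c(0.9, 0.9, 0.83, 0.8300001)
  )
  expect_equal(classify_dead_cells(probe), c(TRUE, FALSE, FALSE, TRUE))
  # monotone: shrinking area / raising ratio never flips dead -> alive
  set.seed(4)
  base <- tibble::tibble(plate_id = "p", well = "A01", field = 1L,
                         object_id = 1:200,
                         cell_area = runif(200, 0, 2000),
                         cell_width_length_ratio = runif(200, 0, 1))
  d0 <- classify_dead_cells(base)
  smaller <- base
  smaller$cell_area <- smaller$cell_area * 0.5
  smaller$cell_width_length_ratio <- pmin(1, smaller$cell_width_length_ratio + 0.1)
  expect_true(all(classify_dead_cells(smaller)[d0]))
  expect_error(classify_dead_cells(base["cell_area"]), class = "paintqc_schema_error")
})

test_that("dead-cell percentages reproduce the reported control summaries", {
  # U-2 OS and Hep G2 control treatments: (dead, total) -> printed %
  expect_equal(dead_cell_summary(969, 444867), 0.2)
  expect_equal(dead_cell_summary(1516, 8206), 18.5)
  expect_equal(dead_cell_summary(86, 16699), 0.5)
  expect_equal(dead_cell_summary(1003, 922096), 0.1)
  expect_equal(dead_cell_summary(517, 48215), 1.1)
  expect_equal(dead_cell_summary(309, 32198), 1.0)
  expect_equal(dead_cell_summary(0, 100), 0.0)
  expect_error(dead_cell_summary(1, 0), class = "paintqc_domain_error")
})

test_that("aggregation takes per-well medians and counts remaining cells", {
  lay <- build_layout(1, c("cpdA", "cpdB"))
  cells <- dplyr::bind_rows(
    toy_cells(cbind(f01 = c(1, 2, 3)), well = "A01", plate = "plate01"),
    toy_cells(cbind(f01 = c(10, 20, 30, 40)), well = "A02", plate = "plate01")
  )
  agg <- aggregate_to_wells(cells, lay)
  expect_equal(agg$profiles$f01, c(2, 25))
  expect_equal(agg$profiles$cell_count, c(3L, 4L))
  # empty filled wells are reported, not silently dropped
  expect_true(all(c("A23", "B24") %in% agg$empty_wells))
  # permutation invariance
  shuf <- cells[sample.int(nrow(cells)), ]
  expect_equal(aggregate_to_wells(shuf, lay)$profiles, agg$profiles)
  # unknown wells are a consistency error
  bad <- cells
  bad$well[1] <- "X99"
  expect_error(aggregate_to_wells(bad, lay), class = "paintqc_consistency_error")
})

test_that("aggregated counts agree with ground-truth post-filter bookkeeping", {
  lay <- build_layout(1, sprintf("CPD%05d", 1:15))
  cfg <- tiny_synth(n_compounds = 15, n_features = 6, frac_toxic = 0,
                    baseline_cell_count = 80, dead_cell_frac_base = 0,
                    outlier_cell_frac = 0, invalid_cell_frac = 0.05)
  sc <- simulate_single_cells(lay, cfg)
  cleaned <- drop_invalid_cells(sc$cells)
  agg <- aggregate_to_wells(cleaned$cells, lay)
  expected <- table(cleaned$cells$well)
  expect_equal(agg$profiles$cell_count,
               as.integer(expected[agg$profiles$well]),
               ignore_attr = TRUE)
  expect_equal(cleaned$removed_count, sum(sc$truth$is_invalid))
})
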