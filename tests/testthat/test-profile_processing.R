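test_that("mad_robustize centers on the DMSO median and scales by raw MAD", {
  mat <- cbind(f = c(1, 2, 3, 4, 5, 5))
  roles <- c(rep("negative_control", 5), "test")
  prof <- toy_profiles(mat, roles)
  names(prof)[names(prof) == "f01"] <- "f"
  out <- mad_robustize(prof)
  # DMSO {1..5}: median 3, MAD 1; the test well at 5 -> (5-3)/(1+1e-6)
  expect_equal(out$profiles$f[6], 2 / (1 + 1e-6))
  expect_equal(out$stats$dmso_median, 3)
  expect_equal(out$stats$dmso_mad, 1)
})

test_that("constant DMSO features divide by epsilon, finitely", {
  mat <- cbind(f01 = c(7, 7, 7, 9))
  prof <- toy_profiles(mat, c(rep("negative_control", 3), "test"))
  out <- mad_robustize(prof)
  expect_equal(out$profiles$f01[1:3], c(0, 0, 0))
  expect_equal(out$profiles$f01[4], 2 / 1e-6)
  expect_true(all(is.finite(out$profiles$f01)))
})

test_that("after normalization every plate's DMSO wells have median 0 and MAD 1", {
  sim <- simulate_profiles(tiny_synth(n_plates = 2, n_compounds = 600))
  out <- mad_robustize(sim$profiles)
  norm <- out$profiles
  feats <- feature_cols(norm)
  for (plate in unique(norm$plate_id)) {
    for (rep_ in unique(norm$replicate)) {
      dmso <- norm[norm$plate_id == plate & norm$replicate == rep_ &
                     norm$role == "negative_control", ]
      med <- vapply(dmso[feats], median, numeric(1))
      mads <- vapply(dmso[feats], function(x) median(abs(x - median(x))), numeric(1))
      expect_lt(max(abs(med)), 1e-10)
      expect_lt(max(abs(mads - 1)), 1e-4)   # epsilon-induced error only
    }
  }
  expect_error(
    mad_robustize(dplyr::mutate(sim$profiles,
                                role = ifelse(role == "negative_control",
                                              "test", role))),
    "DMSO", class = "paintqc_normalization_error"
  )
})

test_that("feature selection drops NA, constant, outlier and correlated features", {
  set.seed(21)
  n <- 60
  base <- rnorm(n)
  mat <- cbind(
    good1 = base,
    good2 = rnorm(n),
    nacol = c(NA, rnorm(n - 1)),
    const = rep(2, n),
    spike = c(150, rnorm(n - 1)),
    dup = 2 * base           # r = 1 with good1
  )
  prof <- toy_profiles(mat, c(rep("negative_control", 4), rep("test", n - 4)))
  out <- select_features(prof)
  rep_ <- setNames(out$report$stage, out$report$feature)
  expect_equal(unname(rep_["nacol"]), "na")
  expect_equal(unname(rep_["const"]), "low_variance")
  expect_equal(unname(rep_["spike"]), "outlier")
  # exactly one of the perfectly correlated pair is dropped
  expect_equal(sort(unname(rep_[c("good1", "dup")])), c("correlated", "kept"))
  expect_equal(unname(rep_["good2"]), "kept")
  surv <- feature_cols(out$profiles)
  cmat <- abs(cor(as.matrix(out$profiles[surv])))
  diag(cmat) <- 0
  expect_lt(max(cmat), 0.9)
})

test_that("selection post-conditions hold on synthetic normalized data", {
  sim <- simulate_profiles(tiny_synth(n_compounds = 200, n_features = 80,
                                      n_plates = 1))
  norm <- mad_robustize(sim$profiles)$profiles
  out <- select_features(norm)
  surv <- feature_cols(out$profiles)
  expect_lte(max(abs(as.matrix(out$profiles[surv]))), 100)
  cmat <- abs(cor(as.matrix(out$profiles[surv])))
  diag(cmat) <- 0
  expect_lte(max(cmat), 0.9)
  # report partitions the feature set
  expect_setequal(out$report$feature, feature_cols(norm))
  expect_equal(sum(out$report$stage == "kept"), length(surv))
})

test_that("near-zero-variance screening needs both conditions", {
  n <- 100
  # frequency ratio 90/10 = 9 < 10: kept despite low unique fraction
  f_ratio_ok <- c(rep(0, 90), rep(1, 10))
  # ratio 95/5 = 19 > 10 and 2/100 unique: dropped
  f_nzv <- c(rep(0, 95), rep(1, 5))
  # high ratio but many unique values: kept
  f_unique <- c(rep(0, 80), rnorm(20))
  mat <- cbind(a = f_ratio_ok, b = f_nzv, c = f_unique, d = rnorm(n))
  prof <- toy_profiles(mat, c(rep("negative_control", 4), rep("test", n - 4)))
  rep_ <- setNames(select_features(prof)$report$stage,
                   select_features(prof)$report$feature)
  expect_equal(unname(rep_["a"]), "kept")
  expect_equal(unname(rep_["b"]), "low_variance")
  expect_equal(unname(rep_["c"]), "kept")
})

test_that("consensus is the replicate-wise median, tolerant of missing replicates", {
  mk <- function(rep_, vals) {
    toy_profiles(cbind(f01 = vals[1], f02 = vals[2]),
                 roles = "test", compounds = "cpd", replicate = rep_)
  }
  prof <- dplyr::bind_rows(mk(1, c(1, 1)), mk(2, c(2, 2)),
                           mk(3, c(3, 3)), mk(4, c(100, 100)))
  cons <- consensus_profiles(prof)
  expect_equal(unname(unlist(cons[c("f01", "f02")])), c(2.5, 2.5))
  # order invariance
  cons2 <- consensus_profiles(prof[c(3, 1, 4, 2), ])
  expect_equal(cons2, cons)
  # 3 of 4 replicates: median of the available three
  cons3 <- consensus_profiles(prof[1:3, ])
  expect_equal(cons3$f01, 2)
  expect_equal(cons3$consensus_cell_count, 100)
})
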