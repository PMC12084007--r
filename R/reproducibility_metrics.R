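# Correlation-based reproducibility metrics with permutation nulls.
#
# All four metrics share one skeleton: a per-item score (median pairwise
# Pearson correlation within a group of profiles, or a single cross-dataset
# correlation), a null distribution built from random non-matching groups of
# the same size, and a pass rule "score strictly above the configured
# percentile of the null". Null sampling is with replacement across the
# n_null draws and without replacement within a draw; the percentile uses
# the linear-interpolation convention (stats::quantile type 7).

# Rows standardized so tcrossprod(Z) is the matrix of pairwise Pearson
# correlations across feature columns. Zero-variance rows come back as NA.
row_standardize <- function(mat) {
  mu <- rowMeans(mat)
  cent <- mat - mu
  ss <- sqrt(rowSums(cent^2))
  ss[ss == 0] <- NA_real_
  cent / ss
}

#' Median pairwise Pearson correlation of a set of profiles
#'
#' @param vectors A numeric matrix (rows = profiles) or list of equal-length
#'   numeric vectors; at least 2 rows of length at least 3.
#' @return The median of Pearson r over all unordered row pairs.
#' @examples
#' median_pairwise_correlation(rbind(c(1, 2, 3, 5), c(2, 4, 6, 10), c(1, 1, 2, 2)))
#' @export
median_pairwise_correlation <- function(vectors) {
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (nrow(vectors) < 2 || ncol(vectors) < 3) {
    abort_paintqc("need >= 2 vectors of length >= 3", "paintqc_metric_error")
  }
  z <- row_standardize(vectors)
  if (anyNA(z)) {
    abort_paintqc("zero-variance vector: correlation undefined", "paintqc_metric_error")
  }
  cmat <- tcrossprod(z)
  stats::median(cmat[upper.tri(cmat)])
}

median_pairwise_from_z <- function(z, idx) {
  cmat <- tcrossprod(z[idx, , drop = FALSE])
  stats::median(cmat[upper.tri(cmat)])
}

make_null <- function(samples, config, descriptor) {
  threshold <- if (all(is.na(samples))) {
    NA_real_
  } else {
    unname(stats::quantile(samples, config$replicating$percentile / 100,
                           type = 7, names = FALSE))
  }
  list(samples = samples, percentile = config$replicating$percentile,
       threshold = threshold, seed = config$replicating$seed,
       descriptor = descriptor)
}

make_result <- function(metric, scores, null) {
  ok <- !is.na(scores$score)
  n_eval <- sum(ok)
  n_pass <- sum(scores$score[ok] > null$threshold)
  structure(list(
    metric = metric,
    value = if (n_eval > 0) 100 * n_pass / n_eval else NA_real_,
    n_evaluated = n_eval, n_passing = n_pass,
    null = null, scores = scores
  ), class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s: %.1f%% (%d of %d above null %gth percentile %.4f)\n",
              x$metric, x$value, x$n_passing, x$n_evaluated,
              x$null$percentile, x$null$threshold))
  invisible(x)
}

#' Permutation null of median non-replicate correlations
#'
#' Draws `n_null` random groups of `group_size` wells, each group taking
#' its wells from `group_size` distinct compounds (never two wells of the
#' same compound), and computes the median pairwise Pearson correlation of
#' each group. The pass threshold is the configured percentile of these
#' samples. Fully reproducible from `replicating$seed`.
#'
#' @param profiles A well-level profile tibble (the evaluated population).
#' @param config A [pipeline_config()]; uses the `replicating` group.
#' @return A null-distribution list: `samples`, `percentile`, `threshold`,
#'   `seed`, `descriptor`.
#' @export
replicate_null <- function(profiles, config = pipeline_config()) {
  feats <- feature_cols(profiles)
  cpds <- profiles$compound_id
  keep <- !is.na(cpds)
  z <- row_standardize(as.matrix(profiles[keep, feats]))
  cpds <- cpds[keep]
  groups <- split(seq_along(cpds), cpds)
  g <- config$replicating$group_size
  if (length(groups) < g) {
    abort_paintqc(sprintf("need >= %d distinct compounds for the null", g),
                  "paintqc_metric_error")
  }
  samples <- with_seed(derive_seed(config$replicating$seed, "replicate_null"), {
    vapply(seq_len(config$replicating$n_null), function(i) {
      picked <- sample.int(length(groups), g)
      idx <- vapply(groups[picked], function(ix) {
        if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
      }, integer(1))
      median_pairwise_from_z(z, idx)
    }, numeric(1))
  })
  make_null(samples, config,
            sprintf("median pairwise r of %d wells from %d distinct compounds", g, g))
}

#' Percent replicating
#'
#' For each compound with at least two replicate wells, the median pairwise
#' Pearson correlation over its replicate profiles; the compound replicates
#' when that value is strictly above the configured percentile (default
#' 95th) of the non-replicate null ([replicate_null()]). The metric is the
#' percentage of evaluated compounds that replicate. Compounds with a
#' single well, or with a zero-variance profile, are skipped and reported
#' with `NA` scores.
#'
#' @param profiles A filtered well-level profile tibble (test compounds,
#'   replicate labels present).
#' @param config A [pipeline_config()].
#' @param null Optional precomputed null (to share one null across calls).
#' @return A `metric_result`: `value` (%), `n_evaluated`, `n_passing`,
#'   `null`, per-compound `scores`.
#' @export
percent_replicating <- function(profiles, config = pipeline_config(), null = NULL) {
  validate_profile_table(profiles)
  test <- profiles[!is.na(profiles$compound_id) & profiles$role == "test", ]
  if (is.null(null)) null <- replicate_null(test, config)
  feats <- feature_cols(test)
  z <- row_standardize(as.matrix(test[feats]))
  groups <- split(seq_len(nrow(test)), test$compound_id)
  score_one <- function(ix) {
    if (length(ix) < 2L) return(NA_real_)
    zi <- z[ix, , drop = FALSE]
    if (anyNA(zi)) return(NA_real_)
    cmat <- tcrossprod(zi)
    stats::median(cmat[upper.tri(cmat)])
  }
  scores <- tibble::tibble(
    id = names(groups),
    n_replicates = lengths(groups),
    score = vapply(groups, score_one, numeric(1))
  )
  make_result("percent_replicating", scores, null)
}

# Long (compound, moa) pairs for MOAs with enough members among `ids`.
qualifying_moas <- function(annotations, ids, min_n) {
  ann <- annotations[annotations$compound_id %in% ids, ]
  long <- tibble::tibble(
    compound_id = rep(ann$compound_id, lengths(ann$moas)),
    moa = unlist(ann$moas)
  )
  if (nrow(long) == 0) return(long[0, ])
  counts <- table(long$moa)
  long[long$moa %in% names(counts)[counts >= min_n], ]
}

consensus_feature_matrix <- function(consensus) {
  feats <- setdiff(names(consensus), c("compound_id", "role", "consensus_cell_count"))
  feats <- feats[vapply(consensus[feats], is.numeric, logical(1))]
  m <- as.matrix(consensus[feats])
  rownames(m) <- consensus$compound_id
  m
}

#' Percent matching of mechanism-of-action groups
#'
#' Each MOA annotation on each compound counts as a separate MOA; MOAs with
#' at least `min_moa_occurrences` annotated compounds present in the
#' consensus table are evaluated. Per MOA, the median pairwise Pearson
#' correlation among its members' consensus profiles is compared with a
#' null of random same-size compound groups (drawn uniformly from all
#' compounds in the table, `n_null` draws per distinct group size). The
#' metric is the percentage of evaluated MOAs whose score is strictly above
#' the percentile threshold of their size's null.
#'
#' @param consensus A consensus tibble of test compounds.
#' @param annotations An annotation tibble ([read_annotations()]).
#' @param config A [pipeline_config()].
#' @return A `metric_result`; `scores` has one row per evaluated MOA.
#' @export
percent_matching <- function(consensus, annotations, config = pipeline_config()) {
  z <- row_standardize(consensus_feature_matrix(consensus))
  long <- qualifying_moas(annotations, rownames(z), config$matching$min_moa_occurrences)
  if (nrow(long) == 0) {
    return(make_result("percent_matching",
                       tibble::tibble(id = character(0), n_members = integer(0),
                                      score = numeric(0)),
                       make_null(NA_real_, config, "no qualifying MOA")))
  }
  members <- split(match(long$compound_id, rownames(z)), long$moa)
  sizes <- sort(unique(lengths(members)))
  nulls <- null_by_group_size(z, sizes, config, stream = "matching_null")
  scores <- tibble::tibble(
    id = names(members),
    n_members = lengths(members),
    score = vapply(members, function(ix) {
      zi <- z[ix, , drop = FALSE]
      if (anyNA(zi)) return(NA_real_)
      cmat <- tcrossprod(zi)
      stats::median(cmat[upper.tri(cmat)])
    }, numeric(1))
  )
  result_with_sized_nulls("percent_matching", scores, scores$n_members, nulls, config)
}

# One null distribution per group size; samples are median pairwise r of
# `size` distinct rows of z, drawn uniformly.
null_by_group_size <- function(z, sizes, config, stream) {
  n <- nrow(z)
  out <- list()
  for (s in sizes) {
    out[[as.character(s)]] <- with_seed(
      derive_seed(config$replicating$seed, stream, s), {
        samples <- vapply(seq_len(config$replicating$n_null), function(i) {
          median_pairwise_from_z(z, sample.int(n, s))
        }, numeric(1))
        make_null(samples, config,
                  sprintf("median pairwise r of %d random distinct compounds", s))
      })
  }
  out
}

result_with_sized_nulls <- function(metric, scores, sizes, nulls, config) {
  thr <- vapply(as.character(sizes), function(s) nulls[[s]]$threshold, numeric(1))
  ok <- !is.na(scores$score)
  n_pass <- sum(scores$score[ok] > thr[ok])
  n_eval <- sum(ok)
  scores$null_threshold <- unname(thr)
  structure(list(
    metric = metric,
    value = if (n_eval > 0) 100 * n_pass / n_eval else NA_real_,
    n_evaluated = n_eval, n_passing = n_pass,
    null = nulls, scores = scores
  ), class = "metric_result")
}

#' Percent pairing of two datasets' consensus profiles
#'
#' Restricts both tables to their shared compounds and the intersection of
#' their feature sets, correlates each compound's two consensus vectors,
#' and compares against a null of `n_null` random non-matching cross-dataset
#' pairs. The metric is the percentage of shared compounds whose
#' cross-dataset correlation is strictly above the percentile threshold.
#'
#' @param consensus_a,consensus_b Consensus tibbles from the two datasets.
#' @param config A [pipeline_config()].
#' @return A `metric_result`; `scores` has one row per shared compound and
#'   the result carries `n_shared_features`.
#' @export
percent_pairing <- function(consensus_a, consensus_b, config = pipeline_config()) {
  ma <- consensus_feature_matrix(consensus_a)
  mb <- consensus_feature_matrix(consensus_b)
  feats <- intersect(colnames(ma), colnames(mb))
  if (length(feats) < 3) {
    abort_paintqc(sprintf("feature intersection too small (%d < 3)", length(feats)),
                  "paintqc_metric_error")
  }
  shared <- intersect(rownames(ma), rownames(mb))
  if (length(shared) < 2) {
    abort_paintqc("need >= 2 shared compounds", "paintqc_metric_error")
  }
  za <- row_standardize(ma[shared, feats, drop = FALSE])
  zb <- row_standardize(mb[shared, feats, drop = FALSE])
  r <- rowSums(za * zb)
  n <- length(shared)
  samples <- with_seed(derive_seed(config$replicating$seed, "pairing_null"), {
    i <- sample.int(n, config$replicating$n_null, replace = TRUE)
    off <- sample.int(n - 1L, config$replicating$n_null, replace = TRUE)
    j <- ((i - 1L + off) %% n) + 1L   # j != i, uniform over non-matching pairs
    rowSums(za[i, , drop = FALSE] * zb[j, , drop = FALSE])
  })
  null <- make_null(samples, config,
                    "Pearson r of random non-matching cross-dataset pairs")
  scores <- tibble::tibble(id = shared, score = unname(r))
  res <- make_result("percent_pairing", scores, null)
  res$n_shared_features <- length(feats)
  res
}

#' Percent matching across datasets
#'
#' Like [percent_matching()], but each MOA's score is the median Pearson
#' correlation over cross-dataset member pairs only (every A-member
#' consensus against every B-member consensus, on the shared feature set).
#' An MOA qualifies only if it has at least `min_moa_occurrences` members
#' in each dataset. Nulls draw random member sets of the same (A, B) sizes
#' and score them the same cross-pair way.
#'
#' @param consensus_a,consensus_b Consensus tibbles from the two datasets.
#' @param annotations An annotation tibble covering both datasets' compounds.
#' @param config A [pipeline_config()].
#' @return A `metric_result`; `scores` has one row per evaluated MOA.
#' @export
percent_matching_across <- function(consensus_a, consensus_b, annotations,
                                    config = pipeline_config()) {
  ma <- consensus_feature_matrix(consensus_a)
  mb <- consensus_feature_matrix(consensus_b)
  feats <- intersect(colnames(ma), colnames(mb))
  if (length(feats) < 3) {
    abort_paintqc(sprintf("feature intersection too small (%d < 3)", length(feats)),
                  "paintqc_metric_error")
  }
  za <- row_standardize(ma[, feats, drop = FALSE])
  zb <- row_standardize(mb[, feats, drop = FALSE])
  min_n <- config$matching$min_moa_occurrences
  long_a <- qualifying_moas(annotations, rownames(za), min_n)
  long_b <- qualifying_moas(annotations, rownames(zb), min_n)
  moas <- intersect(unique(long_a$moa), unique(long_b$moa))
  if (length(moas) == 0) {
    return(make_result("percent_matching_across",
                       tibble::tibble(id = character(0), score = numeric(0)),
                       make_null(NA_real_, config, "no qualifying MOA")))
  }
  mem_a <- split(match(long_a$compound_id, rownames(za)), long_a$moa)[moas]
  mem_b <- split(match(long_b$compound_id, rownames(zb)), long_b$moa)[moas]
  cross_score <- function(ia, ib) {
    cm <- tcrossprod(za[ia, , drop = FALSE], zb[ib, , drop = FALSE])
    if (anyNA(cm)) NA_real_ else stats::median(cm)
  }
  scores <- tibble::tibble(
    id = moas,
    n_members_a = lengths(mem_a), n_members_b = lengths(mem_b),
    score = mapply(cross_score, mem_a, mem_b)
  )
  size_keys <- paste(scores$n_members_a, scores$n_members_b, sep = "x")
  nulls <- list()
  for (key in unique(size_keys)) {
    ss <- as.integer(strsplit(key, "x")[[1]])
    nulls[[key]] <- with_seed(
      derive_seed(config$replicating$seed, "matching_across_null", key), {
        samples <- vapply(seq_len(config$replicating$n_null), function(i) {
          cross_score(sample.int(nrow(za), ss[1]), sample.int(nrow(zb), ss[2]))
        }, numeric(1))
        make_null(samples, config,
                  sprintf("median cross-dataset r of random %d x %d groups", ss[1], ss[2]))
      })
  }
  thr <- vapply(size_keys, function(k) nulls[[k]]$threshold, numeric(1))
  ok <- !is.na(scores$score)
  scores$null_threshold <- unname(thr)
  structure(list(
    metric = "percent_matching_across",
    value = if (sum(ok)) 100 * sum(scores$score[ok] > thr[ok]) / sum(ok) else NA_real_,
    n_evaluated = sum(ok), n_passing = sum(scores$score[ok] > thr[ok]),
    null = nulls, scores = scores
  ), class = "metric_result")
}
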