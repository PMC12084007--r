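# Independent brute-force oracles, deliberately naive: these re-derive the
# quantities the package computes by explicit per-sample loops so the two
# routes share no code.

# HBOS oracle: per feature, recount the equal-width histogram, max-normalize,
# look up each sample's bin one at a time, and sum log(1/(h + alpha)).
oracle_hbos_scores <- function(mat, n_bins = 10, alpha = 0.1, tol = 0.5) {
  n <- nrow(mat)
  scores <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    lo <- min(x)
    hi <- max(x)
    if (lo == hi) {
      h_all <- rep(1, n)
    } else {
      edges <- seq(lo, hi, length.out = n_bins + 1)
      counts <- numeric(n_bins)
      for (v in x) {
        b <- min(n_bins, max(1, floor((v - lo) / (hi - lo) * n_bins) + 1))
        counts[b] <- counts[b] + 1
      }
      heights <- counts / max(counts)
      width <- (hi - lo) / n_bins
      h_all <- numeric(n)
      for (i in seq_len(n)) {
        v <- x[i]
        if (v < lo - tol * width || v > hi + tol * width) {
          h_all[i] <- min(heights)
        } else {
          b <- min(n_bins, max(1, floor((v - lo) / (hi - lo) * n_bins) + 1))
          h_all[i] <- heights[b]
        }
      }
    }
    scores <- scores + log(1 / (h_all + alpha))
  }
  scores
}

# Pearson r of two vectors from first principles.
oracle_pearson <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_median_pairwise <- function(mat) {
  n <- nrow(mat)
  rs <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rs <- c(rs, oracle_pearson(mat[i, ], mat[j, ]))
    }
  }
  median(rs)
}
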