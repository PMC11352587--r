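# Independent oracles and small fixtures, all built in code.

# 4x4 checkerboard starting with 0 in the top-left corner.
checkerboard4 <- function() {
  outer(1:4, 1:4, function(i, j) (i + j) %% 2L)
}

# Brute-force window census: slide a 3x3 window over every valid center
# and tabulate pattern codes one window at a time.
window_counts_oracle <- function(px) {
  counts <- integer(512)
  for (i in 2:(nrow(px) - 1L)) {
    for (j in 2:(ncol(px) - 1L)) {
      code <- patch_code(px[(i - 1L):(i + 1L), (j - 1L):(j + 1L)])
      counts[code + 1L] <- counts[code + 1L] + 1L
    }
  }
  counts
}

# Exhaustive subset search over pattern probabilities, independent of the
# package's mask-based solver: enumerates subsets via utils::combn.
best_subset_oracle <- function(probs, N, W) {
  m <- length(probs)
  best_h <- 0
  best_set <- integer(0)
  for (size in seq_len(min(N, m))) {
    sets <- utils::combn(m, size)
    for (ci in seq_len(ncol(sets))) {
      idx <- sets[, ci]
      if (sum(probs[idx]) <= W + 1e-12) {
        h <- sum(entropy_contribution(probs[idx]))
        if (h > best_h + 1e-12) {
          best_h <- h
          best_set <- idx
        }
      }
    }
  }
  list(entropy = best_h, idx = best_set)
}

# Full 2^n enumeration of the Wilcoxon signed-rank null: returns the
# two-sided p value for the observed paired differences.
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% r)
  total <- sum(r)
  w_min <- pmin(w_plus, total - w_plus)
  # two-sided: both tails at or beyond the observed smaller sum
  min(1, 2 * mean(w_plus <= w_obs + 1e-9))
}

# Random small patch distribution on distinct codes.
random_small_dist <- function(m, seed) {
  set.seed(seed)
  codes <- sort(sample(0:511, m))
  p <- runif(m)
  p <- p / sum(p)
  list(codes = codes, probs = p,
       dist = patch_distribution_from_probs(codes, p))
}

# Feature set holding exactly the given codes (bypasses selection).
new_fs_for_test <- function(codes) {
  fastvision:::new_feature_set(codes, rep(1 / 512, length(codes)),
                               N = max(1L, length(codes)), W = 1)
}
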