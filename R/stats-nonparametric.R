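# Nonparametric analysis chain: paired Wilcoxon signed-rank with
# rank-biserial effect size, Friedman test with Kendall's W, Conover post
# hoc comparisons, and the bandwidth-normalized threshold change score.

#' Threshold relative percentage change
#'
#' `100 * (T_flicker - T_baseline) / max_contrast`: the flicker-induced
#' threshold shift expressed as a percentage of the task's maximum tested
#' contrast, so elevations are comparable across tasks whose contrast
#' ladders span very different ranges. Positive when the flicker threshold
#' is higher.
#'
#' @param t_baseline,t_flicker Contrast thresholds (vectorized).
#' @param max_contrast Maximum contrast of the task's ladder, positive.
#' @return Percentage change score(s).
#' @examples
#' threshold_relative_change(0.14, 0.29, 1) # 15
#' @export
threshold_relative_change <- function(t_baseline, t_flicker, max_contrast) {
  if (any(max_contrast <= 0)) stop_domain("max_contrast must be positive")
  100 * (t_flicker - t_baseline) / max_contrast
}

# Signed ranks of paired differences after dropping zeros. Shared by the
# Wilcoxon test and the rank-biserial effect size.
signed_ranks <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  keep <- complete.cases(x, y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  if (length(d) == 0L) {
    stop_domain("all paired differences are zero (degenerate sample)")
  }
  r <- rank(abs(d))
  list(d = d, r = r, n = length(d),
       w_pos = sum(r[d > 0]), w_neg = sum(r[d < 0]))
}

# Exact null distribution of W+ over doubled ranks (doubling makes average
# ranks integral so a convolution over sign assignments is exact even with
# ties). Returns counts of each achievable doubled rank sum, 0..sum(2r).
wilcoxon_exact_counts <- function(r2) {
  total <- sum(r2)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  counts
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of the null of symmetric paired differences about zero.
#' Zero differences are dropped; tied absolute differences receive average
#' ranks. For `n_effective <= exact_max` the p value comes from the exact
#' null distribution of the signed-rank sum (computed by convolution over
#' all sign assignments, valid under ties); otherwise a normal
#' approximation with continuity and tie corrections is used.
#'
#' @param x,y Paired samples of equal length.
#' @param exact_max Largest effective n for which the exact distribution is
#'   used (default 25).
#' @return A `paired_result`: `statistic` (the smaller of the positive and
#'   negative rank sums), `w_pos`, `w_neg`, `n_effective`, `p_value`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  sr <- signed_ranks(x, y)
  w <- min(sr$w_pos, sr$w_neg)
  n <- sr$n
  if (n <= exact_max) {
    counts <- wilcoxon_exact_counts(round(2 * sr$r))
    # distribution of W+ is symmetric about sum(r)/2, so the probability of
    # the observed smaller-sum tail equals P(W+ <= min(W+, W-))
    p_low <- sum(counts[seq_len(round(2 * w) + 1L)]) / 2^n
    p <- min(1, 2 * p_low)
    method <- "exact"
  } else {
    m <- n * (n + 1) / 4
    tie_tab <- table(sr$r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (sr$w_pos - m - 0.5 * sign(sr$w_pos - m)) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(
    list(statistic = w, w_pos = sr$w_pos, w_neg = sr$w_neg,
         n_effective = n, p_value = p, method = method),
    class = "paired_result"
  )
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %.4g (W+ = %.4g, W- = %.4g), n = %d\n",
              x$statistic, x$w_pos, x$w_neg, x$n_effective))
  cat(sprintf("  two-sided p = %.4g (%s)\n", x$p_value, x$method))
  invisible(x)
}

#' Matched-pairs rank-biserial correlation with bootstrap CI
#'
#' `rrb = (R+ - R-) / (R+ + R-)` over the signed ranks of the paired
#' differences `x - y`; +1 when every difference is positive, -1 when every
#' difference is negative. The confidence interval is a seeded percentile
#' bootstrap over pairs.
#'
#' @param x,y Paired samples.
#' @param n_boot Bootstrap resamples (default 10000; 0 skips the CI).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return List with `rrb`, `ci` (length-2 vector, `NA` if `n_boot = 0`),
#'   `n_boot`, `conf`.
#' @export
rank_biserial <- function(x, y, n_boot = 10000L, seed = 1L, conf = 0.95) {
  sr <- signed_ranks(x, y)
  rrb <- (sr$w_pos - sr$w_neg) / (sr$w_pos + sr$w_neg)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    keep <- complete.cases(x, y)
    xx <- x[keep]
    yy <- y[keep]
    npairs <- length(xx)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(npairs, npairs, replace = TRUE)
        d <- xx[idx] - yy[idx]
        d <- d[d != 0]
        if (length(d) == 0L) return(NA_real_)
        r <- rank(abs(d))
        (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(rrb = rrb, ci = ci, n_boot = n_boot, conf = conf)
}

# Within-row ranks and the sums-of-squares building blocks shared by the
# Friedman test and the Conover post hocs. Follows the T1 formulation:
#   A1 = sum of squared ranks, C1 = n k (k+1)^2 / 4,
#   T1 = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A1 - C1),
# where average ranks make A1 - C1 the tie-corrected variance term.
friedman_parts <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop_domain("data must be complete (no missing cells)")
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2 || k < 2) stop_domain("need at least 2 rows and 2 columns")
  r <- t(apply(data, 1L, rank))
  R <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  num <- sum((R - n * (k + 1) / 2)^2)
  chi2 <- if (A1 - C1 < 1e-12) 0 else (k - 1) * num / (A1 - C1)
  list(n = n, k = k, r = r, R = R, A1 = A1, C1 = C1, chi2 = chi2)
}

#' Friedman rank test for repeated measures, with Kendall's W
#'
#' Nonparametric one-way repeated-measures test across `k` conditions
#' measured on `n` subjects (rows). Ranks are computed within rows with
#' average ranks for ties; the chi-square statistic carries the standard
#' tie correction. Kendall's coefficient of concordance is reported as the
#' effect size, `W = chi2 / (n (k - 1))`.
#'
#' @param data Numeric `n x k` matrix (or data frame), no missing cells.
#' @return A `friedman_result`: `chi2`, `df`, `p_value`, `kendall_w`, `n`,
#'   `k`.
#' @export
friedman_np <- function(data) {
  fp <- friedman_parts(data)
  structure(
    list(chi2 = fp$chi2, df = fp$k - 1L,
         p_value = pchisq(fp$chi2, fp$k - 1L, lower.tail = FALSE),
         kendall_w = kendall_w(fp$chi2, fp$n, fp$k),
         n = fp$n, k = fp$k),
    class = "friedman_result"
  )
}

#' Kendall's W from a Friedman chi-square statistic
#'
#' `W = chi2 / (n * (k - 1))`, the coefficient of concordance in `[0, 1]`.
#'
#' @param chi2 Friedman chi-square statistic.
#' @param n Number of subjects (rows).
#' @param k Number of conditions (columns).
#' @return Kendall's W.
#' @examples
#' kendall_w(14.47, n = 30, k = 3) # 0.2412
#' @export
kendall_w <- function(chi2, n, k) {
  if (n < 2 || k < 2) stop_domain("need n >= 2 and k >= 2")
  chi2 / (n * (k - 1))
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test: chi2(%d) = %.4g, p = %.4g, Kendall's W = %.3f\n",
              x$df, x$chi2, x$p_value, x$kendall_w))
  invisible(x)
}

#' Conover post hoc comparisons after a Friedman test
#'
#' All-pairs rank comparisons using Conover's procedure: the difference of
#' column rank sums divided by the pooled standard error
#' `sqrt(2 n (A1 - C1) (1 - T1 / (n (k-1))) / ((n-1)(k-1)))`, referred to a
#' t distribution with `(n-1)(k-1)` degrees of freedom, with Bonferroni
#' multiplication over the `k(k-1)/2` pairs. (Several variants of the
#' Conover statistic circulate; this is the textbook 1999 formulation with
#' the concordance shrinkage term.) With perfect concordance the standard
#' error vanishes and the statistics are infinite by convention.
#'
#' @param data Numeric `n x k` matrix (or data frame), no missing cells.
#' @return A `posthoc_result`: data frame `comparisons` with columns
#'   `i`, `j` (column names), `statistic`, `df`, `p_value`,
#'   `p_adjusted`.
#' @export
conover_posthoc <- function(data) {
  fp <- friedman_parts(data)
  n <- fp$n
  k <- fp$k
  df <- (n - 1) * (k - 1)
  shrink <- 1 - fp$chi2 / (n * (k - 1))
  se2 <- 2 * n * (fp$A1 - fp$C1) * shrink / df
  labels <- colnames(as.matrix(data))
  if (is.null(labels)) labels <- paste0("col", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  stat <- numeric(n_pairs)
  for (m in seq_len(n_pairs)) {
    dR <- fp$R[pairs[1, m]] - fp$R[pairs[2, m]]
    stat[m] <- if (se2 <= 0) {
      if (dR == 0) 0 else sign(dR) * Inf
    } else {
      dR / sqrt(se2)
    }
  }
  p <- 2 * pt(-abs(stat), df)
  structure(
    list(comparisons = data.frame(
      i = labels[pairs[1, ]], j = labels[pairs[2, ]],
      statistic = stat, df = df, p_value = p,
      p_adjusted = pmin(1, p * n_pairs)
    )),
    class = "posthoc_result"
  )
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat("Conover post hoc comparisons (Bonferroni-adjusted):\n")
  print(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Applies the Shapiro-Wilk test to each sample; the analysis routes to the
#' nonparametric branch when any sample deviates from normality at
#' `alpha`.
#'
#' @param samples Named list of numeric vectors (each `n >= 3`, not
#'   constant).
#' @param alpha Gate level (default 0.05).
#' @return List with `nonparametric` (logical: take the nonparametric
#'   branch) and `p_values` (named vector).
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!is.list(samples) || length(samples) == 0L) {
    stop_domain("samples must be a non-empty list of numeric vectors")
  }
  p <- vapply(samples, function(s) {
    s <- s[is.finite(s)]
    if (length(s) < 3L) stop_domain("each sample needs at least 3 values")
    if (sd(s) == 0) stop_domain("constant sample: normality test undefined")
    shapiro.test(s)$p.value
  }, numeric(1))
  list(nonparametric = any(p < alpha), p_values = p)
}
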