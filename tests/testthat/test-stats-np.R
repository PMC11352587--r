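test_that("threshold relative change applies the bandwidth-normalized formula", {
  expect_equal(threshold_relative_change(0.14, 0.29, 1.0), 15.0,
               tolerance = 1e-12)
  expect_equal(threshold_relative_change(0.2, 0.2, 0.7), 0)
  expect_equal(threshold_relative_change(0.045, 0.063, 0.2), 9.0,
               tolerance = 1e-9)
  expect_equal(threshold_relative_change(0.3, 0.1, 0.5), -40) # sign convention
  expect_error(threshold_relative_change(0.1, 0.2, 0), "positive")
})

test_that("smallest one-sided Wilcoxon case matches hand enumeration", {
  x <- c(2, 4, 6)
  y <- c(1, 2, 3) # differences 1, 2, 3: most extreme of the 8 sign patterns
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$p_value, 0.25)
  expect_equal(res$statistic, 0)
  expect_equal(res$w_pos, 6)
  expect_equal(res$n_effective, 3)
  expect_error(wilcoxon_signed_rank(y, y), "degenerate")
})

test_that("exact Wilcoxon p equals full 2^n enumeration, with and without ties", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:12, 1)
    x <- round(rnorm(n, 0.2), if (seed %% 2) 1 else 3) # coarse rounding -> ties
    y <- round(rnorm(n), if (seed %% 2) 1 else 3)
    if (all(x == y)) next
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p_value, wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon agrees with wilcox.test when ties are absent", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    n <- sample(6:15, 1)
    x <- rnorm(n, 0.3)
    y <- rnorm(n)
    res <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation stays close to the exact p at n = 20", {
  for (seed in 1:10) {
    set.seed(200 + seed)
    x <- rnorm(20, 0.3)
    y <- rnorm(20)
    p_exact <- wilcoxon_signed_rank(x, y, exact_max = 25)$p_value
    p_approx <- wilcoxon_signed_rank(x, y, exact_max = 0)$p_value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("balanced positive and negative differences sit at the null expectation", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3) # differences -1, 1, -1, 1
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$w_pos, res$w_neg)
  expect_equal(res$p_value, 1)
})

test_that("rank-biserial matches the signed-rank-sum formula and its extremes", {
  x <- c(2, 3, 4, 5, 6)
  y <- c(1, 2, 3, 4, 5)
  expect_equal(rank_biserial(x, y, n_boot = 0)$rrb, 1)
  expect_equal(rank_biserial(y, x, n_boot = 0)$rrb, -1)
  # constructed signed ranks: positives take ranks {3, 4, 6} of 1..30
  d <- 1:30
  signs <- rep(-1, 30)
  signs[c(3, 4, 6)] <- 1
  x2 <- signs * d
  res <- rank_biserial(x2, rep(0, 30), n_boot = 0)
  expect_equal(res$rrb, (13 - 452) / 465, tolerance = 1e-12) # -0.944
  # symmetric differences cancel
  expect_equal(rank_biserial(c(1, 2, 3, 4), c(2, 1, 4, 3), n_boot = 0)$rrb, 0)
})

test_that("rank-biserial direction always agrees with the Wilcoxon rank sums", {
  for (seed in 1:20) {
    set.seed(300 + seed)
    x <- rnorm(12, 0.2)
    y <- rnorm(12)
    res <- wilcoxon_signed_rank(x, y)
    rrb <- rank_biserial(x, y, n_boot = 0)$rrb
    expect_equal(rrb < 0, res$w_neg > res$w_pos)
  }
})

test_that("bootstrap CI is seeded, ordered, and collapses for uniform effects", {
  x <- rnorm(20, 1)
  y <- rnorm(20)
  r1 <- rank_biserial(x, y, n_boot = 500, seed = 11)
  r2 <- rank_biserial(x, y, n_boot = 500, seed = 11)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[1], r1$ci[2])
  all_pos <- rank_biserial(21:40, 1:20, n_boot = 200, seed = 3)
  expect_equal(all_pos$ci, c(1, 1))
})

test_that("Friedman statistic hits the concordance extremes", {
  perfect <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3, byrow = TRUE)
  res <- friedman_np(perfect)
  expect_equal(res$chi2, 6)
  expect_equal(res$kendall_w, 1)
  flat <- matrix(5, 4, 3)
  res0 <- friedman_np(flat)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$kendall_w, 0)
  expect_error(friedman_np(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("Friedman chi-square matches stats::friedman.test including ties", {
  for (seed in 1:10) {
    set.seed(400 + seed)
    m <- matrix(sample(1:4, 30, replace = TRUE), 10, 3) # heavy ties
    res <- friedman_np(m)
    ref <- friedman.test(m)
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$kendall_w, res$chi2 / (10 * 2), tolerance = 1e-12)
  }
})

test_that("Friedman is invariant under row-wise monotone transforms", {
  set.seed(5)
  m <- matrix(rnorm(24), 8, 3)
  res <- friedman_np(m)
  warped <- t(apply(m, 1, function(row) exp(3 * row) - min(row)))
  expect_equal(friedman_np(warped)$chi2, res$chi2, tolerance = 1e-12)
})

test_that("Kendall's W conversion reproduces the printed effect size", {
  expect_equal(kendall_w(14.47, n = 30, k = 3), 14.47 / 60, tolerance = 1e-12)
  expect_equal(round(kendall_w(14.47, 30, 3), 2), 0.24)
})

test_that("Conover post hocs match a step-by-step hand computation", {
  set.seed(17)
  base <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  m <- base + matrix(rnorm(30, sd = 0.8), 10, 3)
  res <- conover_posthoc(m)
  cmp <- res$comparisons
  expect_equal(nrow(cmp), 3)
  # independent recomputation of the textbook formula
  r <- t(apply(m, 1, rank))
  R <- colSums(r)
  n <- 10; k <- 3
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  T1 <- (k - 1) * sum((R - n * (k + 1) / 2)^2) / (A1 - C1)
  se <- sqrt(2 * n * (A1 - C1) * (1 - T1 / (n * (k - 1))) /
               ((n - 1) * (k - 1)))
  t12 <- (R[1] - R[2]) / se
  t13 <- (R[1] - R[3]) / se
  t23 <- (R[2] - R[3]) / se
  expect_equal(cmp$statistic, unname(c(t12, t13, t23)), tolerance = 1e-12)
  expect_equal(cmp$df, rep((n - 1) * (k - 1), 3))
  expect_equal(cmp$p_adjusted,
               pmin(1, 3 * 2 * pt(-abs(cmp$statistic), (n - 1) * (k - 1))),
               tolerance = 1e-12)
  # the extreme pair carries the largest statistic
  expect_equal(which.max(abs(cmp$statistic)), 2L)
})

test_that("Conover handles the degenerate concordance extremes", {
  flat <- matrix(2, 6, 3)
  res <- conover_posthoc(flat)
  expect_true(all(res$comparisons$p_adjusted == 1))
  expect_true(all(res$comparisons$statistic == 0))
  perfect <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  resp <- conover_posthoc(perfect)
  expect_true(all(is.infinite(resp$comparisons$statistic)))
  expect_true(all(resp$comparisons$p_adjusted == 0))
})

test_that("normality gate separates Gaussian from log-normal samples", {
  pass <- 0
  fail <- 0
  for (seed in 1:60) {
    set.seed(seed)
    g <- rnorm(30)
    if (!normality_gate(list(a = g))$nonparametric) pass <- pass + 1
    if (normality_gate(list(a = exp(rnorm(30, sd = 1.5))))$nonparametric) {
      fail <- fail + 1
    }
  }
  expect_gt(pass, 40) # clear majority keeps the parametric branch
  expect_gt(fail, 40) # clear majority routes nonparametric
  expect_error(normality_gate(list(a = rep(1, 10))), "constant")
  expect_error(normality_gate(list(a = c(1, 2))), "at least 3")
})
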