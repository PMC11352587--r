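test_that("noiseless proportions on the curve are recovered to optimizer precision", {
  true <- list(mu = 0.1, sigma = 0.05, lapse = 0, guess = 0.5)
  agg <- data.frame(contrast = c(0.02, 0.05, 0.08, 0.1, 0.12, 0.15, 0.2),
                    n = 1000)
  agg$k <- agg$n * psychometric_p(agg$contrast, true)
  fit <- fit_cumulative_gaussian(agg)
  expect_true(fit$converged)
  expect_equal(fit$mu_hat, 0.1, tolerance = 1e-6)
  expect_equal(fit$sigma_hat, 0.05, tolerance = 1e-6)
})

test_that("parameters are recovered from massive simulated data", {
  params <- observer_params(mu = 0.1, sigma = 0.05, lapse = 0)
  tr <- simulate_trials(params, c(0.02, 0.05, 0.08, 0.1, 0.12, 0.15, 0.2),
                        10000, seed = 31)
  fit <- fit_cumulative_gaussian(tr)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_hat - 0.1) / 0.1, 0.05)
})

test_that("degenerate data are flagged instead of silently estimated", {
  all_correct <- data.frame(contrast = rep(c(0.1, 0.2, 0.4), each = 50),
                            correct = 1L)
  fit <- fit_cumulative_gaussian(all_correct)
  expect_false(fit$converged)
  expect_match(fit$boundary, "all responses correct")
  expect_error(threshold_at(fit), "non-converged")

  at_chance <- simulate_trials(observer_params(mu = 100, sigma = 1),
                               c(0.05, 0.1, 0.2), 200, seed = 8)
  fit2 <- fit_cumulative_gaussian(at_chance)
  expect_false(fit2$converged)
  expect_true(length(fit2$boundary) > 0)

  expect_error(fit_cumulative_gaussian(
    data.frame(contrast = 0.1, correct = c(0, 1))), "2 distinct")
})

test_that("threshold inversion matches the closed-form identities", {
  true <- list(mu = 0.1, sigma = 0.05, lapse = 0, guess = 0.5)
  agg <- data.frame(contrast = seq(0.02, 0.3, length.out = 8), n = 500)
  agg$k <- agg$n * psychometric_p(agg$contrast, true)
  fit <- fit_cumulative_gaussian(agg)
  est <- threshold_at(fit, 0.75)
  expect_equal(est$threshold, fit$mu_hat, tolerance = 1e-8) # lapse 0
  # with a lapse the criterion point shifts by sigma * qnorm(0.625)
  true_l <- list(mu = 0.1, sigma = 0.05, lapse = 0.1, guess = 0.5)
  agg$k <- agg$n * psychometric_p(agg$contrast, true_l)
  fit_l <- fit_cumulative_gaussian(agg, lapse_mode = "free", lapse_max = 0.15)
  est_l <- threshold_at(fit_l, 0.75)
  expect_equal(est_l$threshold,
               fit_l$mu_hat + fit_l$sigma_hat * qnorm(0.625),
               tolerance = 1e-8)
  expect_error(threshold_at(fit_l, 0.95), "unattainable")
})

test_that("thresholds outside the tested ladder are flagged extrapolated", {
  true <- list(mu = 0.5, sigma = 0.3, lapse = 0, guess = 0.5)
  agg <- data.frame(contrast = seq(0.05, 0.4, length.out = 8), n = 2000)
  agg$k <- agg$n * psychometric_p(agg$contrast, true)
  fit <- fit_cumulative_gaussian(agg)
  est <- threshold_at(fit, 0.75)
  expect_true(est$extrapolated)
})

test_that("pooling counts trials exactly and adds across subjects", {
  tr <- data.frame(contrast = rep(0.1, 100), correct = rep(c(1, 0), c(75, 25)))
  pooled <- pool_proportions(tr)
  expect_equal(pooled$prop, 0.75)
  expect_equal(pooled$n, 100)
  two <- rbind(cbind(tr, subject = 1), cbind(tr, subject = 2))
  pooled2 <- pool_proportions(two)
  expect_equal(pooled2$n, 200)
  expect_equal(pooled2$k, 150)
  by_subj <- pool_proportions(two, by = "subject")
  expect_equal(by_subj$n, c(100, 100))
})

test_that("pooled cohort curves rise monotonically up to binomial noise", {
  spec <- cohort_spec(n_subjects = 8, trials_per_level = 100, seed = 14)
  tab <- simulate_cohort(spec)
  for (nm in unique(tab$task)) {
    pooled <- pool_proportions(tab[tab$task == nm & tab$condition == "baseline", ])
    sds <- sqrt(pooled$prop * (1 - pooled$prop) / pooled$n)
    expect_true(all(diff(pooled$prop) >= -3 * (sds[-1] + sds[-length(sds)])))
  }
})

test_that("fit_thresholds covers every subject-task-condition cell", {
  spec <- cohort_spec(n_subjects = 4, trials_per_level = 50, seed = 2)
  tab <- simulate_cohort(spec)
  thr <- fit_thresholds(tab)
  expect_equal(nrow(thr), 4 * 3 * 2)
  expect_true(all(thr$lapse_mode[thr$task == "image"] == "free"))
  expect_true(all(thr$lapse_mode[thr$task != "image"] == "fixed"))
  expect_true(mean(thr$converged) > 0.9)
})
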