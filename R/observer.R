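# Synthetic observer cohort.
#
# Each simulated observer answers 2AFC trials as Bernoulli draws from a
# cumulative-Gaussian psychometric function with guess rate 0.5. Flicker
# adaptation acts as a multiplicative shift of the psychometric location,
# with the spread scaling proportionally (Weber-like), so the function's
# shape is invariant on log contrast.

#' Psychometric parameters of one observer in one condition
#'
#' @param mu Location of the cumulative Gaussian (contrast units). With
#'   `lapse = 0` this is exactly the 75%-correct threshold.
#' @param sigma Spread (contrast units), positive.
#' @param lapse Stimulus-independent error rate in `[0, 0.1]`; lowers the
#'   upper asymptote to `1 - lapse`.
#' @param guess Guess rate; fixed at 0.5 for 2AFC.
#' @return An `observer_params`.
#' @export
observer_params <- function(mu, sigma, lapse = 0, guess = 0.5) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop_domain("mu must be a finite number")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop_domain("sigma must be positive")
  }
  if (lapse < 0 || lapse > 0.1) stop_domain("lapse must be in [0, 0.1]")
  if (1 - lapse < guess) stop_domain("asymptote must be at least the guess rate")
  structure(list(mu = mu, sigma = sigma, lapse = lapse, guess = guess),
            class = "observer_params")
}

#' Probability of a correct 2AFC response at a given contrast
#'
#' `p(c) = guess + (1 - guess - lapse) * Phi((c - mu) / sigma)`, bounded in
#' `[guess, 1 - lapse]`. With `lapse = 0` the 75% point is exactly `mu`.
#'
#' @param c Contrast value(s), non-negative.
#' @param params An [observer_params()] (or any list with fields `mu`,
#'   `sigma`, `lapse`, `guess`).
#' @return Probability of a correct response (vectorized over `c`).
#' @export
psychometric_p <- function(c, params) {
  if (any(c < 0)) stop_domain("contrast must be non-negative")
  g <- if (is.null(params$guess)) 0.5 else params$guess
  lapse <- if (is.null(params$lapse)) 0 else params$lapse
  g + (1 - g - lapse) * pnorm((c - params$mu) / params$sigma)
}

#' Simulate 2AFC trials for one observer and condition
#'
#' For each contrast level of the ladder, draws `n_per_level` independent
#' Bernoulli responses with success probability [psychometric_p()].
#'
#' @param params An [observer_params()].
#' @param ladder Contrast levels, strictly increasing, in `(0, 1]`.
#' @param n_per_level Trials per contrast level.
#' @param seed Integer seed; same seed reproduces the same trial table.
#' @param subject,task,condition Labels copied into the output.
#' @return Data frame with columns `subject`, `task`, `condition`,
#'   `contrast`, `correct` (0/1), `trial`.
#' @export
simulate_trials <- function(params, ladder, n_per_level, seed = 1L,
                            subject = 1L, task = "task",
                            condition = "baseline") {
  if (!is_count(n_per_level)) stop_domain("n_per_level must be a positive integer")
  check_ladder(ladder)
  p <- psychometric_p(ladder, params)
  correct <- with_seed(seed, {
    unlist(lapply(p, function(pi) rbinom(n_per_level, 1L, pi)))
  })
  data.frame(
    subject = subject,
    task = task,
    condition = condition,
    contrast = rep(ladder, each = n_per_level),
    correct = correct,
    trial = seq_along(correct)
  )
}

check_ladder <- function(ladder) {
  if (!is.numeric(ladder) || length(ladder) < 2L || any(ladder <= 0) ||
      any(ladder > 1) || any(diff(ladder) <= 0)) {
    stop_domain("ladder must be strictly increasing contrasts in (0, 1]")
  }
  invisible(ladder)
}

#' Per-task design of the simulated cohort
#'
#' Defines one task's contrast ladder and the generative observer
#' parameters: the cohort-median 75% threshold, the multiplicative effect
#' of flicker adaptation on it, and the lapse rate. Internally the
#' psychometric location is derived from the threshold via
#' `mu = T / (1 + sigma_rel * qnorm((0.75 - guess) / (1 - guess - lapse)))`
#' (with `sigma = sigma_rel * mu`), so that the generator is parameterized
#' directly by the quantity the analysis estimates.
#'
#' @param name Task label.
#' @param ladder Contrast ladder.
#' @param threshold_median Cohort median 75%-correct baseline threshold.
#' @param flicker_factor Multiplicative effect of flicker on the threshold
#'   (1 = no effect).
#' @param lapse Lapse rate in `[0, 0.1]`.
#' @param sigma_rel Spread relative to location, `sigma = sigma_rel * mu`.
#' @return A `task_spec`.
#' @export
task_spec <- function(name, ladder, threshold_median, flicker_factor = 1,
                      lapse = 0, sigma_rel = 0.5) {
  check_ladder(ladder)
  if (flicker_factor <= 0) stop_domain("flicker_factor must be positive")
  if (threshold_median <= 0) stop_domain("threshold_median must be positive")
  structure(
    list(name = name, ladder = ladder, threshold_median = threshold_median,
         flicker_factor = flicker_factor, lapse = lapse,
         sigma_rel = sigma_rel),
    class = "task_spec"
  )
}

# Psychometric location implied by a 75% threshold under sigma = sr * mu.
location_from_threshold <- function(threshold, sigma_rel, lapse,
                                    guess = 0.5, criterion = 0.75) {
  z <- qnorm((criterion - guess) / (1 - guess - lapse))
  threshold / (1 + sigma_rel * z)
}

#' Default task designs of the three-task experiment
#'
#' Image discrimination (10 contrasts, 0.02-1), motion direction
#' discrimination (12 contrasts, 0.01-0.2) and orientation discrimination
#' (10 contrasts, 0.01-0.1). Cohort-median baseline thresholds and flicker
#' factors are set to the group means reported for human observers in this
#' paradigm (image 0.14 elevated by x2.07, motion 0.045 elevated by x1.4,
#' orientation 0.037 unaffected); the image task has a 0.1 lapse rate,
#' capping its asymptote near 90%.
#'
#' @return Named list of three [task_spec()] objects.
#' @export
default_tasks <- function() {
  list(
    image = task_spec(
      name = "image",
      ladder = c(0.02, 0.05, 0.07, 0.1, 0.15, 0.2, 0.3, 0.5, 0.7, 1),
      threshold_median = 0.14,
      flicker_factor = 0.29 / 0.14,
      lapse = 0.1
    ),
    motion = task_spec(
      name = "motion",
      ladder = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09,
                 0.1, 0.15, 0.2),
      threshold_median = 0.045,
      flicker_factor = 0.063 / 0.045,
      lapse = 0
    ),
    orientation = task_spec(
      name = "orientation",
      ladder = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09, 0.1),
      threshold_median = 0.037,
      flicker_factor = 1,
      lapse = 0
    )
  )
}

#' Cohort specification for the synthetic experiment
#'
#' @param n_subjects Number of simulated observers (default 30).
#' @param tasks Named list of [task_spec()]s (default [default_tasks()]).
#' @param trials_per_level Trials per contrast level and condition
#'   (default 100).
#' @param geo_sd Between-subject geometric SD of the threshold (log-normal
#'   multiplicative spread; default 1.4).
#' @param seed Master seed; every subject/task/condition gets a derived
#'   substream.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30L, tasks = default_tasks(),
                        trials_per_level = 100L, geo_sd = 1.4, seed = 1L) {
  if (!is_count(n_subjects)) stop_domain("n_subjects must be a positive integer")
  if (!is_count(trials_per_level)) stop_domain("trials_per_level must be a positive integer")
  if (geo_sd < 1) stop_domain("geo_sd must be >= 1")
  stopifnot(length(tasks) >= 1L, all(vapply(tasks, inherits, TRUE, "task_spec")))
  structure(
    list(n_subjects = as.integer(n_subjects), tasks = tasks,
         trials_per_level = as.integer(trials_per_level),
         geo_sd = geo_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate the full trial table of a cohort
#'
#' Per subject and task, a baseline threshold is drawn log-normally around
#' the task median (geometric SD `geo_sd`); the flicker condition
#' multiplies it by the task's flicker factor. All conditions and levels
#' are then simulated with [simulate_trials()] using per-(subject, task,
#' condition) seeds derived from the master seed, so generation is
#' reproducible and order-independent.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of trials (one row per trial; see
#'   [simulate_trials()] for columns).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", spec$n_subjects * length(spec$tasks) * 2L)
  i <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (ti in seq_along(spec$tasks)) {
      tk <- spec$tasks[[ti]]
      thr_b <- with_seed(derive_seed(spec$seed, s, ti, 0L), {
        tk$threshold_median * exp(rnorm(1, 0, log(spec$geo_sd)))
      })
      for (cond in c("baseline", "flicker")) {
        thr <- if (cond == "baseline") thr_b else thr_b * tk$flicker_factor
        mu <- location_from_threshold(thr, tk$sigma_rel, tk$lapse)
        params <- observer_params(mu, tk$sigma_rel * mu, tk$lapse)
        i <- i + 1L
        out[[i]] <- simulate_trials(
          params, tk$ladder, spec$trials_per_level,
          seed = derive_seed(spec$seed, s, ti, match(cond, c("baseline", "flicker"))),
          subject = s, task = tk$name, condition = cond
        )
      }
    }
  }
  do.call(rbind, out)
}
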