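# Psychometric fitting: Bernoulli maximum likelihood for the
# cumulative-Gaussian 2AFC model
#   p(c) = guess + (1 - guess - lapse) * Phi((c - mu) / sigma),
# with the guess rate fixed at 0.5 and the lapse either fixed or free with
# a ceiling. Thresholds are the contrast at which the fitted curve reaches
# a criterion proportion correct (default 0.75).

#' Pool trials into per-level counts and proportions
#'
#' @param trials Data frame with columns `contrast` and `correct`, plus any
#'   grouping columns named in `by`.
#' @param by Optional character vector of grouping columns (e.g.
#'   `c("task", "condition")`); proportions are computed per group and
#'   level.
#' @return Data frame with columns `by...`, `contrast`, `n`, `k`, `prop`.
#' @export
pool_proportions <- function(trials, by = character(0)) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    stop_domain("trials must be a non-empty data frame")
  }
  stopifnot(all(c("contrast", "correct") %in% names(trials)),
            all(by %in% names(trials)))
  keys <- trials[, c(by, "contrast"), drop = FALSE]
  agg_n <- aggregate(trials$correct, by = as.list(keys), FUN = length)
  agg_k <- aggregate(trials$correct, by = as.list(keys), FUN = sum)
  out <- agg_n
  names(out)[ncol(out)] <- "n"
  out$k <- agg_k$x
  out$prop <- out$k / out$n
  ord <- do.call(order, out[, c(by, "contrast"), drop = FALSE])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Normalize fitting input to per-level (contrast, n, k) counts.
as_level_counts <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    stop_domain("trials must be a non-empty data frame")
  }
  if (all(c("contrast", "n", "k") %in% names(trials))) {
    agg <- trials[order(trials$contrast), c("contrast", "n", "k")]
  } else if (all(c("contrast", "correct") %in% names(trials))) {
    agg <- pool_proportions(trials)[, c("contrast", "n", "k")]
  } else {
    stop_domain("trials must have columns (contrast, correct) or (contrast, n, k)")
  }
  if (nrow(agg) < 2L) {
    stop_domain("need at least 2 distinct contrast levels to fit")
  }
  agg
}

#' Fit the cumulative-Gaussian psychometric function by maximum likelihood
#'
#' Maximizes the Bernoulli (binomial per level) likelihood of the 2AFC
#' model with the guess rate fixed at 0.5, using box-constrained
#' quasi-Newton optimization from multiple starting points. The lapse rate
#' is either held fixed (`lapse_mode = "fixed"`, value `lapse`) or
#' estimated freely up to `lapse_max` (`lapse_mode = "free"`).
#'
#' Degenerate data — all responses correct, or a best fit pinned to the
#' location/spread box boundary (e.g. performance never rising above
#' chance) — are reported with `converged = FALSE` rather than as a silent
#' estimate.
#'
#' @param trials Data frame of raw trials (`contrast`, `correct`) or
#'   per-level counts (`contrast`, `n`, `k`). At least 2 distinct levels.
#' @param lapse_mode `"fixed"` or `"free"`.
#' @param lapse Fixed lapse value (used when `lapse_mode = "fixed"`).
#' @param lapse_max Upper bound on a free lapse (default 0.15).
#' @param guess Guess rate (fixed, default 0.5).
#' @return A `psych_fit`: `mu_hat`, `sigma_hat`, `lapse_hat`, `guess`,
#'   `log_likelihood`, `converged`, `n_trials`, `contrast_range`,
#'   `lapse_mode`, and `boundary` diagnostics.
#' @export
fit_cumulative_gaussian <- function(trials, lapse_mode = c("fixed", "free"),
                                    lapse = 0, lapse_max = 0.15,
                                    guess = 0.5) {
  lapse_mode <- match.arg(lapse_mode)
  agg <- as_level_counts(trials)
  cc <- agg$contrast
  n <- agg$n
  k <- agg$k
  free_lapse <- lapse_mode == "free"
  base <- list(mu_hat = NA_real_, sigma_hat = NA_real_,
               lapse_hat = if (free_lapse) NA_real_ else lapse,
               guess = guess, log_likelihood = NA_real_, converged = FALSE,
               n_trials = sum(n), contrast_range = range(cc),
               lapse_mode = lapse_mode, boundary = character(0))
  if (all(k >= n)) {
    base$boundary <- "all responses correct"
    return(structure(base, class = "psych_fit"))
  }
  rng <- diff(range(cc))
  mu_lo <- min(cc) - 3 * rng
  mu_hi <- max(cc) + 3 * rng
  ls_lo <- log(rng / 1e4)
  ls_hi <- log(10 * rng)
  lower <- c(mu_lo, ls_lo, if (free_lapse) 0)
  upper <- c(mu_hi, ls_hi, if (free_lapse) lapse_max)
  nll <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    lp <- if (free_lapse) par[3] else lapse
    p <- guess + (1 - guess - lp) * pnorm((cc - mu) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log1p(-p))
  }
  nll_grad <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    lp <- if (free_lapse) par[3] else lapse
    amp <- 1 - guess - lp
    z <- (cc - mu) / sigma
    p <- guess + amp * pnorm(z)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    dldp <- -(k / p - (n - k) / (1 - p))
    phi <- dnorm(z)
    g_mu <- sum(dldp * amp * phi * (-1 / sigma))
    g_ls <- sum(dldp * amp * phi * (-z)) # d z / d log(sigma) = -z
    if (free_lapse) {
      c(g_mu, g_ls, sum(dldp * (-pnorm(z))))
    } else {
      c(g_mu, g_ls)
    }
  }
  # start location where observed performance crosses midway to the
  # asymptote, plus a central alternative
  prop <- k / n
  mid <- (guess + 1 - lapse) / 2
  cross <- cc[which(prop >= mid)[1]]
  mu_starts <- unique(c(if (!is.na(cross)) cross, median(cc)))
  sig_starts <- c(rng / 4, rng / 20)
  best <- NULL
  best_ok <- NULL
  for (m0 in mu_starts) {
    for (s0 in sig_starts) {
      par0 <- c(m0, log(s0), if (free_lapse) min(0.02, lapse_max / 2))
      fit <- tryCatch(
        optim(par0, nll, gr = nll_grad, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(factr = 1e4, maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
      if (fit$convergence == 0 &&
          (is.null(best_ok) || fit$value < best_ok$value)) best_ok <- fit
    }
  }
  if (is.null(best)) {
    base$boundary <- "optimization failed from all starts"
    return(structure(base, class = "psych_fit"))
  }
  # prefer a cleanly converged start when it reaches the same optimum
  if (!is.null(best_ok) && best_ok$value <= best$value + 1e-6) best <- best_ok
  par <- best$par
  tol <- 1e-6
  boundary <- character(0)
  if (par[1] <= mu_lo + tol || par[1] >= mu_hi - tol) {
    boundary <- c(boundary, "location at box boundary")
  }
  if (par[2] <= ls_lo + tol || par[2] >= ls_hi - tol) {
    boundary <- c(boundary, "spread at box boundary")
  }
  base$mu_hat <- par[1]
  base$sigma_hat <- exp(par[2])
  base$lapse_hat <- if (free_lapse) par[3] else lapse
  base$log_likelihood <- -best$value
  base$converged <- best$convergence == 0 && length(boundary) == 0L
  base$boundary <- boundary
  structure(base, class = "psych_fit")
}

#' @export
print.psych_fit <- function(x, ...) {
  cat("Cumulative-Gaussian psychometric fit\n")
  cat(sprintf("  mu = %.5g, sigma = %.5g, lapse = %.4g (%s)\n",
              x$mu_hat, x$sigma_hat, x$lapse_hat, x$lapse_mode))
  cat(sprintf("  logLik = %.3f over %d trials; converged: %s\n",
              x$log_likelihood, x$n_trials, x$converged))
  if (length(x$boundary)) cat("  diagnostics:", paste(x$boundary, collapse = "; "), "\n")
  invisible(x)
}

#' Contrast threshold at a criterion level of performance
#'
#' Inverts the fitted psychometric function analytically:
#' `T = mu + sigma * qnorm((criterion - guess) / (1 - guess - lapse))`.
#' With `lapse = 0` and `criterion = 0.75` this is exactly `mu`. Thresholds
#' outside the fitted contrast range are flagged `extrapolated` rather than
#' dropped.
#'
#' @param fit A converged `psych_fit`.
#' @param criterion Target proportion correct, strictly between the guess
#'   rate and the fitted asymptote (default 0.75).
#' @return A `threshold_estimate`: `threshold`, `criterion`,
#'   `extrapolated`.
#' @export
threshold_at <- function(fit, criterion = 0.75) {
  stopifnot(inherits(fit, "psych_fit"))
  if (!isTRUE(fit$converged)) {
    stop_domain("cannot extract a threshold from a non-converged fit")
  }
  asym <- 1 - fit$lapse_hat
  if (criterion <= fit$guess || criterion >= asym - 1e-9) {
    stop_domain(sprintf(
      "criterion %.3f is unattainable: fitted curve spans (%.3f, %.3f)",
      criterion, fit$guess, asym))
  }
  z <- qnorm((criterion - fit$guess) / (1 - fit$guess - fit$lapse_hat))
  tt <- fit$mu_hat + fit$sigma_hat * z
  structure(
    list(threshold = tt, criterion = criterion,
         extrapolated = tt < fit$contrast_range[1] || tt > fit$contrast_range[2]),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Contrast threshold at %.0f%% correct: %.5g%s\n",
              100 * x$criterion, x$threshold,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Fit thresholds for every subject, task and condition of a trial table
#'
#' Groups trials by `(subject, task, condition)`, fits each group with
#' [fit_cumulative_gaussian()] and extracts the criterion threshold.
#' By default tasks listed in `free_lapse_tasks` are fitted with a free
#' lapse (their psychometric curve may saturate below 100%) and all others
#' with lapse fixed at 0.
#'
#' @param trials Trial table as produced by [simulate_cohort()].
#' @param criterion Threshold criterion (default 0.75).
#' @param free_lapse_tasks Tasks fitted with a free lapse (default
#'   `"image"`).
#' @param lapse_max Ceiling for free lapses.
#' @return Data frame with one row per subject/task/condition: `threshold`,
#'   `criterion`, `converged`, `extrapolated`, `lapse_mode`, `mu_hat`,
#'   `sigma_hat`, `lapse_hat`. Non-converged fits yield `NA` thresholds.
#' @export
fit_thresholds <- function(trials, criterion = 0.75,
                           free_lapse_tasks = "image", lapse_max = 0.15) {
  stopifnot(all(c("subject", "task", "condition", "contrast", "correct")
                %in% names(trials)))
  groups <- split(trials,
                  list(trials$subject, trials$task, trials$condition),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    mode <- if (g$task[1] %in% free_lapse_tasks) "free" else "fixed"
    fit <- fit_cumulative_gaussian(g, lapse_mode = mode,
                                   lapse_max = lapse_max)
    thr <- NA_real_
    extrap <- NA
    if (fit$converged) {
      est <- threshold_at(fit, criterion)
      thr <- est$threshold
      extrap <- est$extrapolated
    }
    data.frame(subject = g$subject[1], task = g$task[1],
               condition = g$condition[1], threshold = thr,
               criterion = criterion, converged = fit$converged,
               extrapolated = extrap, lapse_mode = mode,
               mu_hat = fit$mu_hat, sigma_hat = fit$sigma_hat,
               lapse_hat = fit$lapse_hat)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$task, out$condition, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}
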