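# End-to-end orchestration: simulate a cohort, fit thresholds, run the
# nonparametric analysis chain, and write/report the results bundle.

#' Experiment configuration
#'
#' Bundles the cohort design with the analysis options. The default
#' configuration mirrors the three-task design: 30 subjects, the printed
#' contrast ladders, 100 trials per level and condition (6400 trials per
#' subject in total), 75% threshold criterion.
#'
#' @param cohort A [cohort_spec()].
#' @param criterion Threshold criterion (default 0.75).
#' @param alpha Significance level for the per-task tests (default 0.05).
#' @param n_boot Bootstrap resamples for the rank-biserial CI.
#' @param seed Master seed (overrides the cohort spec's seed so one number
#'   controls the whole run).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(), criterion = 0.75,
                              alpha = 0.05, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  cohort$seed <- as.integer(seed)
  structure(
    list(cohort = cohort, criterion = criterion, alpha = alpha,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Recognized top-level fields: `seed`, `n_subjects`, `trials_per_level`,
#' `geo_sd`, `criterion`, `alpha`, `n_boot`, and `tasks` — a map from task
#' name to `ladder`, `threshold_median`, `flicker_factor`, `lapse`,
#' `sigma_rel`. Omitted fields fall back to the defaults of
#' [cohort_spec()] / [experiment_config()]; omitted `tasks` means the
#' standard three-task design.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  grab <- function(name, default) if (is.null(y[[name]])) default else y[[name]]
  tasks <- if (is.null(y$tasks)) {
    default_tasks()
  } else {
    out <- lapply(names(y$tasks), function(nm) {
      tk <- y$tasks[[nm]]
      task_spec(
        name = nm,
        ladder = as.numeric(tk$ladder),
        threshold_median = tk$threshold_median,
        flicker_factor = if (is.null(tk$flicker_factor)) 1 else tk$flicker_factor,
        lapse = if (is.null(tk$lapse)) 0 else tk$lapse,
        sigma_rel = if (is.null(tk$sigma_rel)) 0.5 else tk$sigma_rel
      )
    })
    names(out) <- names(y$tasks)
    out
  }
  experiment_config(
    cohort = cohort_spec(
      n_subjects = grab("n_subjects", 30L),
      tasks = tasks,
      trials_per_level = grab("trials_per_level", 100L),
      geo_sd = grab("geo_sd", 1.4)
    ),
    criterion = grab("criterion", 0.75),
    alpha = grab("alpha", 0.05),
    n_boot = grab("n_boot", 10000L),
    seed = grab("seed", 1L)
  )
}

#' Trials per subject implied by a configuration
#'
#' `sum over tasks of levels x trials_per_level x 2 conditions`; 6400 for
#' the default design (2000 image + 2400 motion + 2000 orientation).
#'
#' @param config An [experiment_config()].
#' @return Integer trial count.
#' @export
trials_per_subject <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sum(vapply(config$cohort$tasks, function(tk) length(tk$ladder), 1L)) *
    config$cohort$trials_per_level * 2L
}

#' Analyze a threshold table
#'
#' Runs the statistics chain on a table of per-subject thresholds (as
#' produced by [fit_thresholds()]): Shapiro-Wilk normality gate on each
#' task/condition threshold sample, paired Wilcoxon signed-rank test and
#' rank-biserial effect size for baseline vs flicker within each task,
#' per-subject threshold relative change scores (normalized by each task's
#' maximum tested contrast), and a Friedman test with Kendall's W and
#' Conover post hocs comparing the change scores across tasks.
#'
#' Subjects without a converged threshold in both conditions of a task are
#' excluded from that task's paired test, and from the across-task
#' comparison if any task is incomplete.
#'
#' @param thresholds Data frame from [fit_thresholds()].
#' @param config The [experiment_config()] that produced the data (used
#'   for ladder maxima and analysis options).
#' @return A list of class `stats_bundle`: per-task `tasks` (wilcoxon,
#'   rank-biserial, mean/SD thresholds, mean change score), `normality`,
#'   `friedman`, `posthoc`, `change_matrix`.
#' @export
analyze_thresholds <- function(thresholds, config) {
  stopifnot(inherits(config, "experiment_config"))
  stopifnot(all(c("subject", "task", "condition", "threshold")
                %in% names(thresholds)))
  tasks <- config$cohort$tasks
  task_names <- vapply(tasks, `[[`, "", "name")
  per_task <- list()
  change_cols <- list()
  norm_samples <- list()
  for (tk in tasks) {
    sub <- thresholds[thresholds$task == tk$name, ]
    wide <- merge(
      sub[sub$condition == "baseline", c("subject", "threshold")],
      sub[sub$condition == "flicker", c("subject", "threshold")],
      by = "subject", suffixes = c("_baseline", "_flicker")
    )
    wide <- wide[complete.cases(wide), ]
    wide <- wide[order(wide$subject), ]
    tb <- wide$threshold_baseline
    tf <- wide$threshold_flicker
    change <- threshold_relative_change(tb, tf, max(tk$ladder))
    wilcox <- wilcoxon_signed_rank(tb, tf)
    rrb <- rank_biserial(tb, tf, n_boot = config$n_boot,
                         seed = derive_seed(config$seed, 7919L,
                                            match(tk$name, task_names)))
    per_task[[tk$name]] <- list(
      n = nrow(wide),
      mean_baseline = mean(tb), sd_baseline = sd(tb),
      mean_flicker = mean(tf), sd_flicker = sd(tf),
      wilcoxon = wilcox, rank_biserial = rrb,
      mean_change = mean(change),
      mean_change_from_group_means =
        threshold_relative_change(mean(tb), mean(tf), max(tk$ladder)),
      significant = wilcox$p_value < config$alpha
    )
    change_cols[[tk$name]] <- data.frame(subject = wide$subject,
                                         change = change)
    norm_samples[[paste0(tk$name, "_baseline")]] <- tb
    norm_samples[[paste0(tk$name, "_flicker")]] <- tf
  }
  normality <- normality_gate(norm_samples)
  # across-task comparison on subjects complete in every task
  common <- Reduce(intersect, lapply(change_cols, `[[`, "subject"))
  change_matrix <- vapply(change_cols, function(df) {
    df$change[match(common, df$subject)]
  }, numeric(length(common)))
  if (is.null(dim(change_matrix))) {
    change_matrix <- matrix(change_matrix, nrow = length(common),
                            dimnames = list(NULL, names(change_cols)))
  }
  friedman <- if (length(common) >= 2 && length(tasks) >= 2) {
    friedman_np(change_matrix)
  } else {
    NULL
  }
  posthoc <- if (!is.null(friedman) && length(tasks) > 2) {
    conover_posthoc(change_matrix)
  } else {
    NULL
  }
  structure(
    list(tasks = per_task, normality = normality, friedman = friedman,
         posthoc = posthoc, change_matrix = change_matrix,
         criterion = config$criterion, alpha = config$alpha),
    class = "stats_bundle"
  )
}

#' Run the full simulated experiment
#'
#' Simulates the cohort, fits all per-subject psychometric functions,
#' extracts thresholds, and runs the statistics chain. If `outdir` is
#' given, writes `trials.csv`, `thresholds.csv`, `stats.json` and a
#' `manifest.json` (seed, configuration digest) there; a rerun with the
#' same configuration and seed reproduces identical files.
#'
#' @param config An [experiment_config()].
#' @param outdir Optional output directory (created if missing).
#' @param keep_trials Keep the raw trial table in the returned bundle
#'   (default TRUE; the table has
#'   `n_subjects * trials_per_subject` rows).
#' @return A `results_bundle`: `trials` (optionally), `thresholds`,
#'   `stats`, `config`, `paths`.
#' @export
run_experiment <- function(config = experiment_config(), outdir = NULL,
                           keep_trials = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  trials <- simulate_cohort(config$cohort)
  free_tasks <- vapply(config$cohort$tasks, function(tk) {
    if (tk$lapse > 0) tk$name else NA_character_
  }, "")
  free_tasks <- free_tasks[!is.na(free_tasks)]
  thresholds <- fit_thresholds(trials, criterion = config$criterion,
                               free_lapse_tasks = free_tasks)
  stats <- analyze_thresholds(thresholds, config)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      trials = file.path(outdir, "trials.csv"),
      thresholds = file.path(outdir, "thresholds.csv"),
      stats = file.path(outdir, "stats.json"),
      manifest = file.path(outdir, "manifest.json")
    )
    write.csv(trials, paths$trials, row.names = FALSE)
    write.csv(thresholds, paths$thresholds, row.names = FALSE)
    jsonlite::write_json(stats_to_list(stats), paths$stats,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(seed = config$seed,
           n_subjects = config$cohort$n_subjects,
           trials_per_subject = trials_per_subject(config),
           criterion = config$criterion,
           package_version = as.character(utils::packageVersion("fastvision"))),
      paths$manifest, auto_unbox = TRUE, pretty = TRUE
    )
  }
  structure(
    list(trials = if (keep_trials) trials else NULL,
         thresholds = thresholds, stats = stats, config = config,
         paths = paths),
    class = "results_bundle"
  )
}

# Flatten the stats bundle into plain lists for JSON serialization.
stats_to_list <- function(stats) {
  tasks <- lapply(stats$tasks, function(tk) {
    list(
      n = tk$n,
      mean_baseline = tk$mean_baseline, sd_baseline = tk$sd_baseline,
      mean_flicker = tk$mean_flicker, sd_flicker = tk$sd_flicker,
      wilcoxon_W = tk$wilcoxon$statistic,
      wilcoxon_p = tk$wilcoxon$p_value,
      wilcoxon_method = tk$wilcoxon$method,
      rrb = tk$rank_biserial$rrb,
      rrb_ci = tk$rank_biserial$ci,
      mean_change_pct = tk$mean_change,
      significant = tk$significant
    )
  })
  out <- list(tasks = tasks,
              normality = list(nonparametric = stats$normality$nonparametric,
                               p_values = as.list(stats$normality$p_values)))
  if (!is.null(stats$friedman)) {
    out$friedman <- list(chi2 = stats$friedman$chi2, df = stats$friedman$df,
                         p = stats$friedman$p_value,
                         kendall_w = stats$friedman$kendall_w)
  }
  if (!is.null(stats$posthoc)) {
    out$posthoc <- stats$posthoc$comparisons
  }
  out
}

#' Text report of a results bundle
#'
#' Formats group means, test statistics, effect sizes and threshold
#' elevations task by task, followed by the across-task Friedman/Conover
#' summary.
#'
#' @param bundle A `results_bundle` from [run_experiment()], or a
#'   `stats_bundle` from [analyze_thresholds()].
#' @return Character vector of report lines (invisibly); also printed.
#' @export
report <- function(bundle) {
  stats <- if (inherits(bundle, "results_bundle")) bundle$stats else bundle
  if (!inherits(stats, "stats_bundle")) {
    stop_domain("report needs a results_bundle or stats_bundle")
  }
  if (length(stats$tasks) == 0L) stop_domain("bundle contains no task results")
  lines <- c("Flicker-adaptation contrast threshold analysis",
             sprintf("criterion: %.0f%% correct; alpha = %.2f",
                     100 * stats$criterion, stats$alpha), "")
  for (nm in names(stats$tasks)) {
    tk <- stats$tasks[[nm]]
    lines <- c(lines,
      sprintf("Task: %s (n = %d)", nm, tk$n),
      sprintf("  baseline threshold: M = %.3f, SD = %.3f",
              tk$mean_baseline, tk$sd_baseline),
      sprintf("  flicker threshold:  M = %.3f, SD = %.3f",
              tk$mean_flicker, tk$sd_flicker),
      sprintf("  Wilcoxon W = %.4g, p = %.3g (%s); rrb = %.3f, 95%% CI [%.3f, %.3f]",
              tk$wilcoxon$statistic, tk$wilcoxon$p_value,
              tk$wilcoxon$method, tk$rank_biserial$rrb,
              tk$rank_biserial$ci[1], tk$rank_biserial$ci[2]),
      sprintf("  mean threshold elevation: %.2f%% of max contrast (%s)",
              tk$mean_change,
              if (tk$significant) "significant" else "not significant"),
      "")
  }
  if (!is.null(stats$friedman)) {
    fr <- stats$friedman
    lines <- c(lines,
      sprintf("Across tasks: Friedman chi2(%d) = %.4g, p = %.3g, Kendall's W = %.3f",
              fr$df, fr$chi2, fr$p_value, fr$kendall_w))
  }
  if (!is.null(stats$posthoc)) {
    cmp <- stats$posthoc$comparisons
    for (i in seq_len(nrow(cmp))) {
      lines <- c(lines,
        sprintf("  %s vs %s: t(%d) = %.3g, adjusted p = %.3g",
                cmp$i[i], cmp$j[i], cmp$df[i], cmp$statistic[i],
                cmp$p_adjusted[i]))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
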