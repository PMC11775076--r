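#' Configuration for the end-to-end analysis pipeline
#'
#' Collects every knob of [run_ccaf_pipeline()] in one serialisable object:
#' the cohort to simulate (or a trial data frame to analyse instead), the
#' schedule size, bootstrap settings, the chi-squared correction for the
#' preference table, and the root seed from which all stage seeds are
#' derived.
#'
#' @param cohort a [cohort_config()] used when `trials` is `NULL`.
#' @param trials optional trial-level data frame (or path to a trial CSV);
#'   when supplied, simulation is skipped.
#' @param n_per_level trials per relative point level in the simulated
#'   schedule (default 32, i.e. 96 trials).
#' @param n_boot bootstrap resamples for group and subject CIs.
#' @param ci_level confidence level.
#' @param chi2_correction correction for the group x preference table.
#' @param logit_adjust additive count adjustment for [empirical_logit()].
#' @param seed root integer seed.
#' @param out_dir optional directory; when given, every stage output is
#'   written there as CSV/JSON plus a markdown report and a manifest.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(), trials = NULL,
                            n_per_level = 32, n_boot = 1000,
                            ci_level = 0.95,
                            chi2_correction = c("none", "yates"),
                            logit_adjust = 0.5,
                            seed = 1, out_dir = NULL) {
  structure(list(cohort = cohort, trials = trials,
                 n_per_level = n_per_level, n_boot = n_boot,
                 ci_level = ci_level,
                 chi2_correction = match.arg(chi2_correction),
                 logit_adjust = logit_adjust,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  ser <- config[setdiff(names(config), "trials")]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the whole concurrent-choice analysis pipeline
#'
#' Executes, in order: simulate (unless trial data are supplied) ->
#' aggregate -> empirical logit -> group and per-subject psychometric fits
#' -> parametric bootstrap -> preference classification -> group x
#' preference chi-squared test -> split-plot ANOVA -> back-transformed cell
#' means. All randomness derives from the config's root seed, so a config
#' reproduces its results (and its manifest hash) exactly.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"ccaf_report"`: a list with elements
#'   `cohort`, `schedule`, `trials`, `summary`, `group_fits`, `group_boot`,
#'   `classification`, `preference_tab`, `chi2`, `anova`, `cell_means`,
#'   `manifest`. When `config$out_dir` is set the stage outputs are also
#'   written there (`trials.csv`, `summary.csv`, `group_fits.json`,
#'   `classification.csv`, `stats.json`, `report.md`, `manifest.json`).
#' @examples
#' cfg <- pipeline_config(cohort = cohort_config(n_per_group = 4),
#'                        n_per_level = 8, n_boot = 100, seed = 7)
#' rep <- run_ccaf_pipeline(cfg)
#' rep$chi2
#' @export
run_ccaf_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ccaf("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  schedule <- NULL
  if (is.null(config$trials)) {
    schedule <- stage("schedule",
      generate_schedule(config$n_per_level, seed = derive_seed(seed, "sched")))
    cohort <- stage("cohort",
      generate_cohort(config$cohort, seed = derive_seed(seed, "cohort")))
    trials <- stage("simulate",
      simulate_cohort(cohort, schedule, seed = derive_seed(seed, "trials"),
                      p_miss = config$cohort$p_miss))
  } else {
    cohort <- NULL
    trials <- if (is.character(config$trials)) read_trials(config$trials)
              else config$trials
  }

  summ <- stage("aggregate",
    aggregate_choices(trials, adjust = config$logit_adjust))

  group_fits <- stage("fit", fit_group_curves(summ))
  group_boot <- stage("bootstrap", lapply(names(group_fits), function(g)
    parametric_bootstrap(group_fits[[g]], n_boot = config$n_boot,
                         level = config$ci_level,
                         seed = derive_seed(seed, paste0("boot_", g)))))
  names(group_boot) <- names(group_fits)

  classification <- stage("classify",
    classify_subjects(summ, n_boot = config$n_boot,
                      level = config$ci_level,
                      seed = derive_seed(seed, "classify")))
  pref_tab <- preference_table(classification)

  chi2 <- NULL
  used_tab <- pref_tab[, colSums(pref_tab) > 0, drop = FALSE]
  if (ncol(used_tab) >= 2 && all(rowSums(used_tab) > 0))
    chi2 <- stage("chi2",
      chi2_independence(used_tab, correction = config$chi2_correction))

  keep <- summ$n > 0
  anova_tab <- stage("split-plot",
    split_plot_model(summ[keep, , drop = FALSE], between = "group"))
  cells <- stage("backtransform",
    backtransform_means(summ[keep, , drop = FALSE]))

  manifest <- list(
    package = "ccaf",
    version = as.character(utils::packageVersion("ccaf")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    n_subjects = length(unique(summ$subject_id)),
    n_trials = nrow(trials),
    config_hash = config_hash(config))

  report <- structure(list(cohort = cohort, schedule = schedule,
                           trials = trials, summary = summ,
                           group_fits = group_fits, group_boot = group_boot,
                           classification = classification,
                           preference_tab = pref_tab, chi2 = chi2,
                           anova = anova_tab, cell_means = cells,
                           manifest = manifest, config = config),
                      class = "ccaf_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(report$cohort))
    write.csv(as.data.frame(report$cohort), p("cohort.csv"),
              row.names = FALSE)
  write_trials(report$trials, p("trials.csv"))
  write_summary(report$summary, p("summary.csv"))
  write.csv(report$classification, p("classification.csv"),
            row.names = FALSE)

  fits <- lapply(names(report$group_fits), function(g) {
    fit <- report$group_fits[[g]]
    bs <- report$group_boot[[g]]
    list(group = g, scope = fit$scope, predictor = fit$predictor,
         alpha = unname(fit$coefficients["alpha"]),
         beta = unname(fit$coefficients["beta"]),
         alpha_ci = bs$alpha_ci, beta_ci = bs$beta_ci,
         n_boot = bs$n_boot, separation = fit$separation_flag)
  })
  jsonlite::write_json(fits, p("group_fits.json"), auto_unbox = TRUE,
                       digits = NA)
  stats <- list(
    preference_table = report$preference_tab,
    chi2 = if (!is.null(report$chi2))
      list(statistic = report$chi2$statistic, df = report$chi2$df,
           p = report$chi2$p.value, correction = report$chi2$correction),
    anova = as.data.frame(report$anova),
    cell_means = report$cell_means)
  jsonlite::write_json(stats, p("stats.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  jsonlite::write_json(report$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  md <- c("# Concurrent-choice analysis report", "",
          paste0("Seed: ", report$manifest$seed,
                 "; subjects: ", report$manifest$n_subjects,
                 "; trials: ", report$manifest$n_trials), "",
          "## Group psychometric fits", "")
  for (f in fits)
    md <- c(md, sprintf(
      "- %s: PSE %.3f [%.3f, %.3f], slope %.3f [%.3f, %.3f]",
      f$group, f$alpha, f$alpha_ci[1], f$alpha_ci[2],
      f$beta, f$beta_ci[1], f$beta_ci[2]))
  md <- c(md, "", "## Preference classification (group x category)", "",
          utils::capture.output(print(report$preference_tab)))
  if (!is.null(report$chi2))
    md <- c(md, "",
            sprintf("Chi-squared = %.3f, df = %d, p = %.4g (%s)",
                    report$chi2$statistic, report$chi2$df,
                    report$chi2$p.value, report$chi2$correction))
  md <- c(md, "", "## Split-plot ANOVA (empirical logit)", "",
          utils::capture.output(print(report$anova)),
          "", "## Back-transformed cell means (%)", "",
          utils::capture.output(print(report$cell_means, row.names = FALSE)))
  writeLines(md, p("report.md"))
  invisible(report)
}

#' @export
print.ccaf_report <- function(x, ...) {
  cat("Concurrent-choice analysis report (seed ", x$manifest$seed, ", ",
      x$manifest$n_subjects, " subjects, ", x$manifest$n_trials,
      " trials)\n\n", sep = "")
  for (g in names(x$group_fits)) {
    f <- x$group_fits[[g]]; b <- x$group_boot[[g]]
    cat(sprintf("%s: PSE %.3f [%.3f, %.3f]  slope %.3f [%.3f, %.3f]\n",
                g, f$coefficients["alpha"], b$alpha_ci[1], b$alpha_ci[2],
                f$coefficients["beta"], b$beta_ci[1], b$beta_ci[2]))
  }
  cat("\nPreference counts:\n")
  print(x$preference_tab)
  if (!is.null(x$chi2))
    cat(sprintf("chi-squared = %.3f, df = %d, p = %.4g\n",
                x$chi2$statistic, x$chi2$df, x$chi2$p.value))
  cat("\n")
  print(x$anova)
  invisible(x)
}
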