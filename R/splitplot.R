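#' Split-plot ANOVA on empirical-logit choice percentages
#'
#' Fits the mixed-design (split-plot) analysis of the logit-transformed
#' alcohol-choice percentages: subjects are whole plots, the relative point
#' level is the within-subject factor, and the drinking group (or a
#' continuous severity covariate) plus sex are between-subject terms. On a
#' complete balanced design this two-stratum decomposition is numerically
#' identical to a subject-random-intercept mixed model: between-subject
#' effects are tested against the between-subject residual, within-subject
#' effects against the within-subject residual.
#'
#' Two model forms are provided, matching the two standard analyses of this
#' design:
#' \describe{
#'   \item{`between = "group"`}{full factorial `group * sex * level` with
#'     level categorical. With 2 groups x 2 sexes x 15 subjects this yields
#'     the canonical df structure: between error 56, within error 112.}
#'   \item{`between = "audit"`}{additive between terms
#'     `audit + group + sex` with level entered as a linear (numeric)
#'     contrast, giving 1 df level tests against 116 within df.}
#' }
#'
#' @param data a [aggregate_choices()] data frame with finite `elogit`
#'   values and `group`, `sex` (and `audit` for the covariate model)
#'   columns; every subject must have all three level cells (unbalanced
#'   data raise an error naming the incomplete subjects).
#' @param between `"group"` (categorical model) or `"audit"` (severity
#'   covariate model).
#' @param level_coding `"categorical"` or `"linear"`; defaults to
#'   categorical for the group model and linear for the audit model.
#' @param response response column, default `"elogit"`.
#' @param f_cap cap applied to an effectively infinite F ratio (zero error
#'   mean square with a non-zero effect); such rows are flagged.
#' @return A data frame of class `"ccaf_anova"` with one row per effect:
#'   `effect`, `stratum` (`between`/`within`), `ss`, `df1`, `df2`, `F`,
#'   `p`, `partial_eta_sq`, `flag`. The underlying [stats::aov()] object is
#'   attached as attribute `"aov"`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = 6), seed = 1)
#' trials <- simulate_cohort(cohort, generate_schedule(8, seed = 1), seed = 2)
#' split_plot_model(aggregate_choices(trials))
#' @seealso [backtransform_means()]
#' @export
split_plot_model <- function(data, between = c("group", "audit"),
                             level_coding = NULL, response = "elogit",
                             f_cap = 1e6) {
  between <- match.arg(between)
  level_coding <- level_coding %||%
    if (between == "group") "categorical" else "linear"
  level_coding <- match.arg(level_coding, c("categorical", "linear"))
  need <- c("subject_id", "relative_point_level", response, "group", "sex",
            if (between == "audit") "audit")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_ccaf("data lacks column(s): ", paste(miss, collapse = ", "))

  d <- as.data.frame(data)
  levels_all <- sort(unique(d$relative_point_level))
  cells <- table(d$subject_id)
  incomplete <- names(cells)[cells != length(levels_all)]
  bad_logit <- unique(d$subject_id[!is.finite(d[[response]])])
  drop_list <- union(incomplete, bad_logit)
  if (length(drop_list))
    stop_ccaf("design is unbalanced or has non-finite responses; drop ",
              "incomplete subject(s) first: ",
              paste(sort(drop_list), collapse = ", "))

  d$subject <- factor(d$subject_id)
  d$group <- factor(d$group)
  d$sex <- factor(d$sex)
  d$level <- if (level_coding == "categorical")
    factor(d$relative_point_level) else as.numeric(d$relative_point_level)

  fml <- if (between == "group")
    as.formula(paste(response, "~ group * sex * level + Error(subject)"))
  else
    as.formula(paste(response, "~ (audit + group + sex) * level +",
                     "Error(subject)"))
  fit <- aov(fml, data = d)

  strata <- summary(fit)
  ss_grand <- sum((d[[response]] - mean(d[[response]]))^2)
  # an SS below this is numerically zero relative to the data's scale
  # (exact-arithmetic zeros come out of aov as ~1e-30 rounding residue)
  zero_tol <- 1e-10 * max(ss_grand, .Machine$double.xmin)
  rows <- list()
  for (snm in names(strata)) {
    tab <- strata[[snm]][[1]]
    enm <- trimws(rownames(tab))
    is_res <- enm == "Residuals"
    # a saturated stratum (error df 0) leaves its effects untestable
    ss_err <- if (any(is_res)) tab[is_res, "Sum Sq"] else 0
    df_err <- if (any(is_res)) tab[is_res, "Df"] else 0
    ms_err <- if (df_err > 0) ss_err / df_err else NA_real_
    stratum <- if (grepl("Within", snm)) "within" else "between"
    for (i in which(!is_res)) {
      ss <- tab[i, "Sum Sq"]; df1 <- tab[i, "Df"]
      ms <- ss / df1
      flag <- ""
      if (df_err == 0) {
        Fv <- NA_real_; flag <- "no-error-df"
      } else if (ss_err > zero_tol) {
        Fv <- ms / ms_err
      } else if (ss <= zero_tol) {
        Fv <- NA_real_; flag <- "degenerate"
      } else {
        Fv <- f_cap; flag <- "capped"
      }
      pv <- if (is.na(Fv)) NA_real_ else pf(Fv, df1, df_err, lower.tail = FALSE)
      pes <- if (ss + ss_err > 0) ss / (ss + ss_err) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        effect = enm[i], stratum = stratum, ss = ss, df1 = df1,
        df2 = df_err, F = Fv, p = pv, partial_eta_sq = pes, flag = flag,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      effect = paste0("Residuals(", stratum, ")"), stratum = stratum,
      ss = ss_err, df1 = df_err, df2 = NA_real_, F = NA_real_,
      p = NA_real_, partial_eta_sq = NA_real_, flag = "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, aov = fit, between = between,
            level_coding = level_coding, response = response,
            ss_total = sum((d[[response]] - mean(d[[response]]))^2),
            class = c("ccaf_anova", "data.frame"))
}

#' @export
print.ccaf_anova <- function(x, digits = 4, ...) {
  cat("Split-plot ANOVA on", attr(x, "response"),
      "( between:", attr(x, "between"),
      "; level coding:", attr(x, "level_coding"), ")\n")
  d <- as.data.frame(x)
  d$ss <- signif(d$ss, digits)
  d$F <- signif(d$F, digits)
  d$p <- signif(d$p, digits)
  d$partial_eta_sq <- signif(d$partial_eta_sq, digits)
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}

# p-value lookup for one effect of a ccaf_anova table
anova_p <- function(tab, effect) {
  i <- match(effect, tab$effect)
  if (is.na(i)) stop_ccaf("no effect '", effect, "' in the ANOVA table")
  tab$p[i]
}

#' Back-transform cell means to the percentage scale
#'
#' Estimated marginal means of the empirical-logit response for each cell of
#' the requested margins, with t confidence intervals computed from the
#' spread of the per-subject values in the cell, mapped back to the 0-100%
#' choice scale by the inverse logit. For between-subject margins (`group`,
#' `sex`) subjects are first reduced to their mean logit across levels, so
#' each subject contributes one observation; for the `level` margin each
#' subject contributes its cell value.
#'
#' @param data a balanced [aggregate_choices()] data frame with finite
#'   `elogit`.
#' @param margins character vector of margins among
#'   `"level"`, `"group"`, `"sex"`.
#' @param level confidence level for the t intervals.
#' @return A data frame with `margin`, `cell`, `n`, `mean_elogit`,
#'   `mean_pct`, `lo_pct`, `hi_pct`.
#' @export
backtransform_means <- function(data, margins = c("level", "group", "sex"),
                                level = 0.95) {
  margins <- match.arg(margins, c("level", "group", "sex"),
                       several.ok = TRUE)
  d <- as.data.frame(data)
  if (any(!is.finite(d$elogit)))
    stop_ccaf("non-finite 'elogit' values; drop incomplete cells first")
  tci <- function(vals) {
    n <- length(vals)
    m <- mean(vals)
    half <- if (n > 1) qt(1 - (1 - level) / 2, n - 1) * sd(vals) / sqrt(n)
            else NA_real_
    c(n = n, mean = m, lo = m - half, hi = m + half)
  }
  rows <- list()
  for (mg in margins) {
    if (mg == "level") {
      vals <- split(d$elogit, d$relative_point_level)
    } else {
      subj <- rowsum(d$elogit, d$subject_id) /
        as.vector(table(d$subject_id)[sort(unique(d$subject_id))])
      lab <- d[[mg]][match(rownames(subj), d$subject_id)]
      vals <- split(as.vector(subj), lab)
    }
    for (cell in names(vals)) {
      s <- tci(vals[[cell]])
      rows[[length(rows) + 1L]] <- data.frame(
        margin = mg, cell = cell, n = unname(s["n"]),
        mean_elogit = unname(s["mean"]),
        mean_pct = 100 * plogis(unname(s["mean"])),
        lo_pct = 100 * plogis(unname(s["lo"])),
        hi_pct = 100 * plogis(unname(s["hi"])),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
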