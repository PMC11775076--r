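#' Classify individual reward preference from a PSE confidence interval
#'
#' A subject prefers alcohol when the 95% bootstrap confidence interval of
#' their PSE lies entirely below 0 (alcohol is chosen at equal or worse
#' point values), prefers snacks when it lies entirely above 0, and has no
#' reliable preference (`"neither"`) when the interval covers 0.
#'
#' @param lo,hi numeric vectors of interval bounds (`lo <= hi`), recycled
#'   against each other.
#' @return character vector with values `"alcohol"`, `"snack"`, `"neither"`.
#' @examples
#' classify_preference(c(-0.5, 0.8, -0.2), c(-0.1, 0.9, 0.02))
#' @export
classify_preference <- function(lo, hi) {
  if (any(lo > hi)) stop_ccaf("interval bounds must satisfy lo <= hi")
  ifelse(hi < 0, "alcohol", ifelse(lo > 0, "snack", "neither"))
}

#' Per-subject PSE intervals and preference categories
#'
#' Fits each subject's own psychometric curve ([fit_subject_curves()]),
#' bootstraps the individual PSE, and classifies the subject with
#' [classify_preference()]. Subjects whose data are separated get
#' ridge-penalised fits; their `separation` flag is carried through.
#'
#' @param summary a [aggregate_choices()] data frame.
#' @param n_boot,level bootstrap resamples and confidence level.
#' @param seed root seed; each subject gets a derived substream.
#' @return A data frame, one row per subject: `subject_id`, carried
#'   covariates (`group`, `sex`, `audit`), `pse`, `ci_lo`, `ci_hi`,
#'   `category`, `separation`.
#' @export
classify_subjects <- function(summary, n_boot = 1000, level = 0.95,
                              seed = NULL) {
  fits <- fit_subject_curves(summary)
  rows <- lapply(names(fits), function(id) {
    fit <- fits[[id]]
    sub <- summary[summary$subject_id == id, , drop = FALSE][1, ]
    out <- data.frame(subject_id = id, stringsAsFactors = FALSE)
    for (cov in c("group", "sex", "audit"))
      if (cov %in% names(sub)) out[[cov]] <- sub[[cov]]
    out$pse <- unname(fit$coefficients["alpha"])
    if (!is.finite(out$pse)) {
      # constant all-or-none chooser: no finite PSE, but the direction of
      # preference is unambiguous
      out$ci_lo <- NA_real_
      out$ci_hi <- NA_real_
      out$category <- if (out$pse < 0) "alcohol" else "snack"
    } else {
      s <- if (is.null(seed)) NULL else derive_seed(seed, id)
      bs <- parametric_bootstrap(fit, n_boot = n_boot, level = level,
                                 seed = s)
      out$ci_lo <- bs$alpha_ci[1]
      out$ci_hi <- bs$alpha_ci[2]
      out$category <- classify_preference(out$ci_lo, out$ci_hi)
    }
    out$separation <- fit$separation_flag
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-by-preference contingency table
#'
#' Cross-tabulates drinking group against preference category with all three
#' categories (`alcohol`, `snack`, `neither`) always present as columns.
#'
#' @param classification a [classify_subjects()] data frame (needs `group`
#'   and `category`).
#' @return An integer matrix, groups in rows, categories in columns.
#' @export
preference_table <- function(classification) {
  stopifnot(all(c("group", "category") %in% names(classification)))
  tab <- table(factor(classification$group, levels = c("HD", "LD")),
               factor(classification$category,
                      levels = c("alcohol", "snack", "neither")))
  unclass(tab)
}

#' Pearson chi-squared test of independence on a contingency table
#'
#' Pearson's \eqn{\chi^2 = \sum (O - E)^2 / E} with expected counts from the
#' table margins and `(r-1)(c-1)` degrees of freedom; the Yates continuity
#' correction `(|O - E| - 0.5)^2 / E` is available for 2x2 tables. No
#' correction is the default; the AUDIT-threshold group comparison is the
#' one analysis conventionally run with the continuity correction.
#'
#' @param tab matrix of non-negative counts with at least 2 rows and 2
#'   columns and no zero row/column margin.
#' @param correction `"none"` (default) or `"yates"` (2x2 tables only).
#' @return An object of class `"ccaf_chisq"`: list with `observed`,
#'   `expected`, `statistic`, `df`, `p.value`, `correction`.
#' @examples
#' chi2_independence(rbind(HD = c(11, 7, 12), LD = c(3, 17, 10)))
#' @export
chi2_independence <- function(tab, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab)) stop_ccaf("counts must be non-negative")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop_ccaf("table must have at least 2 rows and 2 columns")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_ccaf("table has a zero row or column margin")
  if (correction == "yates" && !all(dim(tab) == 2))
    stop_ccaf("the Yates correction applies to 2x2 tables only")
  ht <- suppressWarnings(
    chisq.test(tab, correct = correction == "yates"))
  structure(list(observed = tab, expected = ht$expected,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = unname(ht$p.value),
                 correction = correction),
            class = "ccaf_chisq")
}

#' @export
print.ccaf_chisq <- function(x, digits = 4, ...) {
  cat("Chi-squared test of independence",
      if (x$correction == "yates") "(Yates continuity correction)", "\n")
  print(x$observed)
  cat(sprintf("X-squared = %s, df = %d, p = %s\n",
              signif(x$statistic, digits), x$df, signif(x$p.value, digits)))
  invisible(x)
}
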