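#' Adjusted (empirical) logit of a proportion
#'
#' `log((k + 0.5) / (n - k + 0.5))`: a logit that stays finite at observed
#' proportions of 0 and 1, which occur routinely at the extreme relative
#' point levels (near-floor and near-ceiling choice percentages). It is
#' exactly antisymmetric under `k <-> n - k` and strictly increasing in `k`.
#' Set `adjust = 0` with a `clamp` to get a plain logit with clamped
#' proportions instead.
#'
#' @param k number of alcohol choices (0 <= k <= n).
#' @param n number of responded trials (>= 1).
#' @param adjust additive count adjustment; 0.5 is the default empirical
#'   logit, 0 gives the raw logit (combined with `clamp` for boundary cells).
#' @param clamp when `adjust = 0`, proportions are clamped to
#'   `[clamp, 1 - clamp]` before the logit; ignored otherwise.
#' @return numeric vector of adjusted logits.
#' @examples
#' empirical_logit(0, 32)   # finite floor value
#' empirical_logit(16, 32)  # 0 by symmetry
#' @export
empirical_logit <- function(k, n, adjust = 0.5, clamp = 1 / 64) {
  if (any(n < 1)) stop_ccaf("'n' must be >= 1")
  if (any(k < 0 | k > n)) stop_ccaf("'k' must satisfy 0 <= k <= n")
  if (adjust > 0) {
    log((k + adjust) / (n - k + adjust))
  } else {
    p <- pmin(1 - clamp, pmax(clamp, k / n))
    qlogis(p)
  }
}

#' Aggregate trial-level choices to subject-by-level summaries
#'
#' Collapses completed trial records into one row per subject and relative
#' point level: the count of alcohol choices `k`, the count of responded
#' trials `n` (trials with a missing response are excluded from the
#' denominator), the choice percentage `pct = 100 k / n`, and the adjusted
#' logit `elogit` used by the group-level model. Subject covariates
#' (`group`, `sex`, `audit`) are carried through when present. A subject x
#' level cell in which every trial is missing is emitted with `n = 0`,
#' `missing_data = TRUE` and `NA` percentage/logit, and should be excluded
#' from model fits.
#'
#' @param trials data frame of completed trials with `subject_id`,
#'   `relative_point_level` and `choice` columns (as produced by
#'   [simulate_cohort()] or read from disk).
#' @param adjust,clamp passed to [empirical_logit()].
#' @return A data frame of class `"ccaf_summary"`, one row per subject x
#'   level, ordered by subject then level.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = 2), seed = 1)
#' trials <- simulate_cohort(cohort, generate_schedule(8, seed = 1), seed = 2)
#' aggregate_choices(trials)
#' @export
aggregate_choices <- function(trials, adjust = 0.5, clamp = 1 / 64) {
  need <- c("subject_id", "relative_point_level", "choice")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop_ccaf("trial data lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(trials$relative_point_level %in% c(-2L, 0L, 2L)))
    stop_ccaf("relative point levels must be -2, 0 or +2")
  if (!all(trials$choice %in% c("alcohol", "snack", "missing")))
    stop_ccaf("'choice' must be alcohol, snack or missing")

  key <- interaction(trials$subject_id, trials$relative_point_level,
                     drop = TRUE, lex.order = TRUE)
  k <- as.vector(rowsum(as.numeric(trials$choice == "alcohol"), key))
  n <- as.vector(rowsum(as.numeric(trials$choice != "missing"), key))
  first <- match(levels(key), key)
  out <- data.frame(subject_id = trials$subject_id[first],
                    relative_point_level = trials$relative_point_level[first],
                    k = as.integer(k), n = as.integer(n),
                    stringsAsFactors = FALSE)
  for (cov in c("group", "sex", "audit"))
    if (cov %in% names(trials)) out[[cov]] <- trials[[cov]][first]
  out$pct <- ifelse(out$n > 0, 100 * out$k / out$n, NA_real_)
  out$elogit <- NA_real_
  ok <- out$n > 0
  out$elogit[ok] <- empirical_logit(out$k[ok], out$n[ok], adjust, clamp)
  out$missing_data <- out$n == 0
  out <- out[order(out$subject_id, out$relative_point_level), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ccaf_summary", "data.frame"))
}
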