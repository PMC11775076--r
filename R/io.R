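# Plain-text interchange: every pipeline stage reads and writes ordinary
# CSV so that any stage can be swapped for external data.

#' Read and write trial-level and summary CSV files
#'
#' Thin validated wrappers around [utils::read.csv()] /
#' [utils::write.csv()]. Trial files carry one row per trial with at least
#' `subject_id`, `relative_point_level` and `choice`; summary files carry
#' one row per subject x level with at least `subject_id`,
#' `relative_point_level`, `k` and `n`.
#'
#' @param path file path.
#' @param trials,summary data frames to write.
#' @return `read_trials()` a trial data frame; `read_summary()` a
#'   `ccaf_summary` data frame. The writers return their input invisibly.
#' @export
read_trials <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "relative_point_level", "choice")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_ccaf("trial file lacks column(s): ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(trials)
}

#' @rdname read_trials
#' @export
read_summary <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "relative_point_level", "k", "n")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_ccaf("summary file lacks column(s): ", paste(miss, collapse = ", "))
  if (!"pct" %in% names(d)) d$pct <- ifelse(d$n > 0, 100 * d$k / d$n, NA)
  if (!"elogit" %in% names(d)) {
    d$elogit <- NA_real_
    ok <- d$n > 0
    d$elogit[ok] <- empirical_logit(d$k[ok], d$n[ok])
  }
  structure(d, class = c("ccaf_summary", "data.frame"))
}

#' @rdname read_trials
#' @export
write_summary <- function(summary, path) {
  write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(summary)
}
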