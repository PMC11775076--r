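#' Generate a counterbalanced concurrent-choice trial schedule
#'
#' Builds the trial list for one session of the concurrent-choice
#' alcohol-food task: each trial pairs an alcohol and a snack image, each
#' worth 1 or 3 points. The *relative point level* (alcohol minus snack
#' points) takes the values -2, 0 and +2, with exactly `n_per_level` trials
#' per level. Level -2 trials carry (alcohol 1, snack 3) points, level +2
#' trials (3, 1), and level 0 trials are split evenly between (1, 1) and
#' (3, 3) so that mean point magnitude is balanced across levels. The side
#' on which the alcohol image appears is counterbalanced exactly within each
#' level (hence `n_per_level` must be even). Trial order is a seeded random
#' permutation of this fixed trial multiset.
#'
#' @param n_per_level even positive integer; trials per relative point level.
#'   The default 32 gives the standard 96-trial session.
#' @param seed optional integer seed for the trial-order permutation; the
#'   same seed always yields the same schedule, and the multiset of trials is
#'   identical for all seeds.
#' @return A data frame of class `"ccaf_schedule"` with columns
#'   `trial_index`, `relative_point_level`, `alcohol_points`, `snack_points`
#'   and `alcohol_side` (`"left"`/`"right"`), one row per trial.
#' @examples
#' sched <- generate_schedule(32, seed = 1)
#' table(sched$relative_point_level)
#' table(sched$alcohol_side)
#' @seealso [tally_reward()], [simulate_choices()]
#' @export
generate_schedule <- function(n_per_level = 32, seed = NULL) {
  if (length(n_per_level) != 1L || !is.finite(n_per_level) ||
      n_per_level != round(n_per_level) || n_per_level < 2 ||
      n_per_level %% 2 != 0) {
    stop_ccaf("'n_per_level' must be an even integer >= 2 ",
              "(side counterbalancing within level is otherwise impossible)")
  }
  n <- as.integer(n_per_level)
  half <- n %/% 2L
  sides <- rep(c("left", "right"), half)

  block <- function(level, alc, snk) {
    data.frame(relative_point_level = rep(level, n),
               alcohol_points = alc, snack_points = snk,
               alcohol_side = rep(c("left", "right"), each = half),
               stringsAsFactors = FALSE)
  }
  # level 0: pair type blocked, side alternating within pair type, so both
  # the side split and the (1,1)/(3,3) split are exact within the level
  zero <- data.frame(relative_point_level = 0L,
                     alcohol_points = rep(c(1L, 3L), each = half),
                     snack_points = rep(c(1L, 3L), each = half),
                     alcohol_side = sides,
                     stringsAsFactors = FALSE)
  trials <- rbind(block(-2L, 1L, 3L), zero, block(2L, 3L, 1L))
  perm <- with_seed(seed, sample.int(nrow(trials)))
  trials <- trials[perm, , drop = FALSE]
  trials <- cbind(trial_index = seq_len(nrow(trials)), trials)
  rownames(trials) <- NULL
  structure(trials, n_per_level = n,
            class = c("ccaf_schedule", "data.frame"))
}

#' @export
print.ccaf_schedule <- function(x, ...) {
  cat("Concurrent-choice trial schedule:", nrow(x), "trials (",
      attr(x, "n_per_level"), "per relative point level )\n")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more trials\n", sep = "")
  invisible(x)
}

#' Tally session points and determine the earned reward
#'
#' Applies the end-of-session rule: points are earned only for the chosen
#' option on each trial, and the participant receives the reward category
#' (alcohol drink or snack portion) with the larger point total. Trials with
#' a missing choice earn no points. An exact tie is resolved by `tie_break`
#' (default: the snack reward) and flagged with a warning, keeping runs
#' reproducible.
#'
#' @param trials data frame of completed trials with columns `choice`
#'   (`"alcohol"`, `"snack"` or `"missing"`), `alcohol_points`,
#'   `snack_points`.
#' @param tie_break `"snack"` (deterministic default) or `"random"` (seeded
#'   coin flip).
#' @param seed optional seed, used only when `tie_break = "random"`.
#' @return A list of class `"ccaf_tally"` with elements `reward`
#'   (`"alcohol"` or `"snack"`), `alcohol_total`, `snack_total`, `tie`
#'   (logical).
#' @examples
#' sched <- generate_schedule(4, seed = 1)
#' sched$choice <- "snack"
#' tally_reward(sched)$reward
#' @export
tally_reward <- function(trials, tie_break = c("snack", "random"),
                         seed = NULL) {
  tie_break <- match.arg(tie_break)
  stopifnot(all(c("choice", "alcohol_points", "snack_points") %in%
                  names(trials)))
  done <- trials$choice %in% c("alcohol", "snack")
  if (!any(done)) stop_ccaf("all choices are missing; nothing to tally")
  alc <- sum(trials$alcohol_points[done & trials$choice == "alcohol"])
  snk <- sum(trials$snack_points[done & trials$choice == "snack"])
  tie <- alc == snk
  if (tie) {
    warning("alcohol and snack point totals are tied (", alc,
            "); tie broken by rule '", tie_break, "'", call. = FALSE)
    reward <- if (tie_break == "snack") "snack" else
      with_seed(seed, sample(c("alcohol", "snack"), 1L))
  } else {
    reward <- if (alc > snk) "alcohol" else "snack"
  }
  structure(list(reward = reward, alcohol_total = alc, snack_total = snk,
                 tie = tie),
            class = "ccaf_tally")
}

#' @export
print.ccaf_tally <- function(x, ...) {
  cat("Session tally: alcohol", x$alcohol_total, "vs snack", x$snack_total,
      if (x$tie) "(tie)" else "", "-> reward:", x$reward, "\n")
  invisible(x)
}
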