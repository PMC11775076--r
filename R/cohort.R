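#' Logistic choice probability
#'
#' Probability of choosing alcohol on a trial with relative point level `x`
#' under a location-slope logistic psychometric function with an optional
#' lapse rate:
#' \deqn{P(x) = \lambda + (1 - 2\lambda) \, \mathrm{logit}^{-1}(\beta (x - \alpha))}
#' The location `alpha` is the point of subjective equality (PSE): for any
#' lapse the curve passes through 0.5 at `x = alpha`. `beta` is the slope in
#' logit units per relative-point unit, an index of cost sensitivity.
#'
#' @param x numeric vector of relative point levels.
#' @param alpha PSE (location), in relative-point units.
#' @param beta slope, logit units per relative-point unit.
#' @param lapse stimulus-independent error rate in `[0, 0.5)`; default 0.
#' @return numeric vector of probabilities.
#' @examples
#' choice_probability(c(-2, 0, 2), alpha = 0.9, beta = 0.98)
#' @export
choice_probability <- function(x, alpha, beta, lapse = 0) {
  if (any(lapse < 0 | lapse >= 0.5))
    stop_ccaf("'lapse' must lie in [0, 0.5)")
  lapse + (1 - 2 * lapse) * plogis(beta * (x - alpha))
}

#' Configuration for a synthetic two-group cohort
#'
#' Describes the population from which [generate_cohort()] draws simulated
#' participants: light drinkers (LD) and heavy drinkers (HD), each with
#' group-level distributions for the latent psychometric parameters (PSE
#' `alpha`, slope `beta`), AUDIT scores and weekly drinks. The defaults are
#' anchored to the reference study's fitted group curves and sample table:
#' group mean PSEs +0.9 (LD) and -0.1 (HD), slopes 0.98 and 0.76, AUDIT
#' 7.57 +/- 3.91 vs 15.17 +/- 4.97, drinks/week 5.1 +/- 3.43 vs
#' 16.47 +/- 3.74, and an AUDIT-drinks correlation of 0.74. Between-subject
#' spread of `alpha` and `beta` is not reported at the individual level;
#' the defaults (`alpha_sd = 0.8`, `beta_sd = 0.25`) are chosen to yield a
#' realistic mix of alcohol-, snack- and no-preference individuals while
#' keeping pooled group fits close to the configured means.
#'
#' `alpha` and `beta` are normal (beta truncated below at `beta_min`); AUDIT
#' and drinks/week are drawn from a bivariate normal (a Gaussian copula with
#' normal marginals) honouring `audit_drinks_cor`, after which AUDIT is
#' rounded and clipped to `[0, 40]` and drinks clipped at 0.
#'
#' @param n_per_group subjects per group (sexes balanced within group).
#' @param alpha_mean,alpha_sd named per-group means (`LD`, `HD`) and common
#'   sd of the true PSE.
#' @param beta_mean,beta_sd,beta_min per-group means, common sd and lower
#'   truncation point of the true slope.
#' @param audit_mean,audit_sd per-group AUDIT moments (0-40 scale).
#' @param drinks_mean,drinks_sd per-group weekly-drinks moments.
#' @param audit_drinks_cor latent correlation between AUDIT and drinks/week,
#'   in (-1, 1).
#' @param lapse lapse rate given to every simulated subject.
#' @param sex_alpha_shift optional additive PSE shift: males get
#'   `alpha - sex_alpha_shift` (a positive value moves male preference
#'   towards alcohol). Default 0.
#' @param p_miss per-trial probability of a missing response. Default 0.
#' @return A list of class `"cohort_config"`.
#' @seealso [generate_cohort()], [simulate_cohort()]
#' @export
cohort_config <- function(n_per_group = 30,
                          alpha_mean = c(LD = 0.9, HD = -0.1),
                          alpha_sd = 0.8,
                          beta_mean = c(LD = 0.98, HD = 0.76),
                          beta_sd = 0.25,
                          beta_min = 0.05,
                          audit_mean = c(LD = 7.57, HD = 15.17),
                          audit_sd = c(LD = 3.91, HD = 4.97),
                          drinks_mean = c(LD = 5.1, HD = 16.47),
                          drinks_sd = c(LD = 3.43, HD = 3.74),
                          audit_drinks_cor = 0.74,
                          lapse = 0,
                          sex_alpha_shift = 0,
                          p_miss = 0) {
  if (n_per_group < 1) stop_ccaf("'n_per_group' must be >= 1")
  for (nm in c("alpha_sd", "beta_sd", "audit_sd", "drinks_sd"))
    if (any(get(nm) < 0)) stop_ccaf("'", nm, "' must be >= 0")
  if (abs(audit_drinks_cor) >= 1)
    stop_ccaf("'audit_drinks_cor' must lie in the open interval (-1, 1)")
  if (lapse < 0 || lapse >= 0.5) stop_ccaf("'lapse' must lie in [0, 0.5)")
  if (p_miss < 0 || p_miss >= 1) stop_ccaf("'p_miss' must lie in [0, 1)")
  grp <- function(v) {
    v <- rep_len(unname(v), 2L)
    names(v) <- c("LD", "HD")
    v
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 alpha_mean = grp(alpha_mean), alpha_sd = alpha_sd,
                 beta_mean = grp(beta_mean), beta_sd = beta_sd,
                 beta_min = beta_min,
                 audit_mean = grp(audit_mean), audit_sd = grp(audit_sd),
                 drinks_mean = grp(drinks_mean), drinks_sd = grp(drinks_sd),
                 audit_drinks_cor = audit_drinks_cor,
                 lapse = lapse, sex_alpha_shift = sex_alpha_shift,
                 p_miss = p_miss),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration:", x$n_per_group, "subjects/group\n")
  cat("  alpha (PSE):  LD", x$alpha_mean["LD"], " HD", x$alpha_mean["HD"],
      " sd", x$alpha_sd, "\n")
  cat("  beta (slope): LD", x$beta_mean["LD"], " HD", x$beta_mean["HD"],
      " sd", x$beta_sd, "(>", x$beta_min, ")\n")
  cat("  AUDIT-drinks correlation:", x$audit_drinks_cor,
      " lapse:", x$lapse, "\n")
  invisible(x)
}

# truncated-normal draws by rejection; n small, truncation mild
rnorm_trunc <- function(n, mean, sd, lower) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
  }
  out
}

#' Draw a synthetic cohort of participants
#'
#' Generates `n_per_group` participants per drinking group with balanced
#' sexes (15/15 at the default size), latent psychometric parameters, and
#' AUDIT / drinks-per-week scores drawn from a correlated bivariate model as
#' described in [cohort_config()].
#'
#' @param config a [cohort_config()] object.
#' @param seed optional integer seed; same seed, same cohort.
#' @return A data frame of class `"ccaf_cohort"` with one row per subject and
#'   columns `subject_id`, `group` (`LD`/`HD`), `sex` (`female`/`male`),
#'   `audit`, `drinks_per_week`, `alpha`, `beta`, `lapse`.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' table(cohort$group, cohort$sex)
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    rows <- lapply(c("LD", "HD"), function(g) {
      n <- config$n_per_group
      n_f <- ceiling(n / 2)
      sex <- rep(c("female", "male"), c(n_f, n - n_f))
      # bivariate normal via Cholesky: audit first, drinks correlated
      z1 <- rnorm(n); z2 <- rnorm(n)
      r <- config$audit_drinks_cor
      audit_raw <- config$audit_mean[g] + config$audit_sd[g] * z1
      drinks_raw <- config$drinks_mean[g] +
        config$drinks_sd[g] * (r * z1 + sqrt(1 - r^2) * z2)
      alpha <- rnorm(n, config$alpha_mean[g], config$alpha_sd)
      alpha <- alpha - ifelse(sex == "male", config$sex_alpha_shift, 0)
      beta <- if (config$beta_sd > 0)
        rnorm_trunc(n, config$beta_mean[g], config$beta_sd, config$beta_min)
      else rep(max(config$beta_mean[g], config$beta_min), n)
      data.frame(subject_id = sprintf("%s%02d", g, seq_len(n)),
                 group = g, sex = sex,
                 audit = as.integer(pmin(40, pmax(0, round(audit_raw)))),
                 drinks_per_week = pmax(0, drinks_raw),
                 alpha = alpha, beta = beta, lapse = config$lapse,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("ccaf_cohort", "data.frame"))
  })
}

#' Simulate one subject's choices on a trial schedule
#'
#' Each trial's choice is an independent Bernoulli draw with
#' `P(alcohol) = choice_probability(level, alpha, beta, lapse)`; with
#' probability `p_miss` the response is recorded as `"missing"` instead
#' (no response inside the response window). The same profile, schedule and
#' seed always reproduce the same choice vector.
#'
#' @param profile a single-row data frame or list with elements `alpha`,
#'   `beta` and optionally `lapse`, `subject_id` (e.g. one row of a
#'   [generate_cohort()] result).
#' @param schedule a [generate_schedule()] data frame.
#' @param seed optional integer seed.
#' @param p_miss per-trial missing-response probability (default 0).
#' @return The schedule with columns `choice` and, when the profile carries
#'   one, `subject_id` appended.
#' @export
simulate_choices <- function(profile, schedule, seed = NULL, p_miss = 0) {
  if (nrow(schedule) == 0L) stop_ccaf("'schedule' is empty")
  alpha <- profile$alpha; beta <- profile$beta
  lapse <- profile$lapse %||% 0
  p <- choice_probability(schedule$relative_point_level, alpha, beta, lapse)
  out <- as.data.frame(schedule)
  out$choice <- with_seed(seed, {
    ch <- ifelse(runif(nrow(out)) < p, "alcohol", "snack")
    if (p_miss > 0) ch[runif(nrow(out)) < p_miss] <- "missing"
    ch
  })
  if (!is.null(profile$subject_id)) out$subject_id <- profile$subject_id
  out
}

#' Simulate trial data for a whole cohort
#'
#' Runs [simulate_choices()] for every subject on the same schedule. Each
#' subject gets a deterministic RNG substream derived from the root seed and
#' the subject id, so results do not depend on row order.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param schedule a [generate_schedule()] data frame.
#' @param seed root integer seed.
#' @param p_miss per-trial missing-response probability; defaults to 0.
#' @return A long data frame of completed trials (one row per subject x
#'   trial) with `subject_id`, `group`, `sex`, `audit` carried over.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = 2), seed = 1)
#' trials <- simulate_cohort(cohort, generate_schedule(4, seed = 1), seed = 2)
#' head(trials)
#' @export
simulate_cohort <- function(cohort, schedule, seed = NULL, p_miss = 0) {
  pieces <- lapply(seq_len(nrow(cohort)), function(i) {
    prof <- as_record(cohort, i)
    s <- if (is.null(seed)) NULL else derive_seed(seed, prof$subject_id)
    tr <- simulate_choices(prof, schedule, seed = s, p_miss = p_miss)
    tr$group <- prof$group; tr$sex <- prof$sex; tr$audit <- prof$audit
    tr
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
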