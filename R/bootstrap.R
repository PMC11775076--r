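#' Parametric-bootstrap confidence intervals for a psychometric fit
#'
#' Simulates `n_boot` datasets from the fitted model — at each design point
#' `x_j` a fresh count `k* ~ Binomial(n_j, p_hat_j)` — refits the
#' two-parameter logistic model to each, and returns percentile confidence
#' intervals for the PSE (`alpha`) and slope (`beta`). Replicates whose
#' unpenalised refit diverges (separated resamples) are refit with the same
#' weak ridge penalty as the original fit and counted in `n_ridge`;
#' replicates that still fail are dropped and counted in `n_failed`. More
#' than 20% failed refits aborts with an error, since percentile intervals
#' from the remainder would be unreliable.
#'
#' @param fit a [fit_psychometric()] object.
#' @param n_boot number of bootstrap resamples (the standard choice here is
#'   1000).
#' @param level confidence level in (0, 1), default 0.95.
#' @param seed optional integer seed; the same seed reproduces the intervals
#'   exactly.
#' @param ridge ridge penalty for separated resamples.
#' @return An object of class `"psychboot"`: list with `alpha_ci`,
#'   `beta_ci` (length-2 vectors), `alpha_draws`, `beta_draws`, `n_boot`,
#'   `n_failed`, `n_ridge`, `level`, `seed`, and the point `estimates`.
#' @examples
#' d <- data.frame(relative_point_level = c(-2, 0, 2),
#'                 k = c(40, 160, 280), n = 320)
#' fit <- fit_psychometric(d)
#' parametric_bootstrap(fit, n_boot = 200, seed = 1)
#' @export
parametric_bootstrap <- function(fit, n_boot = 1000, level = 0.95,
                                 seed = NULL, ridge = 1e-4) {
  stopifnot(inherits(fit, "psychfit"))
  if (n_boot < 1) stop_ccaf("'n_boot' must be >= 1")
  if (level <= 0 || level >= 1) stop_ccaf("'level' must be in (0, 1)")
  if (!all(is.finite(fit$coefficients)))
    stop_ccaf("cannot bootstrap a boundary fit (constant all-or-none ",
              "choices give an unbounded location); the direction of ",
              "preference is sign(alpha) but no finite interval exists")
  d <- fit$data
  p <- predict(fit)
  m <- nrow(d)

  res <- with_seed(seed, {
    K <- matrix(rbinom(n_boot * m, size = rep(d$n, each = n_boot),
                       prob = rep(p, each = n_boot)), nrow = n_boot)
    r <- irls_many(K, d$n, d$x, ridge = 0)
    bad <- which(r$diverged)
    n_ridge <- 0L
    if (length(bad)) {
      rr <- irls_many(K[bad, , drop = FALSE], d$n, d$x, ridge = ridge)
      r$alpha[bad] <- rr$alpha
      r$beta[bad] <- rr$beta
      r$converged[bad] <- rr$converged
      r$diverged[bad] <- rr$diverged
      n_ridge <- length(bad)
    }
    list(r = r, n_ridge = n_ridge)
  })
  r <- res$r
  ok <- r$converged & !r$diverged & is.finite(r$alpha) & is.finite(r$beta)
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    stop_ccaf("parametric bootstrap unstable: ", n_failed, " of ", n_boot,
              " refits failed (> 20%); the fit is too degenerate for ",
              "percentile intervals")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  structure(list(
    alpha_ci = unname(quantile(r$alpha[ok], qs)),
    beta_ci = unname(quantile(r$beta[ok], qs)),
    alpha_draws = r$alpha[ok], beta_draws = r$beta[ok],
    estimates = fit$coefficients,
    n_boot = as.integer(n_boot), n_failed = as.integer(n_failed),
    n_ridge = as.integer(res$n_ridge),
    level = level, seed = seed
  ), class = "psychboot")
}

#' @export
print.psychboot <- function(x, digits = 4, ...) {
  pct <- 100 * x$level
  cat("Parametric bootstrap (", x$n_boot, " resamples, ", pct,
      "% percentile intervals)\n", sep = "")
  cat(sprintf("  PSE (alpha): %s  CI [%s, %s]\n",
              signif(x$estimates["alpha"], digits),
              signif(x$alpha_ci[1], digits), signif(x$alpha_ci[2], digits)))
  cat(sprintf("  slope (beta): %s  CI [%s, %s]\n",
              signif(x$estimates["beta"], digits),
              signif(x$beta_ci[1], digits), signif(x$beta_ci[2], digits)))
  if (x$n_ridge > 0)
    cat("  ", x$n_ridge, " separated resamples refit with ridge penalty\n")
  if (x$n_failed > 0) cat("  ", x$n_failed, " failed refits dropped\n")
  invisible(x)
}

#' @rdname fit_psychometric
#' @param parm parameters to report (`"alpha"`, `"beta"` or both).
#' @param level confidence level.
#' @param n_boot bootstrap resamples used by `confint`.
#' @export
confint.psychfit <- function(object, parm = c("alpha", "beta"),
                             level = 0.95, n_boot = 1000, seed = NULL, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  bs <- parametric_bootstrap(object, n_boot = n_boot, level = level,
                             seed = seed)
  out <- rbind(alpha = bs$alpha_ci, beta = bs$beta_ci)
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out[parm, , drop = FALSE]
}

#' Psychometric fit of alcohol choice against a severity covariate
#'
#' Within one relative point level, fits the binomial logistic model of
#' alcohol-choice counts on a continuous subject covariate (AUDIT score by
#' default): each subject contributes `(k, n)` at their covariate value. The
#' reported slope is in logit units per covariate point; the location is the
#' covariate value at which alcohol choice crosses 50% at that level.
#'
#' @param summary a [aggregate_choices()] data frame including the covariate
#'   column.
#' @param level the relative point level to subset (-2, 0 or +2).
#' @param covariate covariate column name (default `"audit"`).
#' @param n_boot,ci_level,seed bootstrap settings (see
#'   [parametric_bootstrap()]).
#' @return A list with elements `fit` (a `psychfit`) and `boot` (a
#'   `psychboot`).
#' @export
fit_vs_covariate <- function(summary, level, covariate = "audit",
                             n_boot = 1000, ci_level = 0.95, seed = NULL) {
  if (!covariate %in% names(summary))
    stop_ccaf("summary data lacks a '", covariate, "' column")
  if (anyNA(summary[[covariate]]))
    stop_ccaf("covariate '", covariate, "' has missing values")
  sub <- summary[summary$relative_point_level == level & summary$n > 0, ,
                 drop = FALSE]
  if (nrow(sub) == 0)
    stop_ccaf("no data at relative point level ", level)
  if (length(unique(sub[[covariate]])) < 2)
    stop_ccaf("covariate '", covariate, "' is constant; slope unidentifiable")
  fit <- fit_psychometric(sub, predictor = covariate, scope = "covariate")
  boot <- parametric_bootstrap(fit, n_boot = n_boot, level = ci_level,
                               seed = seed)
  list(fit = fit, boot = boot)
}
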