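# Shared fixtures and independent oracles for the test suite.
# Oracles are written from first principles and never call the package
# routines whose results they check.

# Pearson / Yates chi-squared statistic by direct enumeration of expected
# counts from the table margins.
chi2_oracle <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (yates) sum((abs(tab - E) - 0.5)^2 / E) else sum((tab - E)^2 / E)
}

# Binomial log-likelihood of the location-slope logistic model (without the
# binomial-coefficient constant), written independently of the fit engine.
loglik_oracle <- function(alpha, beta, k, n, x) {
  p <- pmin(1 - 1e-12, pmax(1e-12, plogis(beta * (x - alpha))))
  sum(k * log(p) + (n - k) * log(1 - p))
}

# Two-stage grid maximisation of the likelihood: coarse pass over the full
# ranges, then a fine pass at the stated resolution around the coarse
# optimum. Returns the best log-likelihood found.
grid_loglik_max <- function(k, n, x, a_range = c(-3, 3),
                            b_range = c(0.05, 4), res = 1e-3) {
  best <- -Inf; best_a <- NA; best_b <- NA
  scan <- function(as, bs) {
    for (b in bs) {
      p <- plogis(outer(as, x, function(a, xx) b * (xx - a)))
      # keep the matrix attributes: pmin/pmax take them from the 1st arg
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- drop(log(p) %*% k + log(1 - p) %*% (n - k))
      i <- which.max(ll)
      if (ll[i] > best) {
        best <<- ll[i]; best_a <<- as[i]; best_b <<- b
      }
    }
  }
  scan(seq(a_range[1], a_range[2], by = 0.02),
       seq(b_range[1], b_range[2], by = 0.02))
  scan(seq(best_a - 0.03, best_a + 0.03, by = res),
       seq(max(b_range[1], best_b - 0.03), best_b + 0.03, by = res))
  best
}

# A small complete cohort dataset: trials and subject-by-level summary.
make_summary <- function(n_per_group = 6, n_per_level = 16, seed = 42,
                         config = cohort_config(n_per_group = n_per_group)) {
  cohort <- generate_cohort(config, seed = seed)
  sched <- generate_schedule(n_per_level, seed = seed + 1)
  trials <- simulate_cohort(cohort, sched, seed = seed + 2)
  list(cohort = cohort, schedule = sched, trials = trials,
       summary = aggregate_choices(trials))
}

# Balanced 60-subject design (2 groups x 2 sexes x 15) used by the
# split-plot df checks.
make_study_summary <- function(seed = 7) {
  make_summary(n_per_group = 30, n_per_level = 32, seed = seed)$summary
}
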