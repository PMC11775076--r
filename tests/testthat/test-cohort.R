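test_that("choice_probability has logistic form, location 0.5 and symmetry", {
  # location definition holds for any lapse
  expect_equal(choice_probability(0.3, alpha = 0.3, beta = 2), 0.5)
  expect_equal(choice_probability(-1, alpha = -1, beta = 0.5, lapse = 0.2),
               0.5)
  # flat curve at beta = 0
  expect_equal(choice_probability(c(-2, 0, 2), alpha = 1, beta = 0),
               rep(0.5, 3))
  # direct evaluation of the formula at the reference group parameters
  expect_equal(choice_probability(2, alpha = 0.9, beta = 0.98),
               0.7461153, tolerance = 1e-6)
  # monotone in x, symmetric about alpha when lapse = 0
  x <- seq(-4, 4, by = 0.25)
  p <- choice_probability(x, alpha = 0.4, beta = 1.2)
  expect_true(all(diff(p) > 0))
  d <- runif(20, 0, 3)
  expect_equal(choice_probability(0.4 + d, 0.4, 1.2) +
                 choice_probability(0.4 - d, 0.4, 1.2),
               rep(1, 20))
  # lapse bounds the curve away from 0 and 1
  pl <- choice_probability(c(-50, 50), alpha = 0, beta = 1, lapse = 0.1)
  expect_equal(pl, c(0.1, 0.9))
  expect_error(choice_probability(0, 0, 1, lapse = 0.5), "lapse")
})

test_that("generate_cohort respects sizes, sex balance and ranges", {
  cohort <- generate_cohort(cohort_config(), seed = 1)
  expect_equal(nrow(cohort), 60)
  expect_equal(as.vector(table(cohort$group)), c(30, 30))
  expect_true(all(table(cohort$group, cohort$sex) == 15))
  expect_true(all(cohort$audit >= 0 & cohort$audit <= 40))
  expect_true(all(cohort$beta > 0))
  expect_true(all(cohort$drinks_per_week >= 0))
  expect_identical(cohort, generate_cohort(cohort_config(), seed = 1))
  expect_error(generate_cohort(cohort_config(n_per_group = 0)), "n_per_group")
})

test_that("degenerate spreads collapse to the group means", {
  cfg <- cohort_config(audit_sd = c(LD = 0, HD = 0), beta_sd = 0)
  cohort <- generate_cohort(cfg, seed = 2)
  expect_true(all(cohort$audit[cohort$group == "LD"] == round(7.57)))
  expect_true(all(cohort$audit[cohort$group == "HD"] == round(15.17)))
  expect_equal(unique(cohort$beta[cohort$group == "LD"]), 0.98)
})

test_that("generator moments and AUDIT-drinks correlation converge", {
  cfg <- cohort_config(n_per_group = 2000)
  cohort <- generate_cohort(cfg, seed = 3)
  for (g in c("LD", "HD")) {
    sub <- cohort[cohort$group == g, ]
    # sample correlation honours the configured 0.74 (rounding/clipping
    # attenuates it only marginally)
    expect_equal(cor(sub$audit, sub$drinks_per_week), 0.74,
                 tolerance = 0.05)
    # 3-sigma Monte-Carlo tolerances on the configured moments
    expect_equal(mean(sub$alpha), unname(cfg$alpha_mean[g]),
                 tolerance = 3 * cfg$alpha_sd / sqrt(2000) /
                   abs(cfg$alpha_mean[g]))
    expect_lt(abs(mean(sub$audit) - cfg$audit_mean[g]),
              3 * cfg$audit_sd[g] / sqrt(2000) + 0.5)
  }
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(audit_drinks_cor = 1), "open interval")
  expect_error(cohort_config(alpha_sd = -1), "alpha_sd")
  expect_error(cohort_config(lapse = 0.7), "lapse")
})

test_that("simulate_choices draws from the subject's psychometric curve", {
  sched <- generate_schedule(4, seed = 1)
  # saturated preference: alcohol on every trial
  prof <- list(subject_id = "S", alpha = -1e6, beta = 1, lapse = 0)
  tr <- simulate_choices(prof, sched, seed = 1)
  expect_true(all(tr$choice == "alcohol"))
  # determinism under seed
  prof2 <- list(subject_id = "S", alpha = 0.2, beta = 1, lapse = 0)
  expect_identical(simulate_choices(prof2, sched, seed = 9),
                   simulate_choices(prof2, sched, seed = 9))
  expect_error(simulate_choices(prof2, sched[0, ]), "empty")
})

test_that("empirical choice fractions obey the law of large numbers", {
  many <- data.frame(relative_point_level = rep(2, 10000))
  prof <- list(alpha = 0, beta = 5, lapse = 0)
  tr <- simulate_choices(prof, many, seed = 4)
  p <- choice_probability(2, 0, 5)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(tr$choice == "alcohol") - p), 3 * se)
})

test_that("cohort simulation is reproducible and order independent", {
  cohort <- generate_cohort(cohort_config(n_per_group = 3), seed = 5)
  sched <- generate_schedule(4, seed = 5)
  a <- simulate_cohort(cohort, sched, seed = 6)
  b <- simulate_cohort(cohort[rev(seq_len(nrow(cohort))), ], sched, seed = 6)
  b <- b[order(match(b$subject_id, a$subject_id), b$trial_index), ]
  rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("missing responses appear at the configured rate", {
  cohort <- generate_cohort(cohort_config(n_per_group = 10), seed = 7)
  sched <- generate_schedule(32, seed = 7)
  trials <- simulate_cohort(cohort, sched, seed = 8, p_miss = 0.1)
  rate <- mean(trials$choice == "missing")
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(trials)))
})
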