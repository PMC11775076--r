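test_that("sums of squares decompose the total exactly", {
  dat <- make_summary(n_per_group = 8, n_per_level = 8, seed = 3)
  tab <- split_plot_model(dat$summary)
  expect_equal(sum(tab$ss), attr(tab, "ss_total"), tolerance = 1e-10)
  # every SS non-negative, partial eta squared in [0, 1]
  expect_true(all(tab$ss >= 0))
  pes <- tab$partial_eta_sq[!is.na(tab$partial_eta_sq)]
  expect_true(all(pes >= 0 & pes <= 1))
})

test_that("the audit model uses linear level coding with 1-df tests", {
  summ <- make_study_summary(seed = 19)
  tab <- split_plot_model(summ, between = "audit")
  audit_row <- tab[tab$effect == "audit", ]
  expect_equal(c(audit_row$df1, audit_row$df2), c(1, 56))
  lev <- tab[tab$effect == "level", ]
  expect_equal(c(lev$df1, lev$df2), c(1, 116))
})

test_that("unbalanced designs are rejected with the offending subjects", {
  dat <- make_summary(n_per_group = 4, n_per_level = 8, seed = 5)
  summ <- dat$summary
  broken <- summ[!(summ$subject_id == "LD01" &
                     summ$relative_point_level == 0), ]
  expect_error(split_plot_model(broken), "LD01")
})

test_that("degenerate variance strata are flagged, not fabricated", {
  # constant within subject, constant group offset: group F explodes (capped
  # + flagged), level has zero SS against zero error (flagged degenerate)
  grid <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                      relative_point_level = c(-2, 0, 2))
  grid$group <- ifelse(as.integer(sub("S", "", grid$subject_id)) <= 4,
                       "LD", "HD")
  grid$sex <- rep(c("female", "male"), length.out = nrow(grid))
  grid$elogit <- ifelse(grid$group == "HD", 1, 0)
  tab <- split_plot_model(grid)
  g <- tab[tab$effect == "group", ]
  expect_equal(g$flag, "capped")
  expect_equal(g$F, 1e6)
  lev <- tab[tab$effect == "level", ]
  expect_equal(lev$flag, "degenerate")
  expect_true(is.na(lev$F))
})

test_that("split-plot F equals the subject-random-intercept mixed model", {
  skip_if_not_installed("lmerTest")
  summ <- make_study_summary(seed = 23)
  tab <- split_plot_model(summ)
  d <- as.data.frame(summ)
  d$level <- factor(d$relative_point_level)
  lfit <- lmerTest::lmer(elogit ~ group * sex * level + (1 | subject_id),
                         data = d)
  lan <- as.data.frame(anova(lfit, ddf = "Satterthwaite"))
  for (eff in c("group", "sex", "level", "group:level", "group:sex")) {
    Fv <- tab$F[tab$effect == eff]
    expect_lt(abs(Fv - lan[eff, "F value"]), 1e-6 * max(1, Fv))
    expect_lt(abs(tab$df2[tab$effect == eff] - lan[eff, "DenDF"]), 1e-6)
  }
})

test_that("cell means back-transform to the percentage scale", {
  grid <- expand.grid(subject_id = sprintf("S%02d", 1:6),
                      relative_point_level = c(-2, 0, 2))
  grid$group <- "LD"; grid$sex <- "female"; grid$elogit <- 0
  cells <- backtransform_means(grid, margins = "level")
  expect_equal(cells$mean_pct, rep(50, 3))

  # simulation oracle: with a homogeneous cohort and many trials the level
  # cell means approach the generating probabilities
  cfg <- cohort_config(n_per_group = 20, alpha_sd = 0, beta_sd = 0,
                       alpha_mean = c(LD = 0.4, HD = 0.4),
                       beta_mean = c(LD = 0.9, HD = 0.9))
  dat <- make_summary(n_per_group = 20, n_per_level = 200, seed = 31,
                      config = cfg)
  cells <- backtransform_means(dat$summary, margins = "level")
  truth <- 100 * choice_probability(c(-2, 0, 2), 0.4, 0.9)
  expect_equal(cells$mean_pct, truth, tolerance = 0.05)
  expect_true(all(cells$lo_pct < cells$mean_pct &
                    cells$mean_pct < cells$hi_pct))
})
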