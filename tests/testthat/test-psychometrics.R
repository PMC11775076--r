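ref_counts <- data.frame(relative_point_level = c(-2, 0, 2),
                         k = c(4, 16, 28), n = 32)

test_that("symmetric counts give a PSE of zero", {
  fit <- fit_psychometric(ref_counts)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["alpha"]), 0, tolerance = 1e-8)
  expect_equal(interpolate_pse(fit), 0, tolerance = 1e-8)
})

test_that("shifting every level shifts the PSE by exactly that amount", {
  fit0 <- fit_psychometric(ref_counts)
  for (shift in c(-1.5, 0.7)) {
    d <- ref_counts
    d$relative_point_level <- d$relative_point_level + shift
    fit <- fit_psychometric(d)
    expect_equal(coef(fit)["alpha"], coef(fit0)["alpha"] + shift,
                 tolerance = 1e-7)
    expect_equal(coef(fit)["beta"], coef(fit0)["beta"], tolerance = 1e-7)
  }
})

test_that("location-slope and intercept-slope routes agree to 1e-6", {
  set.seed(31)
  for (r in 1:20) {
    alpha <- runif(1, -1.5, 1.5); beta <- runif(1, 0.3, 2)
    k <- rbinom(3, 64, choice_probability(c(-2, 0, 2), alpha, beta))
    if (all(k %in% c(0, 64))) next
    d <- data.frame(relative_point_level = c(-2, 0, 2), k = k, n = 64)
    fit <- fit_psychometric(d)
    if (fit$separation_flag) next
    ref <- ccaf:::fit_binom_glm(k, rep(64, 3), c(-2, 0, 2))
    expect_equal(unname(coef(fit)["alpha"]), unname(ref["alpha"]),
                 tolerance = 1e-6)
    expect_equal(unname(coef(fit)["beta"]), unname(ref["beta"]),
                 tolerance = 1e-6)
    # intercept-slope conversion identity alpha = -intercept/slope
    expect_equal(unname(-fit$intercept_slope["intercept"] /
                          fit$intercept_slope["slope"]),
                 unname(coef(fit)["alpha"]), tolerance = 1e-8)
  }
})

test_that("the PSE equals -intercept/slope of the reference group curve", {
  # intercept-slope pair equivalent to the light-drinker group curve
  expect_equal(-(-0.882) / 0.98, 0.9)
})

test_that("log-likelihood matches the glm log-likelihood", {
  d <- data.frame(relative_point_level = c(-2, 0, 2),
                  k = c(6, 20, 30), n = 36)
  fit <- fit_psychometric(d)
  gl <- glm(cbind(k, n - k) ~ relative_point_level, binomial(), data = d)
  expect_equal(fit$loglik, as.numeric(logLik(gl)), tolerance = 1e-6)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
})

test_that("exactly representable proportions are fitted exactly", {
  # p = (0.2, 0.5, 0.8) lies on the logistic curve alpha 0, beta logit(.8)/2
  d <- data.frame(relative_point_level = c(-2, 0, 2),
                  k = c(2, 5, 8), n = 10)
  fit <- fit_psychometric(d)
  expect_equal(predict(fit), c(0.2, 0.5, 0.8), tolerance = 1e-7)
  expect_equal(unname(coef(fit)["beta"]), qlogis(0.8) / 2, tolerance = 1e-6)
})

test_that("fits recover pooled group parameters across replicates", {
  # simulation oracle: data generated from alpha 0.9, beta 0.98 at the
  # study's pooled size (30 subjects x 96 trials -> 960 per level). The
  # Fisher information of this design gives se(alpha) ~ 0.050, so
  # |alpha_hat - 0.9| < 0.1 is a ~2-sigma event with probability ~0.95;
  # the assertion allows a 3-sigma Monte-Carlo margin at 200 replicates.
  set.seed(57)
  est <- replicate(200, {
    k <- rbinom(3, 960, choice_probability(c(-2, 0, 2), 0.9, 0.98))
    fit <- fit_psychometric(
      data.frame(relative_point_level = c(-2, 0, 2), k = k, n = 960))
    unname(coef(fit)["alpha"])
  })
  expect_gte(mean(abs(est - 0.9) < 0.1), 0.90)
  expect_lt(abs(mean(est) - 0.9), 3 * 0.05 / sqrt(200))
})

test_that("separated data are flagged and ridge-bounded", {
  d <- data.frame(relative_point_level = c(-2, 0, 2),
                  k = c(0, 0, 32), n = 32)
  fit <- fit_psychometric(d)
  expect_true(fit$separation_flag)
  expect_true(all(is.finite(coef(fit))))
  expect_gt(coef(fit)["beta"], 0)
  expect_equal(fit$ridge_used, 1e-4)
})

test_that("a single predictor value is rejected", {
  d <- data.frame(relative_point_level = 0, k = 10, n = 32)
  expect_error(fit_psychometric(d), "distinct")
})

test_that("prediction, residuals and simulation behave as model methods", {
  fit <- fit_psychometric(ref_counts)
  expect_equal(predict(fit, newdata = coef(fit)["alpha"]), 0.5)
  expect_equal(predict(fit, newdata = 1, type = "link"),
               unname(coef(fit)["beta"] * (1 - coef(fit)["alpha"])))
  expect_length(residuals(fit), 3)
  expect_length(fitted(fit), 3)
  s1 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(s1, simulate(fit, nsim = 3, seed = 1))
  expect_true(all(s1$sim_1 >= 0 & s1$sim_1 <= s1$n))
})

test_that("bootstrap intervals are ordered, cover the estimate and repeat", {
  fit <- fit_psychometric(
    data.frame(relative_point_level = c(-2, 0, 2),
               k = c(40, 160, 280), n = 320))
  bs <- parametric_bootstrap(fit, n_boot = 1000, seed = 10)
  expect_lt(bs$alpha_ci[1], bs$alpha_ci[2])
  expect_true(bs$alpha_ci[1] <= coef(fit)["alpha"] &&
                coef(fit)["alpha"] <= bs$alpha_ci[2])
  expect_true(bs$beta_ci[1] <= coef(fit)["beta"] &&
                coef(fit)["beta"] <= bs$beta_ci[2])
  bs2 <- parametric_bootstrap(fit, n_boot = 1000, seed = 10)
  expect_identical(bs$alpha_ci, bs2$alpha_ci)
  expect_identical(bs$beta_ci, bs2$beta_ci)
  # confint method reports the same intervals
  ci <- confint(fit, n_boot = 1000, seed = 10)
  expect_equal(unname(ci["alpha", ]), bs$alpha_ci)
})

test_that("bootstrap interval width shrinks with the number of trials", {
  set.seed(91)
  width_at <- function(n_per_level) {
    mean(replicate(5, {
      k <- rbinom(3, n_per_level,
                  choice_probability(c(-2, 0, 2), 0.4, 0.9))
      fit <- fit_psychometric(data.frame(
        relative_point_level = c(-2, 0, 2), k = k, n = n_per_level))
      bs <- parametric_bootstrap(fit, n_boot = 400,
                                 seed = sample.int(1e6, 1))
      diff(bs$alpha_ci)
    }))
  }
  expect_lt(width_at(512), width_at(32))
})

test_that("bootstrap of a separated fit falls back to ridge refits", {
  d <- data.frame(relative_point_level = c(-2, 0, 2),
                  k = c(0, 0, 32), n = 32)
  fit <- fit_psychometric(d)
  bs <- parametric_bootstrap(fit, n_boot = 200, seed = 2)
  expect_gt(bs$n_ridge, 0)
  expect_lte(bs$n_failed, 40)
})

test_that("covariate fits recover the sign of an AUDIT-linked preference", {
  # subjects whose PSE decreases with AUDIT choose alcohol more at higher
  # severity: the fitted choice-vs-AUDIT slope must be positive at every
  # relative point level
  set.seed(13)
  audit <- rep(seq(2, 30, length.out = 30), each = 1)
  rows <- do.call(rbind, lapply(seq_along(audit), function(i) {
    alpha_i <- 2 - 0.15 * audit[i]
    p <- choice_probability(c(-2, 0, 2), alpha_i, 0.9)
    data.frame(subject_id = sprintf("S%02d", i),
               relative_point_level = c(-2, 0, 2),
               k = rbinom(3, 32, p), n = 32, audit = audit[i])
  }))
  for (lev in c(-2, 0, 2)) {
    res <- fit_vs_covariate(rows, level = lev, n_boot = 200, seed = lev + 3)
    expect_gt(coef(res$fit)["beta"], 0)
    expect_gt(res$boot$beta_ci[1], 0)
  }
  rows$audit <- 10
  expect_error(fit_vs_covariate(rows, level = 0), "constant")
})

test_that("audit-independent preference yields slope CIs that cover zero", {
  set.seed(29)
  covered <- replicate(30, {
    audit <- sample(2:30, 24, replace = TRUE)
    rows <- do.call(rbind, lapply(seq_along(audit), function(i) {
      p <- choice_probability(c(-2, 0, 2), 0.4, 0.9)
      data.frame(subject_id = sprintf("S%02d", i),
                 relative_point_level = c(-2, 0, 2),
                 k = rbinom(3, 32, p), n = 32, audit = audit[i])
    }))
    res <- fit_vs_covariate(rows, level = 0, n_boot = 300,
                            seed = sample.int(1e6, 1))
    res$boot$beta_ci[1] <= 0 && 0 <= res$boot$beta_ci[2]
  })
  # nominal 95% coverage; 3-sigma lower bound at 30 replicates
  expect_gte(sum(covered), 24)
})
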