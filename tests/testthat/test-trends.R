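test_that("AICc follows its closed form and large-n limit", {
  expect_equal(aicc(-10, 3, 20), 20 + 6 + 24 / 16)
  expect_lt(abs(aicc(-100, 5, 1e6) - (200 + 10)), 0.01)
  expect_gt(aicc(-259.5, 6, 126), 2 * 259.5)
  expect_error(aicc(-10, 5, 6), "AICc undefined")
})

test_that("with no between-whale variance the LMM collapses to OLS", {
  set.seed(71)
  obs <- make_study_shape_obs(71, slope_sd = 0, intercept_sd = 0,
                              resid_sd = 1, center_groups = TRUE)
  ols <- stats::coef(stats::lm(response ~ age_yr, data = obs))
  for (est in c("ML", "REML")) {
    fit <- fit_lmm(obs, "random_intercept", est)
    expect_equal(unname(fit$fixed_effects$estimate), unname(ols),
                 tolerance = 1e-4)
  }
})

test_that("the denominator df matches the within-group convention", {
  obs <- make_study_shape_obs(72)
  expect_equal(nrow(obs), 126L)
  fit <- fit_lmm(obs, "random_intercept_slope", "ML")
  fe <- fit$fixed_effects
  # N - G - q = 126 - 9 - 1
  expect_equal(unname(fe$df[fe$term == "age_yr"]), 116)
  expect_equal(fit$n_groups, 9L)
})

test_that("fixed-slope recovery at the study's data shape", {
  fit <- fit_lmm(make_study_shape_obs(73), "random_intercept_slope", "ML")
  fe <- fit$fixed_effects
  est <- fe$estimate[fe$term == "age_yr"]
  se <- fe$se[fe$term == "age_yr"]
  expect_lt(abs(est - (-0.163)), 2 * se)
  expect_equal(nrow(fit$coefficients), 9L)
})

test_that("model selection ranks by AICc and refits by REML", {
  sel <- select_model(make_study_shape_obs(74, slope_sd = 0.3))
  cmp <- sel$comparison
  # bookkeeping identity: AICc recomputable from logLik, k, n
  expect_equal(cmp$aicc,
               mapply(aicc, cmp$logLik, cmp$k, rep(126, 3)))
  # ML nesting monotonicity for the age-containing variants
  expect_gte(cmp$logLik[3], cmp$logLik[2] - 1e-6)
  expect_gte(cmp$logLik[2], cmp$logLik[1] - 1e-6)
  expect_equal(sel$best_variant, cmp$variant[which.min(cmp$aicc)])
  expect_equal(sel$best_fit$estimation, "REML")
  expect_true(is.finite(sel$diagnostics$shapiro_w))
})

test_that("strong slope heterogeneity selects the random-slope model", {
  sel <- select_model(make_study_shape_obs(75, slope_sd = 0.5,
                                           resid_sd = 0.8))
  expect_equal(sel$best_variant, "random_intercept_slope")
})

test_that("pearson test equals the covariance-formula oracle", {
  set.seed(76)
  for (rep in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    ct <- pearson_corr_test(x, y)
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(ct$r, r, tolerance = 1e-12)
    expect_equal(ct$r_squared, r^2, tolerance = 1e-12)
    tstat <- r * sqrt((9 - 2) / (1 - r^2))
    expect_equal(ct$p_two_tailed, 2 * stats::pt(-abs(tstat), 7),
                 tolerance = 1e-12)
  }
  y <- 3 * (1:9) + 2
  ct <- pearson_corr_test(1:9, y)
  expect_equal(ct$r_squared, 1)
  expect_lt(ct$p_two_tailed, 1e-12)
  expect_error(pearson_corr_test(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_corr_test(1:2, 1:2), "at least 3")
})

test_that("published summary columns reproduce their correlations with age", {
  tab <- bowhead_cycle_summary()
  base <- pearson_corr_test(tab$est_age_yr, tab$baseline_t_ng_g)
  expect_equal(round(base$r_squared, 4), 0.8680)
  med <- pearson_corr_test(tab$est_age_yr, tab$median_t_ng_g)
  expect_equal(round(med$r_squared, 4), 0.5274)
})

test_that("observation tables are validated", {
  obs <- make_study_shape_obs(77)
  obs$response[1] <- NA
  expect_error(fit_lmm(obs, "null"), "non-finite")
  expect_error(fit_lmm(data.frame(whale_id = "a", age_yr = 1, response = 1),
                       "null"), "at least 2 whales")
})
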