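test_that("autocorrelation matches a double-loop oracle and its invariants", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(60 + 10 * rep)
    a <- autocorrelation(x, 20)
    expect_equal(a$acf[1], 1)
    expect_equal(a$acf, oracle_acf(x, 20), tolerance = 1e-10)
    expect_equal(a$significance_bound, 1.96 / sqrt(length(x)))
  }
  s <- sin(2 * pi * (0:99) / 8)
  a <- autocorrelation(s, 20)
  # local maximum near 1 at the 8-sample period
  expect_gt(a$acf[9], a$acf[8])
  expect_gt(a$acf[9], a$acf[10])
  expect_gt(a$acf[9], 0.9)
  expect_error(autocorrelation(rep(2, 30), 5), "zero variance")
})

test_that("Levinson-Durbin equals the direct Yule-Walker solve", {
  set.seed(21)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.6, -0.3)), 300))
  for (p in 1:5) {
    fit <- fit_ar_aic(x, max_order = p)
    if (fit$order == p) {
      expect_equal(fit$coefficients, oracle_yule_walker(x, p),
                   tolerance = 1e-8)
    }
  }
  # independent cross-check against the reference Yule-Walker fitter
  ref <- stats::ar.yw(x, aic = FALSE, order.max = 5, demean = TRUE)
  fit5 <- fit_ar_aic(x, max_order = 5)
  full <- oracle_yule_walker(x, 5)
  expect_equal(full, as.numeric(ref$ar), tolerance = 1e-8)
})

test_that("innovation variance is non-increasing in model order", {
  set.seed(22)
  x <- as.numeric(stats::arima.sim(list(ar = 0.7), 200))
  fit <- fit_ar_aic(x, max_order = 15)
  expect_true(all(diff(fit$innovation_variances) <= 1e-12))
})

test_that("AR order selection behaves on known processes", {
  set.seed(23)
  # white noise: small order selected in most replicates
  small <- vapply(1:50, function(i) {
    fit_ar_aic(rnorm(500), max_order = 20)$order
  }, numeric(1))
  expect_gte(mean(small <= 2), 0.9)
  # peaky AR(2): coefficients recovered at the true order
  hits <- vapply(1:20, function(i) {
    x <- as.numeric(stats::arima.sim(list(ar = c(1.5, -0.9)), 500))
    sel <- fit_ar_aic(x, max_order = 20)$order
    fit2 <- fit_ar_aic(x, max_order = 2)
    sel >= 2 && all(abs(fit2$coefficients - c(1.5, -0.9)) < 0.1)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(fit_ar_aic(rep(1, 50)), "zero variance")
})

test_that("AR spectra follow closed forms", {
  f <- seq(0.01, 0.5, by = 0.01)
  expect_equal(ar_spectrum(numeric(0), 2.5, f), rep(2.5, length(f)))
  s1 <- ar_spectrum(0.9, 1, f)
  expect_true(all(diff(s1) < 0))
  # complex-pole AR(2): spectral peak at the pole angle
  r <- 0.95; omega <- 2 * pi * 0.125
  a <- c(2 * r * cos(omega), -r^2)
  fg <- seq(0.01, 0.49, length.out = 2000)
  s2 <- ar_spectrum(a, 1, fg)
  expect_lt(abs(fg[which.max(s2)] - 0.125), diff(fg[1:2]) * 1.5)
  expect_error(ar_spectrum(0.5, 1, c(0, 0.2)), "0, 0.5")
})

test_that("fitted AR spectrum integrates to the process variance", {
  set.seed(24)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.2)), 2000))
  fit <- fit_ar_aic(x, max_order = 10)
  fr <- seq(1e-6, 0.5, length.out = 40001)
  S <- ar_spectrum(fit$coefficients, fit$innovation_variance, fr)
  integral <- 2 * sum((S[-1] + S[-length(S)]) / 2 * diff(fr))
  expect_equal(integral, mean((x - mean(x))^2), tolerance = 0.02)
})

test_that("period estimation applies the stated frequency-to-period arithmetic", {
  # pure 8-sample cosine at 2-cm spacing: peak frequency 0.125 -> 16 cm
  x <- cos(2 * pi * (0:160) / 8)
  sp <- estimate_period(x, spacing_cm = 2)
  expect_equal(sp$period_cm, 2 / sp$peak_frequency)
  step_cm <- 2 * diff(sp$spectrum$frequency[1:2]) / sp$peak_frequency^2
  expect_lt(abs(sp$period_cm - 16), step_cm)
  # scale invariance
  sp2 <- estimate_period(37.5 * x, spacing_cm = 2)
  expect_equal(sp2$period_cm, sp$period_cm)
  expect_equal(sp2$ar_order, sp$ar_order)
})

test_that("an aperiodic series yields a no-dominant-cycle error", {
  set.seed(25)
  expect_error(estimate_period(rnorm(100), spacing_cm = 2, max_order = 0),
               "no dominant cycle")
})

test_that("windowed estimation ignores an acyclic prefix", {
  s <- synthetic_whale_spec(plate_length_cm = 240, period_start_cm = 16,
                            period_decline_cm_per_cycle = 0,
                            juvenile_acyclic_cm = 80,
                            noise_sd_t = 0.2, noise_sd_n = 0, seed = 8)
  g <- generate_profile(s)
  sp <- estimate_period(g$profile, window = c(0, 160))
  expect_equal(sp$period_cm, 16, tolerance = 0.2)
})
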