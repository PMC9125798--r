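test_that("the four-neighbour rule fires exactly where it should", {
  expect_equal(detect_peaks(1:20)$n, 0L)
  pk <- detect_peaks(c(0, 0, 1, 0, 0))
  expect_equal(pk$indices, 3L)
  expect_equal(pk$positions_cm, 4)
  # plateaus of equal values yield no peak (strict inequality)
  expect_equal(detect_peaks(c(0, 1, 2, 2, 2, 1, 0))$n, 0L)
  # edge samples can never be peaks
  expect_equal(detect_peaks(c(9, 1, 1, 1, 8))$n, 0L)
})

test_that("the detector equals an exhaustive window-checking oracle", {
  set.seed(51)
  for (rep in 1:200) {
    x <- rnorm(30)
    expect_identical(detect_peaks(x)$indices, oracle_peaks(x))
  }
})

test_that("detection is invariant under strictly monotone transforms", {
  set.seed(52)
  x <- abs(rnorm(60)) + 0.1
  expect_identical(detect_peaks(exp(x))$indices, detect_peaks(x)$indices)
  expect_identical(detect_peaks(log(x))$indices, detect_peaks(x)$indices)
  expect_identical(detect_peaks(10 + 3 * x)$indices, detect_peaks(x)$indices)
})

test_that("prominence filtering drops noise bumps but keeps pulses", {
  # two 5-high pulses with a 0.3-high noise bump on the baseline between
  x <- c(0, 0, 5, 0, 0, 0.3, 0, 0, 5, 0, 0)
  expect_equal(detect_peaks(x)$indices, c(3L, 6L, 9L))
  expect_equal(detect_peaks(x, min_prominence = 1)$indices, c(3L, 9L))
})

test_that("cycle segmentation computes minima, periods, ratios, baseline", {
  x <- c(0, 0, 4, 2, 1, 3, 2, 0, 0)
  pk <- detect_peaks(x)
  expect_equal(pk$indices, c(3L, 6L))
  cyc <- segment_cycles(x, pk, spacing_cm = 2)
  expect_equal(cyc$n_cycles, 1L)
  expect_equal(cyc$cycles$min_value, 1)
  expect_equal(cyc$cycles$ratio, 4)
  expect_equal(cyc$cycles$period_cm, 6)
  expect_equal(cyc$baseline, 1)

  # two cycles with troughs 1 and 2 -> baseline 1.5
  saw <- c(0, 0, 3, 2, 1, 2, 3, 2.5, 2, 2.5, 3, 0, 0)
  pk2 <- detect_peaks(saw)
  expect_equal(pk2$indices, c(3L, 7L, 11L))
  cyc2 <- segment_cycles(saw, pk2, spacing_cm = 2)
  expect_equal(cyc2$n_cycles, 2L)
  expect_equal(cyc2$cycles$min_value, c(1, 2))
  expect_equal(cyc2$baseline, 1.5)

  # tie-break: equal minima -> closest to midpoint, then earlier
  tie <- c(0, 0, 5, 1, 3, 1, 3, 1, 5, 0, 0)
  cyc3 <- segment_cycles(tie, detect_peaks(tie), spacing_cm = 2)
  expect_equal(cyc3$cycles$min_idx, 6L)
})

test_that("fewer than two peaks yields an empty flagged cycle set", {
  x <- c(0, 0, 1, 0, 0)
  cyc <- segment_cycles(x, detect_peaks(x), spacing_cm = 2)
  expect_equal(cyc$n_cycles, 0L)
  expect_false(cyc$baseline_defined)
  expect_true(is.na(cyc$baseline))
})

test_that("cycle periods tile the span between first and last peak", {
  s <- synthetic_whale_spec(plate_length_cm = 200, period_start_cm = 17,
                            noise_sd_t = 0.3, noise_sd_n = 0, seed = 53)
  g <- generate_profile(s)
  pk <- detect_peaks(g$profile, min_prominence = 1)
  cyc <- segment_cycles(g$profile, pk)
  expect_equal(sum(cyc$cycles$period_cm),
               diff(range(pk$positions_cm)))
})

test_that("cycle ages are back-calculated from the terminal age", {
  expect_equal(assign_cycle_ages(5, 14), 9:13)
  expect_equal(assign_cycle_ages(11, 18)[1], 7)
  expect_equal(assign_cycle_ages(12, 21)[1], 9)
  expect_equal(assign_cycle_ages(15, 24)[1], 9)
  expect_equal(assign_cycle_ages(1, 10), 9)
  expect_error(assign_cycle_ages(12, 12), "terminal age")
  expect_error(assign_cycle_ages(0, 10), "n_cycles")
})

test_that("plate summaries follow their closed forms", {
  x <- rep(2.5, 20)
  sm <- summarize_plate(x, detect_peaks(x), segment_cycles(x, detect_peaks(x)))
  expect_equal(sm$mean_t, 2.5)
  expect_equal(sm$median_t, 2.5)
  expect_equal(sm$max_t, sm$min_t)
  expect_equal(sm$n_peaks, 0L)
  expect_true(is.na(sm$cv_peaks))

  # peaks {4, 2}: %CV with the n-1 SD is 47.14
  y <- c(0, 0, 4, 1, 0.5, 2, 0, 0)
  pk <- detect_peaks(y)
  expect_equal(sort(pk$heights), c(2, 4))
  sm2 <- summarize_plate(y, pk, segment_cycles(y, pk))
  expect_equal(sm2$cv_peaks, 100 * stats::sd(c(4, 2)) / 3, tolerance = 1e-12)
  expect_equal(round(sm2$cv_peaks, 2), 47.14)

  # footnote-literal ratio mode: mean peak / baseline, no SD
  sm3 <- summarize_plate(y, pk, segment_cycles(y, pk), ratio_mode = "plate")
  expect_equal(sm3$mean_ratio, 3 / 0.5)
  expect_true(is.na(sm3$sd_ratio))
})
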