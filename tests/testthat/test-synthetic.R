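test_that("noiseless constant-period construction places pulses exactly", {
  s <- synthetic_whale_spec(plate_length_cm = 160, period_start_cm = 16,
                            period_decline_cm_per_cycle = 0,
                            noise_sd_t = 0, noise_sd_n = 0, seed = 1)
  g <- generate_profile(s)
  expect_length(g$truth$peak_positions_cm, 10L)
  expect_equal(diff(g$truth$peak_positions_cm), rep(-16, 9))
  expect_equal(g$truth$periods_cm, rep(16, 10))
  # detector recovers every true pulse to within one sample
  pk <- detect_peaks(g$profile)
  expect_equal(pk$n, 10L)
  expect_true(all(abs(sort(pk$positions_cm) -
                        sort(g$truth$peak_positions_cm)) <= s$spacing_cm))
})

test_that("generation is deterministic for a fixed seed", {
  s <- synthetic_whale_spec(seed = 99)
  g1 <- generate_profile(s)
  g2 <- generate_profile(s)
  expect_identical(g1, g2)
  g3 <- generate_profile(synthetic_whale_spec(seed = 100))
  expect_false(identical(g1$profile$testosterone, g3$profile$testosterone))
})

test_that("isotope crest sits phase_lead/12 of a period recentward of the T pulse", {
  s <- synthetic_whale_spec(plate_length_cm = 160, period_start_cm = 16,
                            period_decline_cm_per_cycle = 0,
                            phase_lead_months = 3,
                            noise_sd_t = 0, noise_sd_n = 0, seed = 1)
  g <- generate_profile(s)
  x <- g$profile$positions
  nser <- g$profile$d15n
  crest_idx <- which(diff(sign(diff(nser))) == -2) + 1L
  crests <- x[crest_idx]
  for (pc in g$truth$peak_positions_cm[-1]) {  # skip the edge pulse
    nearest <- crests[which.min(abs(crests - (pc - 4)))]
    expect_equal(nearest, pc - 4, tolerance = 1e-8)  # 3/12 * 16 cm, recentward
  }
})

test_that("truth ages follow the terminal-age convention exactly", {
  s <- synthetic_whale_spec(plate_length_cm = 160, period_start_cm = 16,
                            period_decline_cm_per_cycle = 0,
                            terminal_age_yr = 25, noise_sd_t = 0, seed = 2)
  g <- generate_profile(s)
  n <- length(g$truth$peak_positions_cm)
  expect_equal(g$truth$ages_yr, assign_cycle_ages(n, 25))
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(synthetic_whale_spec(period_start_cm = 3), "twice the spacing")
  expect_error(synthetic_whale_spec(peak_width_fraction = 0.6), "0, 0.5")
  expect_error(synthetic_whale_spec(noise_sd_t = -1), "noise")
  expect_error(synthetic_whale_spec(juvenile_acyclic_cm = 999),
               "juvenile_acyclic_cm")
})

test_that("cohort generation is reproducible and rejects duplicate ids", {
  specs <- study_cohort_specs()
  c1 <- generate_cohort(specs, seed = 5)
  c2 <- generate_cohort(specs, seed = 5)
  expect_identical(c1, c2)
  c3 <- generate_cohort(specs, seed = 6)
  expect_false(identical(c1$profiles, c3$profiles))
  # truth structure is seed-independent
  expect_identical(lapply(c1$truths, `[[`, "peak_positions_cm"),
                   lapply(c3$truths, `[[`, "peak_positions_cm"))
  # plate lengths match the specs
  for (i in seq_along(specs)) {
    expect_equal(max(c1$profiles[[specs[[i]]$whale_id]]$positions),
                 specs[[i]]$plate_length_cm, tolerance = 2)
  }
  dup <- c(specs[1], specs[1])
  expect_error(generate_cohort(dup, seed = 1), "duplicate whale ids")
})

test_that("juvenile acyclic segment carries baseline-only T", {
  s <- synthetic_whale_spec(plate_length_cm = 160, period_start_cm = 16,
                            period_decline_cm_per_cycle = 0,
                            juvenile_acyclic_cm = 60, baseline_start = 1,
                            noise_sd_t = 0, noise_sd_n = 0, seed = 3)
  g <- generate_profile(s)
  old <- g$profile$positions > 100 + 8  # beyond the first pulse's reach
  expect_true(all(abs(g$profile$testosterone[old] - 1) < 0.05))
  expect_true(all(g$truth$peak_positions_cm <= 100))
  # isotope cycling continues through the acyclic segment
  expect_gt(stats::sd(g$profile$d15n[old]), 0.5)
})

test_that("senescence trends propagate to peak metrics", {
  s <- synthetic_whale_spec(plate_length_cm = 240, period_start_cm = 16,
                            period_decline_cm_per_cycle = 0,
                            peak_amplitude_start = 10,
                            peak_amplitude_trend_per_cycle = -0.5,
                            baseline_start = 1,
                            baseline_trend_per_cycle = 0.05,
                            noise_sd_t = 0, noise_sd_n = 0, seed = 4)
  g <- generate_profile(s)
  pk <- detect_peaks(g$profile)
  cyc <- segment_cycles(g$profile, pk)
  # rows are ordered most recent first; senescence means the recent end has
  # lower peaks over a higher baseline
  expect_true(all(diff(cyc$cycles$peak_height) > 0))
  expect_true(all(diff(cyc$cycles$min_value) < 0))
})
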