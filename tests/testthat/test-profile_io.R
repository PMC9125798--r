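test_that("profile construction enforces the data-model invariants", {
  p <- hormone_profile("w", seq(0, 18, by = 2), rep(1, 10))
  expect_s3_class(p, "hormone_profile")
  expect_equal(p$spacing_cm, 2)
  expect_equal(n_samples(p), 10L)

  expect_error(hormone_profile("w", c(0, 2, 5, 7, 9), rep(1, 5)),
               "non-uniform spacing")
  expect_error(hormone_profile("w", c(0, 2, 4, 4, 6), rep(1, 5)),
               "strictly increasing")
  expect_error(hormone_profile("w", seq(0, 8, 2), c(1, 1, -0.1, 1, 1)),
               "negative testosterone")
  expect_error(hormone_profile("w", seq(0, 6, 2), rep(1, 4)),
               "at least 5 samples")
  expect_error(hormone_profile("w", seq(0, 8, 2), rep(1, 5),
                               d15n = c(1, 2, NA, 4, 5)),
               "missing cells")
})

test_that("profiles round-trip through CSV to full precision", {
  specs <- lapply(1:3, function(i) {
    synthetic_whale_spec(whale_id = paste0("w", i),
                         plate_length_cm = 120 + 20 * i,
                         period_start_cm = 15 + i)
  })
  cohort <- generate_cohort(specs, seed = 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(cohort$profiles, path)
  back <- read_profiles(path)
  expect_identical(names(back), names(cohort$profiles))
  for (id in names(back)) {
    orig <- cohort$profiles[[id]]
    attr(orig$testosterone, "n_clipped_t") <- NULL
    expect_identical(back[[id]], orig)
  }
  # byte stability for fixed input
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_profiles(cohort$profiles, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("empty collections and malformed files are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(list(), path)
  expect_identical(readLines(path),
                   "whale_id,position_cm,testosterone_ng_g,d15n_permil,gumline_cut")
  expect_length(read_profiles(path), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("whale_id,position_cm", "w,0"), bad)
  expect_error(read_profiles(bad), "testosterone_ng_g")
  expect_error(read_profiles(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("study metadata fixture reads with expected structure", {
  meta <- bowhead_metadata()
  expect_equal(nrow(meta), 9L)
  expect_true(is.na(meta$aar_age_yr[meta$whale_id == "whale7"]))
  expect_equal(sum(is.na(meta$aar_age_yr)), 3L)
  expect_equal(meta$gumline_cut, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                                   FALSE, FALSE, FALSE))
  # round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_equal(as.data.frame(back), as.data.frame(meta))
})

test_that("metadata validation rejects non-positive lengths and ages", {
  meta <- bowhead_metadata()
  meta$body_length_m[1] <- 0
  expect_error(validate_metadata(meta), "body_length_m")
  meta <- bowhead_metadata()
  meta$aar_age_yr[1] <- -3
  expect_error(validate_metadata(meta), "aar_age_yr")
})

test_that("analysis windows subset profiles and validate bounds", {
  p <- hormone_profile("w", seq(0, 40, 2), seq(1, 21))
  w <- apply_window(p, 10, 30)
  expect_equal(range(w$positions), c(10, 30))
  expect_equal(w$spacing_cm, 2)
  expect_error(apply_window(p, 30, 10), "invalid analysis window")
  expect_error(apply_window(p, 0, 99), "invalid analysis window")
})
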