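# Per-cycle observation table with the study cohort's data shape: 9 whales
# whose peak counts sum to 126, each peak aged by the terminal-age
# convention.
study_shape_counts <- function() c(5, 11, 12, 12, 15, 13, 16, 20, 22)
study_shape_terminal <- function() c(14, 18, 21, 23, 24, 44, 48, 115, 153)

make_study_shape_obs <- function(seed, intercept = 10, slope = -0.163,
                                 slope_sd = 0.2, intercept_sd = 2,
                                 resid_sd = 1.5, center_groups = FALSE) {
  set.seed(seed)
  counts <- study_shape_counts()
  term <- study_shape_terminal()
  out <- do.call(rbind, lapply(seq_along(counts), function(i) {
    ages <- assign_cycle_ages(counts[i], term[i])
    b0 <- intercept + rnorm(1, sd = intercept_sd)
    b1 <- slope + rnorm(1, sd = slope_sd)
    e <- rnorm(counts[i], sd = resid_sd)
    # centring the residuals within whale makes the between-whale variance
    # estimate hit the zero boundary (degenerate limit)
    if (center_groups) e <- e - mean(e)
    data.frame(whale_id = sprintf("w%02d", i), age_yr = ages,
               response = b0 + b1 * ages + e)
  }))
  out
}
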