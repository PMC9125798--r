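#' Metadata for the nine-whale bowhead study cohort
#'
#' Published collection and specimen data for nine male bowhead whales
#' (harvest date, body length, baleen plate length, body-length age
#' estimate, eye-lens AAR age estimate where an eye lens was collected, and
#' whether the plate was cut at the gumline). Whales are numbered in order
#' of best available age; three whales lack AAR ages.
#'
#' @return a `whale_metadata` data frame with 9 rows.
#' @export
bowhead_metadata <- function() {
  read_metadata(system.file("extdata", "bowhead_metadata.csv",
                            package = "baleenT", mustWork = TRUE))
}

#' Published per-whale cycle summary metrics for the bowhead cohort
#'
#' One row per whale: best available terminal age, number of detected T
#' peaks, T and nitrogen-isotope cycle periods (cm), phase offset of T ahead
#' of the isotope crest (months), mean T peak and baseline with SDs,
#' peak/baseline ratio, and whole-plate maximum/minimum/mean/median T
#' (ng/g). These printed summaries are the package's worked-example input
#' for the cross-whale correlation and trend stages; the underlying raw
#' per-position series were not deposited.
#'
#' @return a data frame with 9 rows.
#' @export
bowhead_cycle_summary <- function() {
  utils::read.csv(system.file("extdata", "bowhead_cycle_summary.csv",
                              package = "baleenT", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Synthetic cohort specs shaped on the bowhead study
#'
#' Builds nine [synthetic_whale_spec]s whose plate lengths, cycle periods,
#' peak counts, amplitudes, baselines and phase leads are shaped on the
#' published per-whale summaries: periods spanning 14.5-21.5 cm and
#' shrinking slightly cycle-to-cycle, 5-22 peaks per plate, a juvenile
#' acyclic prefix for the youngest whale (whose T cycles occupy only the
#' recent half of the plate, with no T/isotope offset), and senescence-like
#' amplitude decline with baseline rise for the two oldest whales.
#'
#' @param noise_frac Gaussian noise SD as a fraction of each whale's pulse
#'   amplitude (default 0.10).
#' @return list of 9 [synthetic_whale_spec] objects (unseeded; pass a master
#'   seed to [generate_cohort()]).
#' @export
study_cohort_specs <- function(noise_frac = 0.10) {
  tab <- bowhead_cycle_summary()
  meta <- bowhead_metadata()
  plate <- meta$baleen_length_cm[match(tab$whale_id, meta$whale_id)]
  # within-whale peak decline: shallow in younger whales, an order of
  # magnitude steeper (with rising baseline) in the two oldest — the
  # published per-whale slope structure
  amp_trend <- ifelse(tab$est_age_yr > 100, -0.30, -0.02)
  base_trend <- ifelse(tab$est_age_yr > 100, 0.04, 0)
  amp_start <- (tab$mean_t_peak_ng_g - tab$baseline_t_ng_g) -
    amp_trend * tab$n_t_peaks / 2
  juvenile <- ifelse(tab$whale_id == "whale1", plate / 2, 0)
  lapply(seq_len(nrow(tab)), function(i) {
    synthetic_whale_spec(
      whale_id = tab$whale_id[i],
      plate_length_cm = plate[i],
      spacing_cm = 2,
      period_start_cm = tab$t_period_cm[i] + 0.025 * tab$n_t_peaks[i],
      period_decline_cm_per_cycle = 0.05,
      peak_amplitude_start = amp_start[i],
      peak_amplitude_trend_per_cycle = amp_trend[i],
      baseline_start = tab$baseline_t_ng_g[i],
      baseline_trend_per_cycle = base_trend[i],
      peak_width_fraction = 0.2,
      phase_lead_months = tab$phase_offset_months[i],
      n_mean_permil = 14, n_amplitude_permil = 1,
      noise_sd_t = noise_frac * amp_start[i],
      noise_sd_n = 0.2,
      juvenile_acyclic_cm = juvenile[i],
      terminal_age_yr = tab$est_age_yr[i])
  })
}

#' Default simulate-then-analyse scenario for the study-shaped cohort
#'
#' Simulates the [study_cohort_specs()] cohort under a master seed and
#' returns a ready [run_analysis()] config for it: the youngest whale's
#' acyclic half is excluded by an analysis window, and peak detection uses a
#' per-whale prominence margin of a quarter of the whale's pulse amplitude.
#' The margin is needed because independent measurement noise turns roughly
#' one in five flat baseline samples into a four-neighbour local maximum;
#' real plates are smoother than white noise, so the pure rule needs no
#' margin there but the simulation does.
#'
#' @param seed master seed for [generate_cohort()].
#' @param noise_frac passed to [study_cohort_specs()].
#' @return list with `config` (for [run_analysis()]), `truths`, and `specs`.
#' @export
study_scenario <- function(seed, noise_frac = 0.10) {
  specs <- study_cohort_specs(noise_frac = noise_frac)
  cohort <- generate_cohort(specs, seed = seed)
  prom <- lapply(specs, function(s) 0.25 * s$peak_amplitude_start)
  names(prom) <- vapply(specs, `[[`, character(1), "whale_id")
  meta <- bowhead_metadata()
  w1 <- specs[[which(names(prom) == "whale1")]]
  config <- list(
    profiles = cohort$profiles,
    metadata = meta,
    windows = list(whale1 = c(0, w1$plate_length_cm -
                                w1$juvenile_acyclic_cm)),
    min_prominence = prom,
    seed = seed)
  list(config = config, truths = cohort$truths, specs = specs)
}
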