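#' Specify a synthetic baleen whale profile
#'
#' Describes one simulated whale for the ground-truth generator. The signal
#' model mirrors the structure annual testosterone cycling leaves in baleen:
#' narrow T pulses repeating once per cycle over a low baseline, a nitrogen
#' isotope sinusoid of the same local period that the T pulse leads in time,
#' a cycle period that shrinks toward the recently grown end (baleen growth
#' slows with age), an optional acyclic juvenile segment at the old end of
#' the plate, and optional per-cycle trends in pulse amplitude and baseline
#' (senescence-like decline of peaks with rising baseline).
#'
#' Cycles are indexed from the oldest end of the plate: cycle 1 has period
#' `period_start_cm` and each younger cycle is shorter by
#' `period_decline_cm_per_cycle`.
#'
#' @param whale_id character id.
#' @param plate_length_cm total plate length in cm.
#' @param spacing_cm sampling interval in cm (default 2, the drilling
#'   protocol's spacing).
#' @param period_start_cm period of the oldest cycle in cm.
#' @param period_decline_cm_per_cycle per-cycle shrinkage of the period (cm),
#'   `>= 0`.
#' @param peak_amplitude_start pulse amplitude of the oldest cycle (ng/g).
#' @param peak_amplitude_trend_per_cycle additive per-cycle amplitude change
#'   (ng/g); negative values emulate senescent peak decline.
#' @param baseline_start baseline T of the oldest cycle (ng/g).
#' @param baseline_trend_per_cycle additive per-cycle baseline change (ng/g).
#' @param peak_width_fraction full width at half maximum of the T pulse, as a
#'   fraction of the cycle, in (0, 0.5).
#' @param phase_lead_months months by which the T pulse precedes the isotope
#'   crest within a 12-month cycle.
#' @param n_mean_permil,n_amplitude_permil mean and amplitude of the isotope
#'   sinusoid (permil).
#' @param noise_sd_t,noise_sd_n Gaussian noise standard deviations for the T
#'   and isotope series.
#' @param juvenile_acyclic_cm length of the oldest plate segment carrying
#'   baseline-only T (no pulses), `>= 0`.
#' @param terminal_age_yr the whale's age at death, used for truth ages.
#' @param seed integer RNG seed for this whale, or `NULL`.
#' @return an object of class `synthetic_whale_spec` (a validated list).
#' @export
synthetic_whale_spec <- function(whale_id = "synthetic",
                                 plate_length_cm = 240,
                                 spacing_cm = 2,
                                 period_start_cm = 18,
                                 period_decline_cm_per_cycle = 0.05,
                                 peak_amplitude_start = 8,
                                 peak_amplitude_trend_per_cycle = 0,
                                 baseline_start = 1,
                                 baseline_trend_per_cycle = 0,
                                 peak_width_fraction = 0.2,
                                 phase_lead_months = 3,
                                 n_mean_permil = 14,
                                 n_amplitude_permil = 1,
                                 noise_sd_t = 0.4,
                                 noise_sd_n = 0.25,
                                 juvenile_acyclic_cm = 0,
                                 terminal_age_yr = 40,
                                 seed = NULL) {
  spec <- list(whale_id = whale_id, plate_length_cm = plate_length_cm,
               spacing_cm = spacing_cm, period_start_cm = period_start_cm,
               period_decline_cm_per_cycle = period_decline_cm_per_cycle,
               peak_amplitude_start = peak_amplitude_start,
               peak_amplitude_trend_per_cycle = peak_amplitude_trend_per_cycle,
               baseline_start = baseline_start,
               baseline_trend_per_cycle = baseline_trend_per_cycle,
               peak_width_fraction = peak_width_fraction,
               phase_lead_months = phase_lead_months,
               n_mean_permil = n_mean_permil,
               n_amplitude_permil = n_amplitude_permil,
               noise_sd_t = noise_sd_t, noise_sd_n = noise_sd_n,
               juvenile_acyclic_cm = juvenile_acyclic_cm,
               terminal_age_yr = terminal_age_yr, seed = seed)
  validate_spec(spec)
  structure(spec, class = "synthetic_whale_spec")
}

validate_spec <- function(s) {
  chk <- function(ok, msg) if (!ok) stop("synthetic spec '", s$whale_id,
                                         "': ", msg, call. = FALSE)
  chk(is.character(s$whale_id) && nzchar(s$whale_id), "whale_id required")
  chk(s$plate_length_cm > 0 && s$spacing_cm > 0, "plate and spacing must be > 0")
  chk(s$period_start_cm > 2 * s$spacing_cm,
      "period_start_cm must exceed twice the spacing")
  chk(s$period_decline_cm_per_cycle >= 0, "period decline must be >= 0")
  chk(s$peak_amplitude_start >= 0 && s$baseline_start >= 0 &&
        s$n_amplitude_permil >= 0, "amplitudes and baselines must be >= 0")
  chk(s$peak_width_fraction > 0 && s$peak_width_fraction < 0.5,
      "peak_width_fraction must lie in (0, 0.5)")
  chk(s$noise_sd_t >= 0 && s$noise_sd_n >= 0, "noise sds must be >= 0")
  chk(s$juvenile_acyclic_cm >= 0 && s$juvenile_acyclic_cm < s$plate_length_cm,
      "juvenile_acyclic_cm must be in [0, plate length)")
  chk(s$terminal_age_yr > 0, "terminal_age_yr must be > 0")
  invisible(s)
}

# Cycle layout: boundaries walk from the old (cyclic) end of the plate toward
# position 0, each cycle c (1 = oldest) spanning period_start - (c-1)*decline
# cm. Returns old-end boundary, period and pulse-centre position per cycle.
.cycle_layout <- function(spec) {
  x_old <- spec$plate_length_cm - spec$juvenile_acyclic_cm
  bounds <- x_old
  periods <- numeric(0)
  c <- 1L
  repeat {
    p <- spec$period_start_cm - (c - 1L) * spec$period_decline_cm_per_cycle
    if (p <= 2 * spec$spacing_cm) break  # period collapsed; stop laying cycles
    lo <- bounds[c] - p
    periods <- c(periods, p)
    bounds <- c(bounds, lo)
    if (lo <= 0) break
    c <- c + 1L
  }
  list(hi = bounds[-length(bounds)], lo = bounds[-1L], periods = periods,
       centers = bounds[-length(bounds)] - periods / 2)
}

#' Generate a synthetic profile with known ground truth
#'
#' Noise-free construction: within cycle `c` with old-end boundary `b` and
#' period `p`, the cycle fraction is `frac = (b - x)/p` and
#' `T(x) = baseline_c + amplitude_c * g(frac)` where `g` is a unit-height
#' circular Gaussian pulse centred at `frac = 0.5` with full width at half
#' maximum `peak_width_fraction`. The isotope series is
#' `n_mean + n_amplitude * cos(psi - 2*pi*phase_lead_months/12)` with
#' `psi = 2*pi*(c - 1 + frac) - pi`, so its crest sits
#' `phase_lead_months/12 * p` cm toward the recent end of the T pulse centre
#' (later in time: T leads). Gaussian noise is then added and T clipped at 0
#' (clip count in attribute `n_clipped_t` of the profile's testosterone).
#'
#' @param spec a [synthetic_whale_spec].
#' @return a list with elements `profile` (a [hormone_profile]) and `truth`,
#'   the generating record: true pulse positions (oldest first), per-cycle
#'   periods, baselines and amplitudes, phase lead, and per-cycle ages under
#'   the terminal-age convention of [assign_cycle_ages()].
#' @export
generate_profile <- function(spec) {
  spec <- validate_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  x <- seq(0, spec$plate_length_cm, by = spec$spacing_cm)
  lay <- .cycle_layout(spec)
  ncyc <- length(lay$periods)
  amp <- pmax(0, spec$peak_amplitude_start +
                (seq_len(ncyc) - 1L) * spec$peak_amplitude_trend_per_cycle)
  base <- pmax(0, spec$baseline_start +
                 (seq_len(ncyc) - 1L) * spec$baseline_trend_per_cycle)
  sigma_phi <- spec$peak_width_fraction * 2 * pi / (2 * sqrt(2 * log(2)))

  t_clean <- numeric(length(x))
  psi <- numeric(length(x))
  x_old <- spec$plate_length_cm - spec$juvenile_acyclic_cm
  for (i in seq_along(x)) {
    xi <- x[i]
    if (xi > x_old) {  # juvenile acyclic segment (oldest baleen)
      t_clean[i] <- spec$baseline_start
      # isotope cycling continues through the juvenile segment at the oldest
      # cycle's period
      psi[i] <- -pi - 2 * pi * (xi - x_old) / lay$periods[1L]
      next
    }
    c <- which(xi > lay$lo - 1e-12 & xi <= lay$hi + 1e-12)[1L]
    if (is.na(c)) c <- ncyc  # below the last laid boundary: extend last cycle
    frac <- (lay$hi[c] - xi) / lay$periods[c]
    dphi <- 2 * pi * (frac - 0.5)
    t_clean[i] <- base[c] + amp[c] * exp(-dphi^2 / (2 * sigma_phi^2))
    psi[i] <- 2 * pi * (c - 1 + frac) - pi
  }
  n_clean <- spec$n_mean_permil + spec$n_amplitude_permil *
    cos(psi - 2 * pi * spec$phase_lead_months / 12)

  t_noisy <- t_clean + stats::rnorm(length(x), sd = spec$noise_sd_t)
  n_clipped <- sum(t_noisy < 0)
  t_noisy <- pmax(0, t_noisy)
  n_noisy <- n_clean + stats::rnorm(length(x), sd = spec$noise_sd_n)

  profile <- hormone_profile(spec$whale_id, x, t_noisy, d15n = n_noisy)
  attr(profile$testosterone, "n_clipped_t") <- n_clipped

  on_plate <- lay$centers >= 0 & lay$centers <= spec$plate_length_cm
  peak_pos <- lay$centers[on_plate]
  n_true <- length(peak_pos)
  truth <- list(
    whale_id = spec$whale_id,
    peak_positions_cm = peak_pos,            # oldest pulse first
    periods_cm = lay$periods[on_plate],
    baselines = base[on_plate],
    amplitudes = amp[on_plate],
    phase_lead_months = spec$phase_lead_months,
    terminal_age_yr = spec$terminal_age_yr,
    ages_yr = if (n_true >= 1 && spec$terminal_age_yr > n_true) {
      assign_cycle_ages(n_true, spec$terminal_age_yr)
    } else NULL)
  list(profile = profile, truth = truth)
}

#' Generate a cohort of synthetic whales
#'
#' One [generate_profile()] call per spec. When `seed` is given, each whale
#' receives an independent sub-seed derived deterministically from it (so the
#' cohort is reproducible and whales are independent); otherwise the specs'
#' own seeds are used unchanged.
#'
#' @param specs list of [synthetic_whale_spec] objects with distinct ids.
#' @param seed optional master integer seed.
#' @return list with named lists `profiles` and `truths`.
#' @export
generate_cohort <- function(specs, seed = NULL) {
  ids <- vapply(specs, function(s) s$whale_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate whale ids in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    subs <- sample.int(.Machine$integer.max - 1L, length(specs))
    for (i in seq_along(specs)) specs[[i]]$seed <- subs[i]
  }
  out <- lapply(specs, generate_profile)
  profiles <- lapply(out, `[[`, "profile")
  truths <- lapply(out, `[[`, "truth")
  names(profiles) <- ids
  names(truths) <- ids
  list(profiles = profiles, truths = truths)
}
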