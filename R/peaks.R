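#' Detect T peaks by the four-neighbour rule
#'
#' A T peak is a single sample strictly greater than all four neighbouring
#' samples (the two prior and the two subsequent). The first two and last
#' two samples of a series can therefore never be peaks, and plateaus of
#' equal values yield none. The rule operates on raw concentrations and is
#' invariant under strictly monotone transforms of the values.
#'
#' @param x a [hormone_profile] or a numeric series (length >= 5).
#' @param min_prominence optional non-negative prominence threshold: after
#'   the four-neighbour rule, each candidate's prominence is its height
#'   minus the higher of the two trough minima separating it from the
#'   adjacent candidates (or the series ends), and candidates below the
#'   threshold are dropped. Useful when independent measurement noise
#'   produces spurious local maxima on flat baseline stretches. The default
#'   0 is the pure rule.
#' @param spacing_cm spacing used to report positions when `x` is a bare
#'   series (positions start at 0).
#' @return object of class `peak_set`: `indices` (1-based), `positions_cm`,
#'   `heights`, `n`.
#' @export
detect_peaks <- function(x, min_prominence = 0, spacing_cm = 2) {
  if (inherits(x, "hormone_profile")) {
    series <- x$testosterone
    positions <- x$positions
  } else {
    series <- as.numeric(x)
    positions <- (seq_along(series) - 1L) * spacing_cm
  }
  n <- length(series)
  if (n < 5L) stop("need at least 5 samples to apply the peak rule",
                   call. = FALSE)
  stopifnot(min_prominence >= 0)
  idx <- integer(0)
  for (i in 3:(n - 2L)) {
    nb <- series[c(i - 2L, i - 1L, i + 1L, i + 2L)]
    if (series[i] > max(nb)) idx <- c(idx, i)
  }
  if (min_prominence > 0 && length(idx)) {
    bounds <- c(1L, idx, n)
    keep <- vapply(seq_along(idx), function(j) {
      i <- idx[j]
      lmin <- min(series[bounds[j]:i])
      rmin <- min(series[i:bounds[j + 2L]])
      (series[i] - max(lmin, rmin)) >= min_prominence
    }, logical(1))
    idx <- idx[keep]
  }
  structure(list(indices = idx, positions_cm = positions[idx],
                 heights = series[idx], n = length(idx)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("Peak set: ", x$n, " T peaks\n", sep = "")
  if (x$n) {
    cat("  positions [cm]:", paste(round(x$positions_cm, 1), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Segment complete cycles between consecutive peaks
#'
#' Each pair of consecutive peaks bounds one complete cycle. The cycle
#' minimum is the smallest value strictly between the two peaks (ties broken
#' toward the sample closest to the cycle midpoint, then the earlier one);
#' the cycle period is the distance between the bounding peaks; the
#' peak/minimum ratio divides the leading (lower-index, more recently grown)
#' bounding peak by the cycle's own minimum. The baseline is the mean of the
#' cycle minima — partial cycles at either end of the plate contribute
#' nothing.
#'
#' @param x a [hormone_profile] or a numeric series.
#' @param peaks a [peak_set] from [detect_peaks()].
#' @param spacing_cm spacing for a bare series.
#' @return object of class `cycle_set`: a data frame `cycles` with one row
#'   per complete cycle (columns `peak_lo_idx`, `peak_hi_idx`,
#'   `peak_height`, `min_value`, `min_idx`, `period_cm`, `ratio`, and
#'   `age_yr` filled with `NA` until ages are assigned), plus `baseline`
#'   (`NA` with a flag when fewer than 2 peaks exist) and `n_cycles`.
#'   Cycles are ordered by position: row 1 is the most recently grown cycle.
#' @export
segment_cycles <- function(x, peaks, spacing_cm = 2) {
  if (inherits(x, "hormone_profile")) {
    series <- x$testosterone
    spacing_cm <- x$spacing_cm
  } else {
    series <- as.numeric(x)
  }
  stopifnot(inherits(peaks, "peak_set"))
  idx <- peaks$indices
  if (length(idx) < 2L) {
    return(structure(list(
      cycles = data.frame(peak_lo_idx = integer(0), peak_hi_idx = integer(0),
                          peak_height = numeric(0), min_value = numeric(0),
                          min_idx = integer(0), period_cm = numeric(0),
                          ratio = numeric(0), age_yr = numeric(0)),
      baseline = NA_real_, baseline_defined = FALSE, n_cycles = 0L),
      class = "cycle_set"))
  }
  rows <- lapply(seq_len(length(idx) - 1L), function(c) {
    i <- idx[c]; j <- idx[c + 1L]
    interior <- (i + 1L):(j - 1L)
    v <- series[interior]
    mins <- interior[v == min(v)]
    mid <- (i + j) / 2
    mk <- mins[order(abs(mins - mid), mins)][1L]  # midpoint-proximal, then earlier
    data.frame(peak_lo_idx = i, peak_hi_idx = j,
               peak_height = series[i], min_value = series[mk], min_idx = mk,
               period_cm = (j - i) * spacing_cm,
               ratio = series[i] / series[mk], age_yr = NA_real_)
  })
  cycles <- do.call(rbind, rows)
  structure(list(cycles = cycles, baseline = mean(cycles$min_value),
                 baseline_defined = TRUE, n_cycles = nrow(cycles)),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat("Cycle set: ", x$n_cycles, " complete cycles\n", sep = "")
  if (x$baseline_defined) {
    cat("  baseline (mean of cycle minima): ", round(x$baseline, 3),
        " ng/g; mean period ", round(mean(x$cycles$period_cm), 2), " cm\n",
        sep = "")
  } else {
    cat("  baseline undefined (fewer than 2 peaks)\n")
  }
  invisible(x)
}

#' Assign calendar ages to successive cycles
#'
#' Back-calculates ages by subtracting the number of documented T cycles
#' from the whale's estimated terminal age: the oldest cycle is aged
#' `terminal_age - n_cycles` and each cycle toward the recent end is one
#' year older, the most recent being `terminal_age - 1`.
#'
#' @param n_cycles number of cycles (here: number of T peaks), >= 1.
#' @param terminal_age_yr estimated age at death; must exceed `n_cycles`.
#' @return numeric vector of ages, oldest cycle first.
#' @export
assign_cycle_ages <- function(n_cycles, terminal_age_yr) {
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  if (terminal_age_yr <= n_cycles) {
    stop("terminal age (", terminal_age_yr, ") must exceed the number of ",
         "cycles (", n_cycles, "); age estimate inconsistent with the plate",
         call. = FALSE)
  }
  seq(terminal_age_yr - n_cycles, terminal_age_yr - 1)
}

#' Whole-plate summary metrics
#'
#' The per-whale summary row: sample statistics over the full analysis
#' window (mean, median, maximum, minimum T), peak statistics over detected
#' peaks (mean +/- SD, %CV with the n-1 sample SD), the baseline (mean of
#' cycle minima), the peak/baseline ratio (per-cycle mean +/- SD by default,
#' or the literal mean-peak-over-baseline quotient), and the mean
#' peak-to-peak cycle period.
#'
#' @param x a [hormone_profile] or numeric series.
#' @param peaks a [peak_set].
#' @param cycles a [cycle_set].
#' @param ratio_mode `"per_cycle"` (each cycle's leading peak over its own
#'   minimum, then mean +/- SD) or `"plate"` (mean peak height divided by the
#'   baseline; no SD defined).
#' @return one-row data frame of class `plate_summary`.
#' @export
summarize_plate <- function(x, peaks, cycles,
                            ratio_mode = c("per_cycle", "plate")) {
  ratio_mode <- match.arg(ratio_mode)
  series <- if (inherits(x, "hormone_profile")) x$testosterone else
    as.numeric(x)
  h <- peaks$heights
  mean_peak <- if (length(h)) mean(h) else NA_real_
  sd_peak <- if (length(h) >= 2L) stats::sd(h) else NA_real_
  cv_peaks <- if (length(h) >= 2L && mean_peak > 0) 100 * sd_peak / mean_peak
    else NA_real_
  if (ratio_mode == "per_cycle") {
    mean_ratio <- if (cycles$n_cycles) mean(cycles$cycles$ratio) else NA_real_
    sd_ratio <- if (cycles$n_cycles >= 2L) stats::sd(cycles$cycles$ratio)
      else NA_real_
  } else {
    mean_ratio <- if (cycles$baseline_defined) mean_peak / cycles$baseline
      else NA_real_
    sd_ratio <- NA_real_
  }
  out <- data.frame(
    n_peaks = length(h),
    mean_peak = mean_peak, sd_peak = sd_peak,
    baseline = cycles$baseline,
    mean_ratio = mean_ratio, sd_ratio = sd_ratio,
    max_t = max(series), min_t = min(series),
    mean_t = mean(series), median_t = stats::median(series),
    cv_peaks = cv_peaks,
    mean_cycle_period_cm = if (cycles$n_cycles)
      mean(cycles$cycles$period_cm) else NA_real_)
  class(out) <- c("plate_summary", "data.frame")
  out
}
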