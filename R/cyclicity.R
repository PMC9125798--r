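#' Autocorrelation diagnostics of a hormone series
#'
#' Mean-removed, biased (1/n normalised) autocorrelation, the standard first
#' look at whether a baleen T profile is periodic: annual cycling shows up as
#' significant positive autocorrelation recurring at the cycle's lag.
#'
#' @param series numeric vector.
#' @param max_lag largest lag (in samples), `< length(series)`.
#' @return object of class `acf_result`: lags `0..max_lag`, the ACF values,
#'   the 5% significance bound `1.96/sqrt(n)`, and `n`.
#' @export
autocorrelation <- function(series, max_lag) {
  series <- as.numeric(series)
  n <- length(series)
  if (max_lag >= n) stop("max_lag must be < series length", call. = FALSE)
  if (stats::var(series) == 0) {
    stop("series has zero variance; autocorrelation undefined", call. = FALSE)
  }
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(list(lags = 0:max_lag, acf = as.numeric(a$acf),
                 significance_bound = 1.96 / sqrt(n), n = n),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat("Autocorrelation (n = ", x$n, ", lags 0-", max(x$lags),
      ", 5% bound +/-", round(x$significance_bound, 3), ")\n", sep = "")
  sig <- x$lags[x$lags > 0 & abs(x$acf) > x$significance_bound]
  cat("  significant lags:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

# Biased (1/n) autocovariances at lags 0..max_lag of the demeaned series.
.autocov <- function(series, max_lag) {
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE, demean = TRUE,
                  type = "covariance")
  as.numeric(a$acf)
}

#' Fit an autoregressive model with AIC order selection
#'
#' Yule-Walker AR(p) fits computed by the Levinson-Durbin recursion for every
#' order `p` in `0..max_order`; the order minimising
#' `AIC(p) = n * log(sigma2_p) + 2p` is returned (ties broken toward the
#' smaller order). `sigma2_p` is the innovation variance implied by the
#' recursion, which is non-increasing in `p`.
#'
#' @param series numeric vector (detrended), length >= 10.
#' @param max_order largest candidate order; default
#'   `min(floor(n/3), 40)` — high enough to resolve narrow-band annual
#'   cycling on 90-165-sample plates without overfitting.
#' @return list with `order`, `coefficients` (`a_1..a_p` in
#'   `x_t = sum a_j x_{t-j} + e_t`), `innovation_variance`, `aic` (vector over
#'   orders `0..max_order`) and `n`.
#' @export
fit_ar_aic <- function(series, max_order = NULL) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) stop("need at least 10 samples for AR fitting", call. = FALSE)
  if (is.null(max_order)) max_order <- min(floor(n / 3), 40L)
  max_order <- as.integer(max_order)
  if (max_order >= n / 2) stop("max_order must be < n/2", call. = FALSE)
  g <- .autocov(series, max_order)
  if (g[1L] <= 0) {
    stop("series has zero variance; AR fit undefined", call. = FALSE)
  }
  sigma2 <- g[1L]
  a <- numeric(0)
  sig_by_order <- numeric(max_order + 1L)
  coef_by_order <- vector("list", max_order + 1L)
  sig_by_order[1L] <- sigma2
  coef_by_order[[1L]] <- numeric(0)
  for (p in seq_len(max_order)) {
    k <- (g[p + 1L] - if (p > 1L) sum(a * g[p:2L]) else 0) / sigma2
    a <- c(a - k * rev(a), k)
    sigma2 <- sigma2 * (1 - k^2)
    sig_by_order[p + 1L] <- sigma2
    coef_by_order[[p + 1L]] <- a
  }
  aic <- n * log(sig_by_order) + 2 * (0:max_order)
  best <- which.min(aic) - 1L   # first minimum = smallest order on ties
  list(order = best, coefficients = coef_by_order[[best + 1L]],
       innovation_variance = sig_by_order[best + 1L], aic = aic, n = n,
       innovation_variances = sig_by_order)
}

#' Spectral density of a fitted AR model
#'
#' `S(f) = sigma2 / |1 - sum_j a_j exp(-2i*pi*f*j)|^2` in cycles per sample;
#' integrated over `(-1/2, 1/2]` this recovers the process variance.
#'
#' @param coefficients AR coefficients `a_1..a_p` (may be empty for order 0).
#' @param sigma2 innovation variance.
#' @param freq numeric vector of frequencies in `(0, 0.5]`.
#' @return numeric vector of spectral densities.
#' @export
ar_spectrum <- function(coefficients, sigma2, freq) {
  if (any(freq <= 0 | freq > 0.5)) {
    stop("frequencies must lie in (0, 0.5]", call. = FALSE)
  }
  p <- length(coefficients)
  if (p == 0L) return(rep(sigma2, length(freq)))
  j <- seq_len(p)
  denom <- vapply(freq, function(f) {
    Mod(1 - sum(coefficients * exp(-2i * pi * f * j)))^2
  }, numeric(1))
  sigma2 / denom
}

#' Estimate the hormone cycle period by AR spectral analysis
#'
#' The full plate-level period estimator: detrend with a Gaussian low-pass
#' filter, fit an AR model with AIC order selection, evaluate its spectral
#' density on a dense frequency grid restricted to the period search band,
#' and convert the spectral peak frequency (cycles per sample) to a period in
#' cm via `period = spacing / peak_frequency`.
#'
#' @param x a [hormone_profile] (its testosterone series is used) or a
#'   numeric series.
#' @param spacing_cm sample spacing in cm; taken from the profile when `x` is
#'   one.
#' @param window optional `c(start_cm, end_cm)` analysis window (profiles
#'   only), applied before any processing.
#' @param sigma_cm detrending filter width in cm (see [detrend()]).
#' @param max_order passed to [fit_ar_aic()].
#' @param grid_points number of frequency grid points across the band.
#' @param period_band_cm `c(min, max)` period search band in cm; the spectral
#'   argmax is required to be a local maximum inside this band.
#' @param series_name which profile series to analyse: `"testosterone"` or
#'   `"d15n"`.
#' @return object of class `spectral_result`: `ar_order`, `ar_coefficients`,
#'   `innovation_variance`, `peak_frequency` (cycles/sample), `period_cm`,
#'   and the evaluated `spectrum` (data frame of frequency and density).
#' @export
estimate_period <- function(x, spacing_cm = NULL, window = NULL, sigma_cm = 8,
                            max_order = NULL, grid_points = 4096,
                            period_band_cm = c(4, 60),
                            series_name = c("testosterone", "d15n")) {
  series_name <- match.arg(series_name)
  if (inherits(x, "hormone_profile")) {
    if (!is.null(window)) x <- apply_window(x, window[1L], window[2L])
    spacing_cm <- x$spacing_cm
    series <- x[[series_name]]
    if (is.null(series)) {
      stop("profile '", x$whale_id, "' has no ", series_name, " series",
           call. = FALSE)
    }
  } else {
    if (is.null(spacing_cm)) {
      stop("spacing_cm is required for a bare numeric series", call. = FALSE)
    }
    series <- as.numeric(x)
  }
  stopifnot(length(period_band_cm) == 2L, period_band_cm[1L] > 0,
            period_band_cm[1L] < period_band_cm[2L])

  resid <- detrend(series, spacing_cm, sigma_cm = sigma_cm)
  fit <- fit_ar_aic(resid, max_order = max_order)

  f_lo <- spacing_cm / period_band_cm[2L]
  f_hi <- min(0.5, spacing_cm / period_band_cm[1L])
  if (f_lo >= f_hi) stop("period band is empty at this spacing", call. = FALSE)
  freq <- seq(f_lo, f_hi, length.out = grid_points)
  dens <- ar_spectrum(fit$coefficients, fit$innovation_variance, freq)

  # interior local maxima only; ties toward lower frequency
  m <- length(dens)
  is_max <- c(FALSE, dens[2:(m - 1)] > dens[1:(m - 2)] &
                dens[2:(m - 1)] >= dens[3:m], FALSE)
  if (!any(is_max)) {
    stop("no dominant cycle: spectral density has no local maximum inside ",
         "the ", period_band_cm[1L], "-", period_band_cm[2L], " cm band",
         call. = FALSE)
  }
  cand <- which(is_max)
  peak <- cand[which.max(dens[cand])]
  structure(list(ar_order = fit$order, ar_coefficients = fit$coefficients,
                 innovation_variance = fit$innovation_variance,
                 peak_frequency = freq[peak],
                 period_cm = spacing_cm / freq[peak],
                 spectrum = data.frame(frequency = freq, density = dens),
                 spacing_cm = spacing_cm, sigma_cm = sigma_cm, n = fit$n),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat("AR spectral period estimate\n")
  cat("  AR order ", x$ar_order, " (AIC-selected, n = ", x$n,
      ", detrend sigma = ", x$sigma_cm, " cm)\n", sep = "")
  cat("  peak frequency ", signif(x$peak_frequency, 4),
      " cycles/sample -> period ", round(x$period_cm, 2), " cm\n", sep = "")
  invisible(x)
}
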