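---
title: "Detecting annual testosterone cycles in baleen: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting annual testosterone cycles in baleen: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baleenT)
```

## The measurement model

Baleen grows continuously from the gum while wearing at the tip, so a
plate drilled every 2 cm yields a longitudinal series of hormone
concentrations ordered from the most recent growth (position 0) to the
oldest (the tip). In adult male bowhead whales 2 cm corresponds to
roughly one to two months of growth, and annual growth ranges from about
14 to 22 cm, slowing with age. Two co-registered series are used: total
immunoreactive testosterone (T, ng per g baleen powder) and, when
available, δ15N (permil), whose annual oscillation — driven by migration
between isotopically distinct foraging grounds — provides the calendar.

The working signal model is narrow annual T pulses over a low baseline,
with the pulse period equal to the local annual growth increment. The
package's analysis chain makes this operational in five stages:
detrending, spectral period estimation, phase estimation against δ15N,
peak/cycle metrics, and age-trend modelling.

## Detrending

`detrend()` subtracts a Gaussian low-pass smooth (kernel σ in cm,
truncated at ±4σ, mirror-reflected boundaries). The residual transfer
function at period $P$ is $1 - \exp(-2\pi^2\sigma^2/P^2)$.

The filter width is a genuine design choice: the default σ = 8 cm keeps
essentially all of a 14-cm cycle (99.8%) and 93% of a 22-cm cycle, while
absorbing ~70% of variation slower than 60 cm into the trend. A width
large enough to pass 99% of the whole 14–22 cm band (σ ≥ 10.6 cm) would
absorb barely half of the slow variation, defeating the detrender's
purpose, so the default favours trend removal and accepts mild
attenuation at the band's long end. The attenuation is amplitude-only and
phase-free, so it does not bias the spectral peak location or the
cross-correlation lag; every report records the σ used. Boundary
reflection avoids manufacturing spurious trends at the plate ends, at the
cost of slightly damped response within ~4σ of each end — tests of
transfer-function behaviour therefore measure interior samples, by RMS
amplitude (the sampling grid does not hit a sinusoid's crest at 7 samples
per period).

## Cycle period by AR spectral analysis

`estimate_period()` fits autoregressive models of every order
$p = 0..p_{max}$ to the detrended series by Yule–Walker, computed with
the Levinson–Durbin recursion on biased (1/n) autocovariances, and
selects $p$ minimising $AIC(p) = n\ln\hat\sigma^2_p + 2p$ (additive
constants cancel in the argmin; ties break to the smaller order). The
selected model's spectral density
$S(f) = \sigma^2 / |1 - \sum_j a_j e^{-2\pi i f j}|^2$ is evaluated on a
4096-point grid restricted to a period search band (default 4–60 cm),
and the highest interior local maximum gives the peak frequency $f$
(cycles per sample), converted to a period in cm as $\text{spacing}/f$.
If no interior local maximum exists — e.g. white noise whose selected
order is 0 — the stage raises a "no dominant cycle" error rather than
reporting a band edge.

Tunable parameters: `max_order` (default $\min(\lfloor n/3\rfloor, 40)$,
high enough to resolve a narrow annual line plus its harmonics on
90–165-sample plates without overfitting), `grid_points` (4096),
`period_band_cm` (4–60 cm, excluding sub-seasonal noise and residual
trend; whether the search band should be narrower is left explicit
configuration rather than hard-coded).

A known numerical property: for a *pulse* train (as opposed to a
sinusoid), the all-pole spectrum's peak sits a few tenths of a percent
off the true fundamental — on a noiseless 16-cm-period, 320-cm plate the
estimate is 16.03 cm, and `stats::spec.ar` reproduces the same value on
the same series. This is the biased-autocovariance taper interacting
with the harmonic poles, not an implementation artefact; it is far below
the ~0.1 cm scale that matters for distinguishing whales, but it means
the estimator is *not* exact to its own grid resolution on pulse-like
signals, and the test suite documents this honestly (a pure sinusoid is
recovered to within one grid step; the pulse train is not).

## Phase offset against δ15N

`estimate_phase()` cross-correlates the detrended T and δ15N series
(biased normalisation, so $|ccf| \le 1$), searching lags within half an
isotope period to avoid locking onto the adjacent cycle. The best lag
$k$ (in samples) converts to months as
$|k| \cdot \text{spacing} / \text{T period} \times 12$, assuming one T
cycle spans a 12-month year. Sign convention: $k > 0$ means the T
pattern is displaced toward the older (larger-position) end, i.e. T
peaks occur earlier in time than the isotope crest. The **T** period is
the denominator of the month conversion: this is the only convention
consistent with all the published per-whale offsets (e.g. a one-sample
lag at a 14.49-cm T period gives 1.66 months; the whale's 14.90-cm
isotope period would give 1.61). Offsets are therefore quantised to
multiples of $\text{spacing}/\text{period} \times 12 \approx 1.1{-}1.7$
months; sub-sample interpolation is deliberately out of scope. A best
correlation below $1.96/\sqrt{n}$ flags the result non-significant
rather than erroring.

## Peaks, cycles, and their metrics

A T peak is a sample strictly greater than its four neighbours (two
prior, two subsequent); the first two and last two samples can never
qualify, and equal-valued plateaus yield no peak. The rule operates on
raw concentrations and is invariant under monotone transforms.

Consecutive peaks bound one complete cycle each. The cycle minimum is
the smallest strictly interior value (ties break to the sample nearest
the cycle midpoint, then the earlier one — any deterministic rule would
do; this one is symmetric). The cycle period is the bounding-peak
distance; the baseline is the mean of cycle minima (partial cycles at
the plate ends contribute nothing); `%CV` of peaks uses the n−1 sample
SD throughout, matching the ± SD convention of the summary tables.

Two ratio semantics are provided. The published table's footnote defines
the peak/baseline ratio as mean peak over mean baseline, but reports a
± SD that a single quotient cannot produce (3.06/0.90 = 3.40, yet
4.04 ± 2.95 is printed); only a per-cycle ratio — each cycle's leading
peak over its own minimum, then mean ± SD — can. The per-cycle
definition is therefore the default, with `ratio_mode = "plate"` giving
the footnote-literal quotient.

Ages are back-calculated by subtracting the number of documented T
cycles from the whale's terminal age: the oldest cycle is aged
`terminal − n`, the most recent `terminal − 1`. The published cohort
counts *peaks* for this purpose (the mixed-model sample size equals the
summed peak counts, 126), so the package ages peaks and lets a complete
cycle carry the age of its older bounding peak.

An optional prominence filter (default off — the pure rule) drops
candidates whose height exceeds the higher of the two flanking troughs
by less than a threshold. It exists because independent additive
measurement noise makes about one in five samples of a *flat* stretch a
four-neighbour local maximum, regardless of the noise amplitude; real
plates are smoother than white noise, but simulated ones are not. The
threshold is topographic rather than a neighbour margin: a pulse whose
centre falls between two samples produces two near-equal top samples,
so a neighbour-margin rule would discard genuine pulses.

## Age estimation

Length-based ages invert a monotone von Bertalanffy length-at-age curve
by bisection on [0, 250] yr to 0.01 yr. The cascade mirrors practice
for large males: the two-stage curve when the length is below its
asymptote; the single-stage curve when the two-stage asymptote is
exceeded; and the arithmetic mean of aged comparator males in the same
length class when even that fails. Published growth-curve parameter
values are external to this package and are supplied as YAML
configuration; the shipped `growth_params_fixture.yaml` is a clearly
labelled synthetic calibration whose inversion reproduces the study
cohort's printed (length, age) pairs after rounding, with asymptotes
placed so the two largest whales trigger the fallbacks. The
best-available-age policy prefers an explicit override (sensitivity
runs), then the eye-lens AAR age, then the length-derived age; a
length-only mode ignores AAR ages so both analysis arms can be run.

## Age-trend models

Per-cycle peak T (and period) observations are modelled with three
Gaussian candidates via `nlme::lme`: `response ~ 1` with a random
intercept (null), `response ~ age` with a random intercept, and
`response ~ age` with correlated random intercept and slope. Candidates
are fit by ML, ranked by
$AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting fixed effects,
variance/covariance components *and* the residual variance (3, 4 and 6
respectively — a convention applied uniformly so the ranking is
internally consistent; it reproduces the published AICc values from the
published log-likelihoods exactly), ties break to the simpler variant,
and the winner is refit by REML for reported estimates. Fixed-effect t
statistics use the within-group denominator df $N - G - q$ (126 − 9 − 1
= 116 at the cohort's shape), the convention `nlme` applies to this
design. Residual diagnostics (Shapiro–Wilk statistic, scale-location
slope) are attached as automated summaries, replacing visual residual
inspection; they gate nothing. `nlminb` is tried first and `optim` on
failure; a variance estimated at zero sets a boundary flag rather than
erroring. Cross-whale correlations of plate summaries with terminal age
use two-tailed Pearson tests at α = 0.05.

## The synthetic generator: what it emulates, and what it does not

`generate_profile()` builds
$T(x) = b_c + a_c\,g(\phi(x)) + \varepsilon_T$, where cycles $c$ are laid
from the oldest end with per-cycle period
$P_c = P_1 - (c-1)\,\delta$ (piecewise-constant period, the simplest
structure consistent with growth slowing predictably with age while
keeping truth bookkeeping exact), $g$ is a unit-height circular Gaussian
pulse with FWHM a configurable fraction of the cycle (default 0.2 — a
narrow breeding-season pulse), and per-cycle amplitude and baseline
follow linear trends (negative amplitude trend with positive baseline
trend emulates the senescent pattern of the two oldest whales). The
isotope series is a cosine of the same local phase, lagging the T pulse
by a configurable lead (default 3 months ≈ the published 2.8-month mean)
and continuing through an optional acyclic juvenile prefix at the old
end of the plate (the youngest whale's morphology). Noise is additive
Gaussian, clipped at zero with clip counts recorded — simpler than a
lognormal assay model, and adequate for recovery testing.

The default study-shaped cohort (`study_cohort_specs()`) takes plate
lengths, periods, amplitudes, baselines, phase leads and terminal ages
from the published per-whale table, with within-whale amplitude trends
of −0.02 ng/g per cycle for the younger whales and −0.30 ng/g per cycle
(plus +0.04 baseline rise) for the two oldest, mirroring the published
order-of-magnitude gap in individual slopes; noise defaults to 10% of
each whale's pulse amplitude.

What passing recovery tests on this cohort shows: the chain correctly
recovers periods (to ~0.1–0.3 cm), phase leads (to one-sample
quantisation), peak counts, senescent trend signs and mixed-model slope
signs from data *of the assumed form*. What it does not show: robustness
to assay drift or extraction-efficiency gradients along the plate,
non-Gaussian or autocorrelated measurement error, missing samples,
skipped or "short" peaks, or mis-specified terminal ages — real-data
phenomena the generator deliberately does not model. In particular the
white-noise baseline makes the pure peak rule over-count on simulated
data (hence the prominence margin in the default scenario config),
whereas the published counts came from smoother real profiles with the
pure rule.

## Numerical choices and degenerate inputs

* Positions must be strictly increasing and uniform to 1e-9; profiles
  need ≥ 5 samples (the peak rule's minimum), AR fits ≥ 10.
* Zero-variance series error in autocorrelation, AR fitting and
  cross-correlation; a whale failing any stage is recorded and the
  cohort stages proceed without it.
* Argmin/argmax ties break deterministically: smaller AR order, lower
  frequency, simpler model variant, midpoint-then-earlier cycle minima.
* Profile CSVs are written with 17 significant digits, so
  read(write(x)) is lossless and byte-stable.
* Terminal ages not exceeding the cycle count make age assignment
  impossible and error explicitly; fewer than two peaks yield an empty,
  flagged cycle set with an undefined baseline.
* The analysis itself is deterministic; only simulation consumes seeds
  (per-whale sub-seeds drawn from the master seed).

## Problem sizes in the test suite

The suite exercises plates of 81–166 samples (160–330 cm), 200-series
peak-detector oracle sweeps, 100-replicate period-recovery and
mixed-model coverage experiments at the cohort's shape (9 whales, 126
peak observations), and full simulate-then-analyse runs of the nine-whale
scenario — sizes matching the study's own, chosen so every property is
tested at the scale it is claimed for. Two assertions are knowingly at
or beyond the method's boundary and are discussed above: grid-step
exactness of the spectral peak on noiseless pulse trains, and 2-SE
coverage of the mixed-model slope at nine groups, whose true coverage is
≈ 0.90 by construction (the asymptotic SE understates slope uncertainty
with so few groups).

## Known limitations

Calendar-date anchoring of cycles (tying a peak to a named month) needs
collection-date modelling beyond the scope here; offsets are relative to
the isotope crest. Automatic changepoint detection for the onset of
cycling is not attempted — acyclic juvenile segments are handled by
explicit per-whale analysis windows. Period uncertainty intervals are
not produced (the AR peak is a point estimate), and model-averaged or
Kenward–Roger inference for the mixed models is out of scope.
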