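# baleenT

Annual testosterone (T) cycle analysis along baleen plates.

Baleen, the keratinised filter-feeding apparatus of mysticete whales, grows
continuously from the gum while wearing at the tip, so a single plate
archives a continuous multi-year record of circulating hormones. Drilled at
a uniform 2-cm spacing, a bowhead whale plate yields a longitudinal T
series (ng immunoreactive hormone per g baleen powder) at roughly monthly
resolution over one or two decades, alongside stable-nitrogen-isotope
(δ15N) oscillations that act as an annual calendar (one crest per summer
foraging season). `baleenT` implements the full analysis chain for such
records, for wildlife endocrinologists asking whether male whales cycle
testosterone annually, when in the year they peak, and how cycling changes
with age.

## What it computes

For each whale's profile `T(x)` on positions `x = 0, 2, 4, ...` cm
(0 = most recently grown baleen):

* **Detrending** — subtraction of a Gaussian low-pass smooth (default
  σ = 8 cm, reflected boundaries). The residual at period `P` retains a
  fraction `1 − exp(−2π²σ²/P²)` of the amplitude, so 14–22 cm annual
  cycles pass nearly intact while slower trends are absorbed.
* **Cycle period** — Yule–Walker AR(p) fits by the Levinson–Durbin
  recursion for p = 0..max order, order selected by
  `AIC(p) = n·ln(σ̂²ₚ) + 2p`; the model spectral density
  `S(f) = σ²/|1 − Σⱼ aⱼe^(−2πifj)|²` is evaluated on a dense grid and the
  peak frequency converted to a period via `period = spacing / f`.
* **Phase offset** — cross-correlation of the detrended T and δ15N series;
  the best whole-sample lag `k` becomes an offset of
  `|k|·spacing / T-period × 12` months, with `k > 0` meaning T peaks
  precede the isotope crest in time.
* **Peaks and cycles** — a T peak is a sample strictly greater than its
  four neighbours (two prior, two subsequent); consecutive peaks bound
  complete cycles, each with one minimum; the baseline is the mean of the
  cycle minima; per-cycle ages are back-calculated by subtracting the
  number of cycles from the whale's terminal age.
* **Age estimation** — von Bertalanffy length-at-age inversion (two-stage,
  with single-stage and comparator-average fallbacks for the largest
  males), eye-lens AAR ages when available, and a best-available-age
  policy with sensitivity overrides.
* **Age trends** — candidate linear mixed models (null, random intercept,
  random intercept and slope) of per-cycle peak T and period against age,
  fit by ML via `nlme`, ranked by AICc, refit by REML; plus Pearson
  correlations of whole-plate summaries with terminal age.

A seeded synthetic-profile generator produces baleen-like T and δ15N
series with exact ground truth (pulse positions, periods, baselines, phase
lead, ages), so every stage has a recovery test.

## Worked example

The package ships the published per-whale summary table for the nine-male
bowhead cohort. Baseline T rises strongly with terminal age:

```r
library(baleenT)
tab <- bowhead_cycle_summary()
pearson_corr_test(tab$est_age_yr, tab$baseline_t_ng_g)
#> Pearson correlation: r = 0.9317, r^2 = 0.8680, t(7) = 6.785, p = 0.0002567 * (n = 9)
```

`r² = 0.868` means 87% of the between-whale variance in baseline T is
explained by age — the oldest whales have the highest hormone floor.

A full simulate-then-analyse run on the study-shaped synthetic cohort:

```r
sc  <- study_scenario(seed = 1)   # 9 whales shaped on the published cohort
res <- run_analysis(sc$config)
res
#> Baleen T cycle analysis: 9 whales
#>   whale1     age    14   5 peaks  period 18.41 cm  offset 0.00 mo
#>   whale2     age    18  12 peaks  period 19.25 cm  offset 2.49 mo
#>   whale3     age    21  13 peaks  period 21.57 cm  offset 3.34 mo
#>   whale4     age    23  13 peaks  period 16.92 cm  offset 2.84 mo
#>   whale5     age    24  15 peaks  period 17.70 cm  offset 2.71 mo
#>   whale6     age    44  12 peaks  period 16.52 cm  offset 2.91 mo
#>   whale7     age    48  18 peaks  period 16.14 cm  offset 2.97 mo
#>   whale8     age   115  22 peaks  period 14.62 cm  offset 3.28 mo
#>   whale9     age   153  25 peaks  period 14.63 cm  offset 1.64 mo
#>   [best] peak T ~ age: random_intercept_slope model, slope -0.053
#>   [best] period T ~ age: random_intercept model, slope -0.0397
#>   [length_only] peak T ~ age: random_intercept model, slope -0.108
#>   [length_only] period T ~ age: random_intercept model, slope -0.0414
```

Periods land within a few tenths of a cm of the generating truth, the
youngest whale's T and isotope cycles are synchronised (offset 0) while
every older whale's T leads by roughly 1.6–3.4 months, and both mixed
models recover the generating negative age trends (peak T and cycle period
both decline with age). Setting `output_dir` in the config writes the
per-whale summary, per-cycle, phase and correlation CSVs plus mixed-model
JSON reports; `inst/scripts/baleen-pipeline.R` wraps the same calls for
shell use.

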