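---
title: "Methods: first-difference analysis of rice yield responses to climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-difference analysis of rice yield responses to climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricedelta)
library(dplyr)
```

## The problem

Long-term rice variety trials accumulate two confounded signals: slow gains
from breeding and management ("technology"), and year-to-year weather. A
level-on-level regression of yield on climate absorbs the technology trend
into whichever climate variable happens to drift, so the climate
coefficients are biased. `ricedelta` implements the standard remedy for
long agronomic records: work in *first differences*. For an annual series
$v$ the first difference is $\Delta v(y) = v(y+1) - v(y)$; any component of
yield that is (locally) linear in calendar year contributes only a constant
to $\Delta Y$, which the regression intercept absorbs.

The analysis chain is:

1. **Weather QC and seasonal aggregation.** Daily station records (average,
   minimum and maximum temperature, rainfall, sunshine duration) are
   screened and aggregated over the two fixed cropping-season windows used
   in central Taiwan: *cool* (January 20 - June 23) and *warm* (July 4 -
   November 22). Per season-year this yields the mean daily temperature
   $T$, the mean diurnal temperature range $DTR = \overline{t_{max} -
   t_{min}}$, total rainfall $R$ and total sunshine duration $S$.
2. **Climate trends.** Each seasonal series is fit by ordinary least
   squares, $x = \beta_0 + \beta_1 t + \varepsilon$, with the slope's
   p-value from the $t$ statistic on $n - 2$ degrees of freedom. The
   trend-implied total change over a period is $\beta_1 \times
   (\text{end} - \text{start})$ — the rise of the regression line between
   its endpoint years, so a 1925-2019 record uses a multiplier of 94, not
   95.
3. **First-difference regression.** Per cultivar and season,
   $$\Delta Y = \beta_0 + \beta_T \Delta T + \beta_{DTR} \Delta DTR +
     \beta_R \Delta R + \beta_S \Delta S + \varepsilon,$$
   by OLS. Percent coefficients normalize by the cultivar's average grain
   yield over its trial years: $\beta_\% = 100\,\beta / \bar{Y}$, in
   percent per unit of the climate variable, which makes cultivars of very
   different yield levels comparable.
4. **Grouping.** Cultivars with overlapping cultivation periods are grouped
   (either from an explicit configuration or as connected components of
   the span-overlap graph) and summarized by the arithmetic mean and
   sample SD of their percent coefficients.
5. **Projection.** For each group period, the total relative yield change
   is $\beta_\% \times \Delta\text{Climate}_{\text{total}}$ (%) and the
   annual actual change is $\beta \times \Delta\text{Climate}_{\text{total}}
   / n_{\text{years}}$ (kg/ha per year), with $n_{\text{years}} =
   \text{end} - \text{start} + 1$. The two are linked by the identity
   $\text{annual} = (\text{relative}/100)\,\bar{Y}/n_{\text{years}}$,
   which holds row by row in the output and is verified by the tests.

## Quality control rules

The station rule for a bad cell on calendar day $(m, d)$ of year $y$ is the
mean of the same calendar day in years $y-1$ and $y+1$; with only one
usable neighbouring year, that value is used alone. "Bad" means missing,
or an *outlier*: further than `outlier_z` (default 4) climatological
standard deviations from the day-of-year mean, where the climatology pools
a ±7-day window across all years. The threshold is deliberately
conservative so that genuine extremes — typhoon rainfall in particular —
survive screening. Every replacement is logged (date, variable, old, new,
rule).

Three deliberate choices:

* **Doubly-missing cells.** If both neighbouring years are unusable the
  cell is left absent and flagged by default (`fallback = "none"`), and
  seasonal aggregation refuses to silently average over it. At a realistic
  2.65% whole-day missing rate, a 95-year series contains a couple of
  dozen such cells, so the pipeline runs with
  `fallback = "climatology"`: the day-of-year climatological mean fills
  the cell, logged under its own rule tag so the fills can be audited.
* **Unresolved outliers keep their value.** An outlier with no usable
  neighbour is retained (flagged) rather than blanked: discarding an
  observed value outright would destroy data and abort aggregation.
* **One-pass screening.** The outlier screen is applied once. Replacing a
  value shrinks the climatological SD, so re-screening can cascade on
  heavily skewed variables (rainfall); missing-value imputation itself is
  idempotent and tested to be.

The leap day falls inside the cool window; windows are date-anchored, so
leap years aggregate 156 rather than 155 days and `n_days` records the
difference. Rainfall uses the same neighbour rule as temperature for
uniformity even though it is zero-inflated; its replacements are
distinguishable in the log. A mid-record station relocation in such
datasets is treated as one continuous series; no break-point
homogenization is attempted.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `outlier_z` | 4 | climatological SD | outlier screen threshold |
| `min_pairs` | 6 | pairs | minimum first differences for a 5-parameter fit |
| `fallback` | `"none"` / pipeline `"climatology"` | — | doubly-missing cells |
| `delta_mode` | `"period"` | — | climate delta from period-local or full-record trend |
| season windows | Jan 20-Jun 23, Jul 4-Nov 22 | dates | aggregation windows |

`min_pairs = 6` keeps the five-parameter regression determined with at
least one residual degree of freedom; cultivars with fewer usable pairs
are skipped and listed rather than fitted. First differences are formed
only across *consecutive calendar years both present* for that cultivar —
a pair bridging a multi-year trial interruption would reintroduce exactly
the technology drift the method removes.

`delta_mode` addresses a genuine ambiguity: a period's total climate
change can come from a trend refit inside the period (default, matching
the per-interval coefficient language of interval analyses) or from the
full-record slope applied to the period's span. Both are implemented; the
mode is recorded in every projection row.

Significance markers follow the convention `**` for $p<0.01$, `*` for
$0.01 \le p < 0.05$, `'` for $0.05 \le p < 0.1$, with boundary values
assigned to the weaker class — a deterministic tie rule.

## The synthetic generator

Every stage is testable without any external download because the package
generates daily weather and cultivar yields with known ground truth.

The weather model: a sinusoidal annual temperature cycle (peak mid-July)
plus an AR(1) daily anomaly; linear trends applied separately to minimum
and maximum temperature so that warming concentrated in the nights shrinks
DTR (defaults 0.016 and 0.003 °C/yr, i.e. about 1.5 and 0.3 °C over 94
years); Bernoulli–Gamma daily rainfall whose Gamma scale drifts to impose
a rainfall trend; sunshine driven by day length with a penalty on wet days
and a small negative drift; and a fraction of whole days (default 2.65%)
removed at random. Defaults were chosen once to match the first moments of
a 95-year central-Taiwan station record — cool-season mean temperature
near 21.7 °C, seasonal rainfall totals of roughly 700–800 mm, seasonal
sunshine near 900–1000 h — and the signs and magnitudes of its reported
trends.

What the generator does *not* emulate, and hence what passing tests do not
establish about real data: a pure sinusoid cannot match both the cool- and
warm-season window means of an asymmetric subtropical annual cycle (the
warm season runs about 1 °C cool here); day-to-day autocorrelation is an
AR(1) modelling choice, not an observed property; rainfall has no typhoon
or frontal clustering, so seasonal totals are under-dispersed relative to
real records; and interannual DTR variability is smaller than observed.
Parameter-recovery results therefore validate the *estimator and
plumbing* — identifiability, technology-trend immunity, consistency — not
the meteorological realism of any particular record.

The yield model is the regression read forwards:
$Y = \text{intercept} + \text{tech} \cdot (y - y_0) + \beta_T T +
\beta_{DTR} DTR + \beta_R R + \beta_S S + \varepsilon$, with gap years
producing absent records (never zeros). With $\varepsilon \equiv 0$ and a
full-rank design the fit recovers the generating coefficients to numerical
precision; with noise, recovery is checked across seed replicates against
Monte-Carlo standard errors at spans of 20, 45 and 90 years.

## Problem sizes used in the tests

The suite exercises 3-to-20-year series for hand-checkable unit tests,
90-to-95-year series for trend and recovery checks, 50 seed replicates for
the Monte-Carlo recovery criterion, and 10-to-12 replicates for the
consistency-with-span sweep; these sizes make every statistical check
stable under its fixed seeds while keeping the default test run fast.

## Degenerate inputs and numerical choices

* Trend fits require at least 3 points and 2 distinct years; identical
  years raise a rank error, not a crash inside `lm()`.
* Exact fits (zero residual SD) report $R^2 = 1$ and a slope p-value of 0,
  avoiding the 0/0 from the usual formulas.
* The first-difference design is rank-checked by QR before fitting;
  collinear columns are named in the error.
* Mean-yield normalization requires a strictly positive average yield.
* Correlation pairs with fewer than 3 complete observations are reported
  as undefined rather than fabricated; cultivar pairs without 3 shared
  years are omitted with a log entry.
* Group SDs are sample (n-1) SDs; a single-member group reports `NA`
  rather than 0.

## Reference tables

The package ships the published cultivar-level percent coefficients and
the cultivation spans and grouping of the 14-cultivar, 1925-2019 Taichung
trial (`taichung_coefficients()`, `taichung_cultivars()`,
`taichung_groups()`). These are worked-example inputs: the group
summaries computed from them by `summarize_group()` reproduce the
published group means, which the acceptance tests verify. The underlying
deposited daily-weather and field-yield tables are not redistributed; the
full-record reproduction test runs only when a user places them under
`inst/extdata/taichung/`. The group covering 1977-1983 (two cultivars,
seven years, nested inside 1945-1983) is computed and written but flagged
`excluded`, and projection plots drop it.

## Known limitations

* Plain OLS standard errors throughout; no autocorrelation-robust
  (Newey-West) correction, matching the analysis the package reproduces.
* The model is strictly linear and additive in the four climate
  variables; no interactions, thresholds or quadratic terms.
* Neighbour-year mean imputation biases variances slightly downward, a
  known property of mean substitution; the QC report exposes every
  replacement so sensitivity analyses can drop imputed years.
* Grouping is by cultivation-period overlap only; no yield-similarity
  clustering.

## A worked example

```{r example, eval = FALSE}
# generate a century-scale synthetic trial, then analyse it
dir <- tempfile()
paths <- simulate_inputs(out_dir = dir, seed = 1)
run_pipeline(list(weather = paths$weather, yields = paths$yields),
             file.path(dir, "out"))
render_report(file.path(dir, "out"))$group_summary
```
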