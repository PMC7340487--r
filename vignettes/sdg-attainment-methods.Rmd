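---
title: "Methods: attainment scaling, topic aggregation and trend projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attainment scaling, topic aggregation and trend projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdgtrack)
```

# The problem

National and subnational tracking of the health-related Sustainable
Development Goal (SDG) targets needs three things: a common 0–100 scale that
makes a maternal mortality ratio comparable with a smoking prevalence, a way
to combine indicator scores into thematic summaries, and a defensible
"business-as-usual" projection of each indicator to its target year. This
package implements that pipeline for a registry of 28 health-related SDG
monitoring indicators grouped under nine thematic topics (child nutrition;
maternal, child and reproductive health; infectious diseases; NCD mortality;
NCD risk factors; road injury; environmental outcomes; environmental
exposures; universal health coverage), with China's provincial monitoring
set-up as the motivating design (31 provinces in an eastern/central/western
grouping, sex-stratified series from 1990 onward).

# The attainment index

For an indicator with observed value $x$ the attainment index is

$$\mathrm{score}(x) = 100\,\frac{f(x) - f(W)}{f(T) - f(W)},$$

clipped to $[0, 100]$, where

* $f$ is the indicator's transform: $\ln$ for incidence and mortality rates,
  $\mathrm{logit}$ for proportions bounded in $[0,1]$, identity otherwise.
  Scaling rates in log space means that a halving of mortality earns the same
  increment anywhere along the scale;
* $W$ (index 0) is the **worst value** of the location's own 1990–2015
  history after trimming outliers with Tukey fences
  ($Q_1 - 1.5\,\mathrm{IQR}$, $Q_3 + 1.5\,\mathrm{IQR}$; quartiles by linear
  interpolation between order statistics, the `quantile()` type-7 rule —
  the most widespread convention, chosen because the method itself does not
  prescribe one);
* $T$ (index 100) is the **resolved target**: the published absolute target
  where one exists; `baseline × (1 − reduction)` for relative-reduction
  targets (baseline year 2015 unless the target text names another year, as
  the HIV target does with 2010); the 2015 value itself for the no-increase
  childhood-overweight target; and, for elimination-type targets with no
  numeric value, half the smallest positive retained historical value — the
  same floor convention used to make exact zeros scorable under a log
  transform.

Values past the target clip to 100, values past the worst clip to 0. A few
conventions deserve explicit statement:

* **Anchoring level.** Anchors are resolved per location (and per sex) from
  that series' own history, which reproduces provincial heterogeneity; a
  national-anchor mode (`anchor_level = "national"` in `scale_panel()`)
  scores every location against the national history instead.
* **Zeros under log.** An observed zero (e.g. malaria elimination) is
  replaced by half the smallest positive retained value of that series
  before transforming; after clipping such values score 100 when the target
  is effectively reached.
* **Inverted anchors.** If even the trimmed worst historical value meets the
  target — childhood wasting has sat under its 5% ceiling for the whole
  observation window, and a monotonically worsening no-increase series has
  its historical maximum exactly at the 2015 baseline — there is no
  unfavourable span to stretch a scale over. Such series are graded
  pass/fail: 100 where the value meets the target, 0 where it has
  deteriorated past it. The only hard error is a series whose every retained
  value equals the resolved target, which carries no information at all.
* **Rounding.** Scores are kept unrounded internally; provincial tables are
  conventionally printed as integers and national values at one decimal.

# Topic aggregation

The topic index is the equal-weight geometric mean of the member indicator
scores, with scores below 1 floored at 1 first so the geometric mean stays
valid and a single collapsed indicator cannot zero out a whole topic:

$$I = \exp\!\Big(\tfrac1m \sum_{j=1}^m \ln \max(s_j, 1)\Big).$$

Equal weights reflect the preference-weighted reading of the 2030 Agenda, in
which member states treat the indicators as equally important; no health-loss
or data-driven weighting is offered. Flooring is applied to *unrounded*
scores (aggregating the printed integer scores therefore reproduces
published topic values only to about one rounding unit). Cells missing some
registered members aggregate over the available members with a warning — a
fail-soft policy that keeps one broken provincial series from erasing a
topic, while the member list recorded in the output keeps the gap auditable.

# Trend projection

Each (location, indicator, sex) series is projected with a recency-weighted
mean annual rate of change in transform space. With $r_t = f(x_t) -
f(x_{t-1})$ the consecutive-year changes and weights

$$w_t \propto (t - t_0 + 1)^{\omega}, \qquad \sum_t w_t = 1,$$

the drift estimate is $\bar r = \sum_t w_t r_t$ and the projection is
$f(x_{T+h}) = f(x_T) + h\,\bar r$, back-transformed to indicator units.
Working in transform space guarantees projected rates stay positive and
projected proportions stay inside $(0, 1)$.

The exponent $\omega \ge 0$ tunes how much the recent trend dominates:
$\omega = 0$ is the uniform-weight mean (equivalently the endpoint log-ratio
divided by the span), large $\omega$ approaches the last observed change.
$\omega$ is selected per series from the grid $\{0, 0.25, \dots, 3\}$ by
backcast validation: the final 3 observed years are held out, the model is
fitted to the remainder, and the $\omega$ minimising the mean absolute error
of the held-out predictions on the natural scale wins, ties broken toward
the smallest $\omega$ (so an exactly constant-rate series, for which all
$\omega$ are equivalent, selects $\omega = 0$ deterministically). The grid,
the holdout length, and the MAE-on-natural-scale criterion are design
choices the selection mechanism leaves open; all three are arguments of
`aroc_fit()`/`project_panel()`. Series too short to hold anything out fall
back to $\omega = 1$ with a warning. Missing interior years (up to 5
consecutive) are interpolated linearly in transform space before
differencing; longer gaps are an error rather than a guess.

`aroc_fit()` returns a classed model object with the usual verbs:

```{r aroc-example}
fit <- aroc_fit(c(100, 90, 81), 2000:2002, transform = "log", omega = 1)
coef(fit)
predict(fit, years = 2003:2004)   # constant-rate series: 81 * 0.9^h
summary(fit)
```

No uncertainty intervals are produced: the projection is a deterministic
trend extrapolation, and dressing it in intervals that reflected only
residual noise — not model error — would overstate what it knows.
`simulate()` is available for parametric what-if draws around a fitted
drift.

# Progress and disparity summaries

An indicator counts as **achieved** when its projected attainment score at
its own target year (2020, 2025 or 2030 depending on the target) is at
least 90 — the comparison is inclusive, reading "an index of 90" as the
attainment bar itself. Topic progress is summarised by the **annual change
rate** `(index_end − index_start) / (year_end − year_start)` in index
points per year, computed from the last observed year to the topic's
horizon (the latest member target year). Disparity ratios are plain
quotients reported in a fixed stratum order (rural/urban, male/female,
western/eastern) and never auto-inverted, so a ratio below 1 is meaningful.
Regional summaries are unweighted province means — no population weighting
is applied, since the method description does not state any — with national
aggregates and Special Administrative Regions excluded.

Published annual change rates for several topics are *not* reproducible
from the printed one-decimal endpoint indices (they were evidently computed
on unrounded or differently-windowed series); `fixture_topic_indices()`
flags per topic whether endpoint arithmetic reproduces the printed rate,
and the package reports endpoint-arithmetic rates rather than guessing the
original series.

# The synthetic-data generator

Real GBD-style provincial estimates are external and large; the generator
exists so every pipeline stage is exercisable from code alone. It emulates
the statistical structure the projection model assumes — and deliberately
nothing more:

$$f(x_{p,i,s,t}) = f(\beta_i) + r_i\,(t - 1990) + a_i\,(t-1990)^2 +
\delta_{\mathrm{prov}(p)} + \delta_{\mathrm{region}(p)} \pm
\tfrac{\delta_{\mathrm{sex},i}}{2} + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma_i^2),$$

with noise Normal in transform space (log-Normal on rates), so domains stay
valid by construction. Default conditions: 31 provinces split 11 eastern /
8 central / 12 western, years 1990–2016, both sexes plus a derived both-sex
and national series (transform-space means), and per-indicator baselines,
drifts and noise levels in `default_indicator_params()` chosen once as
plausible for a middle-income country over that window (child stunting
falling from ~32% in logit space, under-5 mortality declining ~6.5%/year,
childhood overweight and alcohol exposure worsening, a strongly male-skewed
smoking prevalence). Region effects are signed so eastern provinces are
better off on every indicator. The seed is a required argument.

What the generator does **not** emulate: cross-indicator covariance, GBD
estimation uncertainty, reporting artefacts, or structural breaks. Passing
tests on synthetic panels therefore demonstrate the *pipeline's* arithmetic
and invariances — scale/aggregate/project/threshold behave as specified —
not that the projection model is well-specified for any real series.

`make_achievement_scenario()` constructs a noise-free panel whose national
pipeline result hits an exact designed achievement count: for each
indicator a transform-space-linear series is solved (by root finding
against the package's own anchoring and projection rules) to land at a
projected score of ~97 (achieved) or ~55 (not achieved), margins wide
enough that grid-selection discontinuities cannot flip a verdict; the
designed count is verified end-to-end before the panel is returned.
Indicators whose default baseline already satisfies an absolute target are
started on the unfavourable side so a 0–100 scale exists to design against.

# Numerical choices and problem sizes

Quartiles use the type-7 interpolation rule; omega ties break to the
smallest grid value; floored geometric means operate on unrounded scores;
backcast MAE is measured on the natural scale so that errors are in
indicator units rather than transform units. The test-suite panels use 3–8
provinces and the full 28-indicator registry (the acceptance scenario uses
31), sizes at which the complete pipeline runs in seconds while still
exercising every code path; all property suites fix their seeds.

# Known limitations

* The omega-selection rule is a documented surrogate for a per-province
  trend calibration whose exact functional form is not published; results
  for strongly non-log-linear series depend on it.
* Pass/fail grading of inverted-anchor series is a boundary convention; a
  location that deteriorates marginally past an always-met target drops
  from 100 to 0 with no intermediate scale.
* Attainment against relative targets measures relative progress only — two
  locations can both score 100 with very different absolute rates.
* Regional means are unweighted by population, and no statistical inference
  (intervals, tests) is attached to disparity ratios: they are descriptive.
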