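---
title: "Growth references and registry summaries for achondroplasia cohorts: methods"
author: "achondro package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth references and registry summaries for achondroplasia cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(achondro)
```

## The problem

Achondroplasia, the most common short-stature skeletal dysplasia, follows a
growth trajectory that separates from average-stature standards within the
first months of life. Clinical care relies on condition-specific reference
curves and on natural-history registries that catalogue anthropometry,
surgical burden (ENT, brain, foramen magnum, spine, extremity procedures),
sleep-disordered breathing and imaging across decades of follow-up. This
package implements that analysis pipeline end to end: a validated registry
container, the exclusion and quality-control rules applied before curve
construction, sex-specific percentile curves built from age-windowed
empirical quantiles and penalized-spline smoothing, height-velocity and
milestone estimation, comparison against external reference curves, and the
summary-table engines for demographics, surgical burden, polysomnography
and imaging.

Because registry data of this kind are not publicly deposited, the package
ships a first-class synthetic cohort generator. Every downstream stage is
developed and tested against generated registries whose true parameters are
known, so estimator accuracy can be measured rather than assumed.

## The percentile-curve procedure

Curves are built in two steps.

**Step 1 — windowed empirical percentiles.** At each age on an evaluation
grid, all measurements whose age falls inside a closed window around the
grid age are pooled (regardless of subject) and the 5th, 50th and 95th
percentiles are computed as order statistics with linear interpolation at
rank $1 + (n-1)p$ (`stats::quantile` type 7). Window half-widths follow the
age bands ±0.5 months for 0–12 months, ±1 for >12–36, ±3 for >36–120 and
±6 for >120–216 months; a grid age supported by fewer than `min_n = 20`
values yields a gap rather than an estimate. The evaluation grid is monthly
to 36 months, quarterly to 120 and semiannual to 216, so adjacent windows
overlap at most 50%; head-circumference curves run birth to 5 years.

**Step 2 — penalized-spline smoothing.** Each percentile series is smoothed
with a penalized smoothing spline (`stats::smooth.spline`, window counts as
weights, penalty chosen by generalized cross-validation unless fixed).
Stature and head circumference use one spline per percentile level
("isopleths"); weight, whose skewness grows with age, is fitted separately
on birth–3 years and 3–18 years and blended with a linear cross-fade over
±3 months around the 36-month seam. Non-crossing ($p_5 \le p_{50} \le
p_{95}$) is enforced after smoothing by sorting the three values at each
age — an isotonic adjustment across percentile levels that leaves each
series essentially unchanged when curves are well separated.

Birth statistics are the mean, SD and normal 95% CI
($\bar{x} \pm 1.96\,s/\sqrt{n}$) of values measured in the first half-month;
a difference from an average-stature reference mean is called significant
when the reference mean falls outside the CI. The normal $z$ is used rather
than $t$ because $n$ is in the hundreds in every reported use.

## Height velocity and milestones

Velocity estimates are difference quotients of two time-ordered
length/height values 6–18 months apart, converted to cm/year and plotted at
the midpoint age. Pairing is greedy and non-overlapping: each measurement
pairs with the earliest subsequent measurement at least 6 months later; if
that partner is within 18 months the pair is emitted and the scan resumes
from the partner, otherwise the start advances by one. Estimates are binned
by the same window scheme (extended to 21 years) and averaged.

Reading the age at which velocity "reaches zero" off this curve needs care.
A pair whose interval straddles the growth plateau maps its positive
average velocity onto a midpoint that may lie *past* the plateau, so binned
means stay slightly positive for up to half the maximum pair gap beyond it
and may never cross zero. The midpoint rule is, however, exactly unbiased
wherever velocity declines linearly; `velocity_threshold_age(method =
"tail_fit")` therefore fits a weighted line to the binned means over the
terminal decline (smoothed curve between 0.5 and 3 cm/year above the
threshold) and extrapolates it to the threshold. The default
`method = "interpolate"` reads the first downward crossing of the smoothed
curve and is appropriate for thresholds well above zero.

Two further milestones: `crossing_age()` finds the first age at which the
cohort's 95th percentile falls below the reference 5th percentile and stays
below; `attainment_age()` finds when the median head-circumference curve
reaches 90% of its plateau, the plateau being the mean of the median curve
over the final year of the grid (an asymptote estimate — the denominator is
the curve's own plateau value, not an external adult reference).

## Cleaning and exclusions

The exclusion rules applied before curve construction are: all
anthropometry from limb-lengthened, growth-hormone-treated or
growth-modulating-trial subjects is removed (GH deficiency without
treatment does not exclude); preterm subjects (<37 completed weeks) are
omitted before 24 months of age, re-entering at exactly 24.0 months
(boundary inclusive, reading "up to 2 years" as [0, 24)); subjects of
unknown gestation are presumed term when *every* birth measurement lies
within ±2 SD of the sex-specific achondroplasia birth reference
(`achondroplasia_birth_reference()`), and are otherwise excluded before
24 months like preterm subjects. The conjunctive reading of "birth
parameters" is deliberate: it is the conservative combination rule when no
rule is stated.

The QC layer is a documented stand-in — the original registry's cleaning
algorithms are not public — with every threshold exposed in `qc_config()`:

* exact duplicates (same subject, measure, age, value) collapse to one;
* hard physiologic bounds: length/height 20–220 cm, weight 0.3–250 kg,
  OFC 20–70 cm;
* a point far from the subject's leave-one-out interpolated trajectory
  (beyond 4 residual scales: 2 cm stature, 1.5 cm OFC, 0.10 log-weight) is
  a *unit-swap suspect* when multiplying by 2.54 (inches to cm) or dividing
  by 2.20462 (pounds to kg) lands back within 2 scales of the trajectory,
  and *implausible* otherwise;
* consecutive stature decreases beyond 2 cm before age 18 years flag the
  later point.

Weight is handled on the log scale throughout. Trajectory prediction runs
in two passes so first-pass outliers do not contaminate neighbours, and a
cohort-level binned median curve substitutes when a subject has fewer than
three points of a measure. Because linear extrapolation is a poor model at
trajectory endpoints (infancy growth is strongly curved), an endpoint flag
must be confirmed by the cohort-level band before it stands; this removes
the clean-data false positives that pure extrapolation produces at birth
measurements while leaving genuine unit swaps (which sit far from the
cohort band too) detected. Flags are annotations: points stay in the
registry, and `curve_points(drop_flagged = TRUE)` excludes them from curve
input.

## What the synthetic generator emulates

Defaults are the published cohort's printed proportions: 51.2% male,
birth-decade weights 234/231/314/356/239, 12.7% preterm, 76.0% de novo
(10.1% unknown), 20/1374 deceased, per-category lifetime surgery
probabilities 65.0/10.0/20.5/12.7/21.2%, polysomnography uptake rising from
15.0% to 81.2% across decades with decade-specific ages at first study, an
imaging mix proportional to 7201/1069/1826/166/465 studies, and
decade-specific diagnosis timing and mode distributions.

Growth trajectories come from a parametric model anchored at the published
achondroplasia birth moments (length 47.90/47.28 cm, weight 3.41/3.32 kg,
OFC 37.1/36.4 cm, with the printed SDs) and published adult sizes:

* **stature**: the median is the integral of
  $v(t) = a\,e^{-t/\tau} + b\,(1 - t/T)_+$ — a fast infancy component plus
  a linearly decaying term that reaches exactly zero at the plateau age
  $T$ (19.37/18.44 years). The closed-form zero and the linear tail make
  milestone recovery testable. A logistic pubertal spurt is deliberately
  absent; the model is a smooth monotone stand-in, not a mechanistic one.
* **OFC**: saturating exponential $c + A(1 - e^{-kt})$ with $k$ anchored so
  that 90% of the plateau value $c + A$ is attained at 11.1/11.2 months
  (closed form $\ln(10A/(A+c))/k$).
* **weight**: log-normal around a monotone log-scale median, with a
  log-SD increasing from the birth coefficient of variation to an adult
  value of 0.28 — right skew growing with age.

Spread is split into a per-subject centile offset (constant over life, so
children track their centile and within-subject velocity noise stays small)
plus measurement noise (0.5 cm stature, 0.3 cm OFC, 0.015 log-weight);
their sum matches the printed birth SDs. Preterm subjects (and the same
share of latent preterm among unknown-gestation subjects) carry an infancy
deficit proportional to weeks below 37, decaying over the first year — the
contamination the preterm exclusion exists to keep out.

Visit spacing is not documented for the source registries, so the generator
uses Gamma-distributed gaps with age-dependent means (3 months in infancy,
9 in childhood, 12 in adolescence, 18 in adulthood) and flags this in the
provenance string. One root seed expands into per-subject substreams, so
subject $k$'s data are invariant to cohort size and the whole registry is
bit-reproducible.

What generated data do **not** show: secular trends, site effects,
informative visit timing (sick children visiting more), measurement rounding
to clinical precision, pubertal spurts, or correlated measure errors.
Passing parameter-recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to every feature of real
registry data.

## Numerical choices

* Quantiles: type-7 order statistics (continuous, oracle-checkable).
* Percentage rounding: half-up to one decimal (`round_half_up()`), the
  convention that reproduces the printed summary-table arithmetic.
* Ages: months internally, converted from days as days/30.4375; years =
  months/12. Unknown categories are first-class in memory and empty strings
  on disk; serialized row and column order is fixed so round trips are
  byte-identical.
* Degenerate inputs: percentile windows below `min_n` yield gaps, not
  estimates; smoothing requires at least 10 estimable grid ages per
  (segment of a) curve; `birth_stats` with $n < 2$ reports no SD or CI;
  velocity needs two eligible points; an empty cohort is a valid registry.
* The linear-tail milestone fit requires at least 4 bins in the decline
  window and a negative slope, returning `NA` otherwise.

## Problem sizes used in tests

The test suite exercises oracle equivalence (windowed quantiles, velocity
pairing, all six summary engines against independent brute-force tallies)
on 100 generated registries of 12 subjects; parameter recovery on a
1,000-subject cohort (about 500 per sex, roughly 60,000 measurement
points), where the constructed median curves recover the generator's truth
to well under 1 cm (stature), 0.5 cm (OFC) and 5% (weight), the
velocity-zero age to under half a year and OFC attainment to under half a
month; QC sensitivity on about a thousand points at 5% corruption (recall
above 0.9, zero flags in the noiseless limit); and closed-form agreement of
the milestone readers to $10^{-6}$. These sizes were chosen as the smallest
that leave clear daylight between expected estimator error and the stated
tolerances.

## Known limitations

Pooling all points regardless of subject ignores repeated measures, so
percentile curves weight frequently measured children more heavily — the
same limitation the source procedure carries. The QC layer is a documented
reconstruction, not the original algorithms. LMS/GAMLSS re-estimation of
cohort curves is deliberately out of scope: the implemented procedure is
windowed-empirical percentiles plus splines. The synthetic average-stature
reference (`synthetic_reference()`) is a smooth stand-in for external
standards, adequate for exercising comparisons but not a published
standard. The active subcohort is derived from the last-encounter date
(on or after 2017-01-01), a reconstruction of "still in clinical
follow-up".
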