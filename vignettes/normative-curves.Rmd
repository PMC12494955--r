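---
title: "Normative reference curves, field-strength robustness, and atrophy assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative reference curves, field-strength robustness, and atrophy assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainref)
```

## The problem

Regional brain volumes shrink with age, and neurodegenerative disease
accelerates that decline in specific structures — most prominently the
hippocampus and amygdala in Alzheimer's disease, accompanied by enlargement
of the adjacent inferior lateral ventricle.  Normative modeling turns this
into a usable diagnostic signal: fit lifespan *reference curves* of a
volume against age in cognitively normal (CN) subjects, and call atrophy
when an individual's volume falls below the lower bound of the normative
band at their age.

Two practical obstacles motivate everything in this package:

1. **Head size and sex.** Larger heads have larger structures.  All volumes
   are therefore expressed as a percentage of intracranial volume (ICV),
   `100 * volume / icv`, which also removes most of the apparent sex
   difference.
2. **Machine effects.** Pooled cohorts mix scanners and field strengths
   (1.5T vs 3T), and segmentation pipelines respond to the different
   contrast-to-noise regimes.  A measurement bias of a few percent is
   comparable to early disease effects, so before reference curves are
   trusted, their stability across field strengths has to be quantified —
   and tested against chance.

## The model: shape-constrained expectile P-splines

The normative band is built from three *expectile* curves at levels
$\tau = 0.05, 0.50, 0.95$.  The $\tau$-expectile of a distribution
minimizes the asymmetrically weighted squared loss
$\sum_i w_i(\tau)\,(y_i - e)^2$ with $w_i = \tau$ for $y_i > e$ and
$1-\tau$ otherwise; the 0.5-expectile is the mean.  Expectiles are
smooth-loss analogues of quantiles: the 0.05-expectile of a Gaussian sits
near its 13th percentile, so the expected "atrophy rate" in healthy
controls is around 12–13%, not 5% — a point to keep in mind when reading
the rates below.

A curve $f_\tau(\text{age})$ is expanded in `basis_size = 20` cubic
B-splines on uniform knots spanning the observed age range and fitted by
iteratively reweighted penalized least squares on the objective

$$\sum_i w_i(\tau)\bigl(y_i - f_\tau(a_i)\bigr)^2
  + \lambda \lVert D_2 \beta \rVert^2,$$

where $D_2$ takes second differences of the coefficients (the standard
P-spline penalty).  Numerical conventions that matter:

* **Standardization.** The response is centered and scaled before fitting,
  so `lambda` (default 1) acts on standardized data and the fit is exactly
  translation- and scale-equivariant.
* **Shared smoothness.** `lambda = "gcv"` selects the penalty on a 13-point
  log grid ($10^{-3}$–$10^3$) by generalized cross-validation at
  $\tau = 0.5$ only; the chosen value is reused for 0.05 and 0.95 so the
  three bounds have comparable smoothness.
* **Shape constraints.** Lifespan trajectories should not wiggle on short
  time scales.  `smoothing = "concave"` (the default used for hippocampal
  curves) penalizes positive second differences of the coefficients with an
  iterated weight of $10^9$ — a sufficient condition for concavity of the
  spline on uniform knots.  `"convex"` is the mirror image.
* **Minimum knot resolution.** Knot spacing never drops below one year:
  age structure finer than the reporting grid is not modeled, which also
  makes a degenerate single-age cluster collapse cleanly to the scalar
  expectile.
* **Convergence** is declared when fitted values change by less than
  $10^{-6}$ (relative) — coefficients themselves can be arbitrary on
  ill-conditioned designs — within 100 iterations; non-convergence is
  flagged in `fit_meta`, not raised.
* **Non-crossing.** Expectile levels fitted independently can cross in
  sparse age regions; crossings are repaired by pointwise sorting and
  counted in `fit_meta$crossings_repaired`, with a warning unless
  `quiet = TRUE`.
* Curves are evaluated on an integer-aligned age grid (step 1 year) by
  linear interpolation, and never extrapolated beyond the observed ages.
  Aligning grids to multiples of the step makes curves from different data
  subsets directly comparable on their overlap.

## Comparing curves across field strengths

`compare_curvesets()` computes five error metrics between a reference
series $A$ and a compared series $F$ on the common grid, separately for
the lower/mean/upper bounds.  All are zero for identical curves,
sign-agnostic and invariant to joint rescaling:

| metric | definition |
|---|---|
| sMAPE  | $100 \cdot \tfrac1n \sum 2\lvert F-A\rvert / (\lvert A\rvert + \lvert F\rvert)$ |
| sMSPE  | $100 \cdot \tfrac1n \sum \bigl[2\lvert F-A\rvert / (\lvert A\rvert+\lvert F\rvert)\bigr]^2$ |
| wMAPE  | $100 \cdot \sum \lvert F-A\rvert / \sum \lvert A\rvert$ |
| sMdAPE | $100 \cdot \operatorname{median} 2\lvert F-A\rvert / (\lvert A\rvert+\lvert F\rvert)$ |
| MASE   | $\operatorname{mean}\lvert F-A\rvert / \operatorname{mean}\lvert \Delta A\rvert$ |

These are one dialect of a family of definitions (the symmetric forms
divide by $(\lvert A\rvert+\lvert F\rvert)$, i.e. twice the mean
magnitude; sMSPE squares the ratio before averaging and multiplies by
100); the dialect is fixed here and documented rather than claimed
canonical.  In the field comparison the **1.5T-only curves are the
reference $A$** and the 3T-only curves the compared $F$ — with a uniform
multiplicative 3T bias $b$, the mean-bound wMAPE then equals
$100\,(b-1)$.  MASE is included because it behaves badly on exactly the
kind of smooth, nearly flat series reference curves are: its naive
denominator $\operatorname{mean}\lvert A_{i}-A_{i-1}\rvert$ collapses, and
`subsample_step` exposes how strongly its value depends on the number of
points kept.  One deliberately asymmetric quantity lives elsewhere: the
cohort-level *median percent field difference* uses the 3T median as the
denominator, `100 |med(V3T) - med(V1.5T)| / med(V3T)`, the convention that
reproduces the published 1.89% example from medians 3.63/3.70 cm³.

### The label-shuffling null

An observed sMAPE of, say, 1.7% between per-field curves means nothing by
itself: two random halves of the same cohort produce nonzero metrics too.
`bootstrap_field_bias()` therefore permutes the field-strength labels
across subjects (the label multiset is fixed, so group sizes are preserved
exactly), refits both curve sets and recomputes the metrics, `B = 10000`
times by default.  A bias is declared when the true-label value falls
outside the empirical 5th–95th percentile range of the null (type-7
linear-interpolation quantiles — immaterial at $B = 10^4$, but it must be
frozen for test-scale $B$).  Although the procedure is often called
bootstrapping, it is a permutation scheme: labels are shuffled without
replacement, which keeps the two-sample structure intact.

Because the subjects' ages never change under permutation, the internal
engine precomputes one design matrix on a basis spanning the full CN age
range and shares it between the two per-field fits; each per-field curve
is still evaluated only inside its own observed age range, and metrics are
taken on the overlap.  This differs slightly from calling
`fit_reference_curves()` twice (which builds knots from each subset's own
range) and is what makes $10^4$ refits tractable.

Under an exchangeable null the two-sided 5%+5% test flags about 10% of
replicates (plus an $O(1/B)$ discreteness excess at small $B$); the test
suite verifies a per-(bound, metric) flag rate of $0.10 \pm 0.05$ over 200
replicate cohorts at $B = 199$, and ≥ 90% power against a 5%
multiplicative 3T bias at 500 subjects per field group.

## Atrophy and the HAVAs composite

`call_atrophy()` flags a record when its normalized volume is *strictly*
below the $\tau = 0.05$ curve at the subject's age.  Classification
reports take AD as the positive class: sensitivity is the AD atrophy rate,
specificity the CN non-atrophy rate, balanced accuracy their exact
average.  The AUC needs a continuous marker, which the source tables never
specify; the convention chosen here is the scale-free *deviation score*

$$d = \frac{\text{value} - \text{mid}}{\max(\text{mid} - \text{lower},\ \varepsilon)},$$

centered at the mid curve and scaled by the local lower spread ($d = -1$
exactly on the lower bound).  AUC is the Mann–Whitney probability (ties
counted ½) that an AD record has higher $-d$ than a CN record.  Method
comparisons use McNemar's test on paired calls: continuity-corrected
$\chi^2 = (\lvert b-c\rvert - 1)^2/(b+c)$, with the exact two-sided
binomial p-value substituted when $b + c < 25$.

The **HAVAs** composite (hippocampal-amygdalo-ventricular atrophy score)
aggregates the three AD-sensitive structures per side: each ICV-normalized
volume is z-scored against the CN reference cohort, the raw composite is
$z_{hip} + z_{amy} - z_{vent}$, and the composite is z-scored again
against the same reference.  The z-statistics use the *global lifespan*
CN mean and SD (sample, $n-1$) — not age-binned statistics; age-dependence
is then handled by fitting reference curves to the normalized composite
itself.  Sides are scored independently, with no bilateral averaging.
Because the composite accumulates three correlated disease signals, its
AUC dominates the single-structure hippocampal AUC in the simulation
suite (≥ 40 of 50 replicates), mirroring the motivation for the score.

Repeated-scan designs (the same subjects scanned at many sites in a short
window) are summarized by `stability_report()`: per subject, the fraction
of sessions agreeing with the majority call, with ties resolving to the
non-atrophied side.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws ages uniformly on 7–94 years (the pooled
lifespan range of the kind of multi-cohort data the method targets; an
irregular pooled age histogram is deliberately not imitated — uniform
coverage maximizes the curve fits' testability), sex at 51.2% female, ICV
from sex-specific normals (F: 1380 ± 100, M: 1550 ± 110 cm³), and
per-structure %ICV trajectories:

* hippocampus: concave-quadratic, peak 0.25 %ICV at 35 y, losing
  0.004 %ICV per squared decade (about a third of peak volume by the 90s);
* amygdala: concave-quadratic, peak 0.090 %ICV at 40 y;
* inferior lateral ventricle: flat to 40 y, then *growing* 0.010 %ICV per
  decade.

Measurement noise is additive Gaussian on the %ICV scale with
per-structure SDs (0.020 / 0.008 / 0.006) — a single global SD would be
unrealistic across structures an order of magnitude apart.  Field bias is
**multiplicative** on 3T scans (volumetric biases scale with structure
size); AD effects are multiplicative (0.8 hippocampus, 0.85 amygdala, 1.4
ventricle); traveling-subject site perturbations are **additive** (
short-interval scan–rescan error does not scale with the structure).
68.4% of scans are 3T by default.  Every cohort is deterministic given its
seed (one seeded stream per cohort, fixed draw order), and the latent
noise-free values are attached for oracle tests.

What it does *not* emulate: realistic MRI physics, scanner-model or
sequence taxonomies beyond the single field factor and site noise,
non-Gaussian segmentation failure modes, longitudinal within-subject
decline, or correlated multi-structure noise.  Passing tests therefore
demonstrate the *statistical machinery* — calibration of the permutation
test, recovery of injected effects, correctness of the metrics and
classifiers — not segmentation accuracy on real images.

## Problem sizes and presets

Four frozen scenarios (`preset_scenarios()`) drive the test and
acceptance suites: `null_field` (600 CN, balanced fields, no bias — the
exchangeable null), `biased_field_5pct` (1000 CN, 5% 3T hippocampal
bias), `ad_contrast` (1000 CN + 1000 AD, full structure set) and
`traveling` (9 subjects × 12 sites).  Calibration runs 200 replicates at
$B = 199$ and power runs 50 replicates — sizes chosen so the whole suite
completes in minutes while keeping Monte-Carlo error well inside the
stated tolerances; production analyses should use the default
$B = 10000$.

## Worked example

```{r example, eval = FALSE}
cfg <- preset_scenarios("ad_contrast")
co <- generate_cohort(cfg)
cn <- normalize_by_icv(subset_cohort(co, co$group == "CN"))

curves <- fit_reference_curves(cn, "left_hippocampus",
                               smoothing = "concave", subset = "combined")
ok <- co$age >= min(curves$age_grid) & co$age <= max(curves$age_grid)
calls <- call_atrophy(normalize_by_icv(subset_cohort(co, ok)), curves)
classification_report(calls[calls$group == "AD", ],
                      calls[calls$group == "CN", ])
```

## Known limitations

* Expectile bounds are not quantiles; rates under the 0.05 curve hover
  near 13% in Gaussian controls.  This matches the behavior of
  expectile-based normative tooling but must not be read as a 5th
  centile.
* The deviation-score AUC convention is an implementation choice; AUCs
  are comparable within this package, not against publications using a
  different marker.
* The permutation engine shares one basis across field groups for speed;
  curve values can differ in the fourth decimal from per-subset-knot fits.
* `lambda` is fixed (or GCV-selected at the mean) rather than selected
  per expectile level; sparse age extremes rely on the non-crossing
  repair.
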