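# brainref

Normative brain-volume reference curves, their robustness to MRI field
strength, and atrophy assessment.

## What problem this solves

Volumetric MRI analysis detects neurodegeneration by comparing an
individual's regional brain volumes — normalized by intracranial volume
(ICV) — against lifespan *reference curves* fitted on cognitively normal
(CN) subjects: atrophy is called when a volume falls below the lower bound
of the normative band at the subject's age.  But pooled cohorts mix 1.5T
and 3T scanners, and field-strength measurement biases of a few percent
are the same size as early disease effects.  Anyone building or validating
such reference curves needs to (a) fit them robustly, (b) quantify how
much they move between field strengths, (c) test whether that movement
exceeds chance, and (d) check that atrophy detection still works.  This
package does all four, end to end, with a synthetic cohort generator so
every stage is testable without imaging data.

## The model

Reference bands are **expectile curves** at levels τ = 0.05 / 0.50 / 0.95,
fitted as penalized cubic B-splines (P-splines): the curve f minimizes

    Σᵢ wᵢ(τ) (yᵢ − f(ageᵢ))² + λ ‖D₂β‖²,   wᵢ = τ if yᵢ > f(ageᵢ), else 1 − τ

by iteratively reweighted penalized least squares, with optional concave or
convex shape constraints (iterated quadratic penalty on coefficient second
differences) keeping lifespan trajectories physiologically plausible.

Curve pairs (1.5T-only vs 3T-only) are compared per bound with five
scale-invariant error metrics — sMAPE, sMSPE, wMAPE, sMdAPE, MASE — and the
observed values are tested against a **label-shuffling permutation null**:
field labels are permuted across subjects (group sizes preserved), both
curve sets refitted and metrics recomputed, B = 10000 times; a bias is
flagged when the true-label value falls outside the null's 5th–95th
percentile range.

Atrophy is called strictly below the τ = 0.05 curve, summarized by
sensitivity / specificity / balanced accuracy / AUC and McNemar tests, and
complemented by the **HAVAs composite**
z(hippocampus) + z(amygdala) − z(inferior lateral ventricle), z-normalized
twice against the CN reference.  See the methods vignette
(`vignettes/normative-curves.Rmd`) for every convention and default.

## Worked example

```r
library(brainref)

cfg <- preset_scenarios("ad_contrast")          # 1000 CN + 1000 AD, seeded
co  <- generate_cohort(cfg)
cn  <- normalize_by_icv(subset_cohort(co, co$group == "CN"))

curves <- fit_reference_curves(cn, "left_hippocampus", smoothing = "concave")
curves
#> <expectile_curveset> left_hippocampus [combined, concave smoothing], ages 8-93, taus 0.05/0.5/0.95, n=1000

ok    <- co$age >= min(curves$age_grid) & co$age <= max(curves$age_grid)
calls <- call_atrophy(normalize_by_icv(subset_cohort(co, ok)), curves)
classification_report(calls[calls$group == "AD", ],
                      calls[calls$group == "CN", ])
#> <classification_report> sens=0.809 spec=0.866 bacc=0.837 auc=0.922 (TP=793 FN=187 TN=851 FP=132)

observed_field_metrics(cn, "left_hippocampus")
#>       smape smspe wmape smdape
#> lower 2.111 0.055 2.080  2.192
#> mean  1.655 0.034 1.680  1.600
#> upper 1.359 0.025 1.366  1.337
```

Reading the numbers: 80.9% of synthetic AD subjects (hippocampal volumes
reduced ×0.8) fall below the lower reference bound, against a 13.4%
false-positive rate in controls — the 0.05-*expectile* of a Gaussian sits
near its 13th percentile, so ~13% is the expected healthy rate, not an
error.  The per-field curve discrepancies of 1–2% (sMAPE) are what chance
alone produces at this sample size; `bootstrap_field_bias()` is the formal
test.

A full run (simulate → fit → compare → permutation test → atrophy/HAVAs
reports, with a JSON manifest) is one call:

```r
run_pipeline(list(preset = "ad_contrast", B = 1000, seed = 1,
                  out_dir = "run1"))
```

or, from a shell, `Rscript inst/scripts/brainref-run.R --config run.yaml`.

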