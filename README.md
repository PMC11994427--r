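# thyrospina

Structure-parameter-inference (SPINA) analysis of pituitary–thyroid
homeostasis for pediatric cohorts. The package is aimed at endocrinology
researchers who have paired serum TSH/FT4 measurements — typically a mix of
euthyroid children and children with subclinical hypothyroidism (SH) — and
want to look past the univariate reference ranges at the *functional*
quantity behind them: the thyroid's maximum stimulated secretory capacity.

## What it computes

**SPINA-GT.** From a paired measurement at equilibrium,

```
GT = beta_T * (D_T + TSH) * (1 + K41*[TBG] + K42*[TBPA]) * FT4 / (alpha_T * TSH)
```

with TSH in mIU/L, FT4 in pmol/L (converted internally to mol/L) and GT in
pmol/s (reference range 1.4–8.7). Defaults: `alpha_T = 0.1 L^-1`,
`beta_T = 1.1e-6 s^-1`, `D_T = 2.75 mIU/L`, binding factor
`1 + K41*TBG + K42*TBPA = 6901`. GT is strictly decreasing in TSH at fixed
FT4 and linear in FT4 at fixed TSH; `invert_gt()` is the exact algebraic
inverse, used by the synthetic-cohort generator.

**Predicted TSH and predicted GT.** A published population TSH–FT4 curve —
two negative log-sigmoid branches in `ln TSH` vs FT4, switching at
12 pmol/L — gives the TSH a population-average child would show at a
subject's FT4 (`predict_ln_tsh()`), and from it the predicted capacity
(`predict_gt()`). Actual-below-predicted GT localises a subject's set point
relative to the population curve.

**Cohort pipeline.** `analyze_cohort()` classifies subjects (euthyroid
TSH ≤ 4.5 mIU/L; mild SH 4.5–10; severe SH > 10), bins the euthyroid group
into TSH quartiles, summarises actual and predicted GT and thyroid-antibody
positivity (> 34 IU/mL, and/or across TG-Ab and TPO-Ab) per stratum, and
runs the standard comparisons (Welch t-test, ANOVA + Tukey, chi-squared).

**Synthetic cohorts.** `generate_cohort(synthetic_spec(seed = ...))` draws
per-subject set points (lognormal capacity × Normal FT4), derives the true
TSH by inverting the GT formula, adds 5% assay noise and rejects into the
group TSH windows; `recovery_experiment()` validates the whole pipeline
against the generator's hidden truth table.

## Worked example

```r
library(thyrospina)

compute_gt(tsh = 6.7, ft4 = 15.7)
#> [1] 1.680975

cohort <- generate_cohort(synthetic_spec(seed = 42))
fit <- analyze_cohort(cohort$subjects)
fit$strata[, c("stratum", "n", "tsh_min", "tsh_max",
               "gt_actual_median", "gt_predicted_median")]
#>   stratum       n tsh_min tsh_max gt_actual_median gt_predicted_median
#> 1 Q1           79   0.653    2.32             2.93                2.28
#> 2 Q2           78   2.32     2.92             2.38                2.51
#> 3 Q3           78   2.93     3.65             2.19                2.81
#> 4 Q4           78   3.66     4.47             1.92                2.50
#> 5 mild_SH     167   4.50     9.82             1.90                3.81
#> 6 severe_SH    16  10.0     14.4              1.81                6.49

stratum_gt_ordering(fit)
#> $core
#> [1] TRUE
#> $full
#> [1] TRUE
```

Reading the output: at the SH group's typical values (TSH 6.7 mIU/L, FT4
15.7 pmol/L) the estimated capacity is ≈1.68 pmol/s — inside the reference
range, but well below euthyroid levels. In the simulated cohort the median
actual capacity falls monotonically from the first euthyroid TSH quartile
(2.93 pmol/s) through mild (1.90) to severe SH (1.81), while the predicted
capacity — a function of FT4 only — rises with TSH stratum; every SH
subject sits above the predicted TSH curve and hence below their predicted
capacity. The chi-squared contrast of antibody positivity between the SH
and euthyroid groups in this run gives p ≈ 0.003.

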