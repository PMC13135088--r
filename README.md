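# bctrisk

An end-to-end, testable pipeline for **opportunistic CT-based hip-fracture
risk assessment**. Millions of older adults get an abdominal–pelvic CT each
year for unrelated indications; those scans already contain the three
biomechanical determinants of hip fracture — fall risk (muscle size and
quality), impact force (subcutaneous fat padding, skeletal size) and
femoral strength (bone density distribution). `bctrisk` implements a 0–100
risk score integrating nine such factors, together with everything needed
to validate it without access to patient data.

The package is aimed at quantitative researchers in osteoporosis screening
and at methodologists who want a fully reproducible reference
implementation of this class of case-cohort diagnostic study.

## What it implements

**The score.** A logistic model on age, femoral strength, and six
image-derived traits — trabecular/cortical BMD ratio, posterior
subcutaneous fat thickness, gluteus maximus area, gluteus medius/minimus
intramuscular fat, femoral neck volume, hip width — with no sex term:

    logit(p) = b0 + Σ bj·xj + c_sex,   score = 100 · logistic(logit)

The per-sex constant `c_sex` is calibrated (not fitted to outcomes) so
that each sex's fraction scoring ≥ 75 equals its fraction at high risk by
FRAX (10-yr hip risk ≥ 3.0%) in a random population sample. That shift is
rank-preserving within sex, so AUC, sensitivity and specificity are
provably unchanged.

**Trait extraction** (`measure_all_traits()` and constituents): femoral
head localisation by distance-transform peaks, the 10-mm rotated
transverse section through both head centres, threshold + connected-
component muscle segmentation, the biphasic muscle/fat HU mixture model at
50 keV, the density-or-2-mm-shell cortical rule, and the stated left/right
combination rules (minimum for muscle area and fat thickness, mean for
intramuscular fat).

**Synthetic substrates with ground truth**: a parametric hip phantom whose
trait values are closed-form (`phantom_spec()`, `generate_phantom()`), and
a case-cohort simulator with a known logistic outcome model, age-matched
random sample, 1:1 per-sex case:control sampling, dropouts, late
fractures and treated patients (`cohort_spec()`, `generate_cohort()`).

**Evaluation**: horizon recoding with an exclusion ledger, rank-based AUC
with DeLong variance, DeLong's paired test, sensitivity/specificity with
binomial CIs, diagnostic odds ratios (`recode_outcomes()`, `auc()`,
`delong_test()`, `sensitivity_specificity()`).

**Clinical effectiveness**: `PPV = S × PopFR / TestPR` and preventable hip
fractures per 1000 tested `= S × PopFR × E × 1000` (E = 0.53,
alendronate), threshold sweeps, and high/very-high risk classification
against FRAX reference PPVs.

## Worked example

Simulate a study, fit and calibrate the score, and evaluate it:

```r
library(bctrisk)
res <- run_pipeline(cohort_spec(seed = 1), pipeline_config(seed = 1))

res$model
#> <bct_risk_model> (sex-calibrated)
#>   intercept  -4.924
#>   age                0.04996
#>   strength           -0.001188
#>   ...
#>   sex offsets F 1.773  M 1.155; high-risk threshold 75

res$per_sex$F$auc_bct
#> AUC 0.883 (95% CI 0.871-0.895; 1317 cases, 1411 controls)

res$per_sex$F$delong_bct_vs_bmd
#> AUC 0.883 vs 0.741, difference +0.142, z = 17.58, p = 3.5e-69 (DeLong)

res$per_sex$F$metrics_bct
#> threshold >=75: sens 86.5% [84.6-88.3], spec 72.2% [69.9-74.6], DOR 16.6 [13.7-20.2]

res$effectiveness$women_ge65$sweep[, c("threshold", "positive_rate",
                                       "sensitivity", "ppv",
                                       "preventable_per_1000", "risk_class")]
#>   threshold positive_rate sensitivity  ppv preventable_per_1000 risk_class
#> 1        75          31.8        86.5 15.7                   26       high
#> 2        80          26.5        83.3 18.1                   26  very_high
#> 3        85          21.1        77.0 21.1                   24  very_high
#> 4        90          14.8        67.6 26.4                   21  very_high
#> 5        95           7.8        48.5 36.1                   15  very_high
```

Reading the output: the score separates future hip-fracture cases from
controls far better than the BMD T-score on the same synthetic patients
(AUC 0.883 vs 0.741, DeLong p < 1e-68). At the calibrated threshold of
75, 31.8% of the random sample tests positive — by construction the same
fraction as FRAX ≥ 3.0% — with 86.5% sensitivity. Each sweep row's PPV is
classified against the FRAX 3.0%/4.5% reference PPVs from the same
stratum: here every threshold of 80+ identifies women at a "very high
risk" level of 5-yr fracture probability.

The closed-form clinical arithmetic is available directly:

```r
ppv(effectiveness_inputs(S = 0.759, pop_fr = 0.058, test_pr = 0.346))
#> [1] 12.7
preventable_per_1000(effectiveness_inputs(0.814, 0.058, 0.345))
#> [1] 25
dor_from_rates(sens = 47.8, spec = 92.9)
#> [1] 12
net_gain(81.4, 80.0, 47.8, 92.9)
#> [1] 20.7
```

A thin command-line wrapper (`exec/bctrisk`) exposes the stages as
subcommands (`simulate-cohort`, `simulate-phantom`, `extract-traits`,
`fit`, `score`, `evaluate`, `effectiveness`,
`reproduce-worked-examples`); run it without arguments for usage.

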