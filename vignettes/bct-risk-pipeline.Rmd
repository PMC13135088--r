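---
title: "Methods: an integrative CT-based hip-fracture risk score, simulated and validated end to end"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an integrative CT-based hip-fracture risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bctrisk)
```

## The problem and the model

Hip fracture has three biomechanical determinants: fall risk, the impact
force delivered to the hip, and the breaking strength of the proximal femur.
A routine abdominal-pelvic CT scan, taken for any indication, carries
information about all three — muscle size and quality relate to fall risk,
subcutaneous fat thickness and skeletal size to impact force, and bone
density distribution to strength. `bctrisk` implements a risk score that
integrates nine such factors into a single 0–100 metric:

* **age** and **femoral strength** (strength is an input covariate here; in
  clinical practice it comes from finite-element analysis of the CT scan);
* six image-derived physical traits: the **trabecular/cortical BMD ratio**
  of the proximal femur, posterior subcutaneous **fat thickness** below the
  femoral head, gluteus maximus **muscle area**, **intramuscular fat**
  fraction of the gluteus medius/minimus, **femoral neck volume**, and
  **hip width** (the 3-D distance between femoral head centres).

The score is a logistic model on the raw covariates, with no sex term:

$$\mathrm{logit}(p) = \beta_0 + \sum_{j} \beta_j x_j + c_{\mathrm{sex}},
\qquad \mathrm{score} = 100 \cdot \mathrm{logistic}(\mathrm{logit}).$$

The per-sex constant $c_{\mathrm{sex}}$ is *not* fitted to outcomes. It is
calibrated afterwards so that, in a random sample of the screening
population, the fraction of each sex scoring at or above the high-risk
threshold (75) equals the fraction at high risk by FRAX (10-yr hip risk
$\ge$ 3.0%). Because adding a constant to the logit is a rank-preserving
transformation within sex, this calibration provably leaves per-sex AUC,
sensitivity and specificity unchanged — a property the test suite asserts
exactly rather than approximately.

Because the cohort that motivated this design is not public, the package is
organised around two synthetic substrates with known ground truth: a
parametric voxel phantom of the hip for the image-analysis stages, and a
case-cohort simulator for the statistical stages. Everything downstream of
those substrates is the same code a real analysis would use.

## The phantom: closed-form anatomy

`phantom_spec()` describes a stylised hip in world millimetres (x
left–right, y posterior–anterior, z inferior–superior): two spherical
femoral heads with cylindrical necks, a 2-mm cortical shell (1.2 g/cm³)
around a trabecular interior (0.3 g/cm³), three gluteal muscles per side as
ellipsoids filled with a muscle/fat mixture, a posterior subcutaneous fat
slab per side, and air elsewhere. Bone HU follow an affine density-to-HU map
(slope 800 HU per g/cm³); pure muscle and fat sit at +60 and −120 HU, the
nominal values at a 50 keV effective energy.

Every trait the extraction stage measures has a closed-form value from the
spec alone — ellipse cross-section areas $\pi a b$, cylinder volume
$\pi r^2 L$, compartment density ratios, Euclidean distances — so
`generate_phantom()` returns ground truth computed from geometry, never
from voxels. That makes the phantom a genuine oracle: voxelisation and
algorithmic error are visible, not absorbed.

Extraction choices worth knowing:

* Femoral heads are located at the two dominant peaks of the interior
  Euclidean distance transform of the bone mask (a sphere centre is the
  deepest interior point), refined by a deep-interior centroid. A compiled
  Felzenszwalb distance transform (`src/geometry.cpp`) supplies exact
  distances with anisotropic spacing.
* The head section is the 10-mm transverse slab rotated about the
  anterior–posterior axis to contain both head centres; slab membership is
  by voxel centre, ties at half-thickness included.
* Muscles are segmented by an HU window (default −50 to 150) plus
  6-connected components — a deliberate, documented stand-in for the
  segmentation network used on clinical scans, adequate because phantom
  compartments are known. Cross-sectional area divides slab volume by the
  effective slab thickness (span of included layers plus one layer step),
  which removes the half-voxel inflation a naive division produces.
* The fat-fraction measurement erodes the segmented mask by 1 mm before
  averaging the per-voxel mixture fractions
  $f = (\mathrm{HU}_{\mathrm{muscle}} - \mathrm{HU}) /
  (\mathrm{HU}_{\mathrm{muscle}} - \mathrm{HU}_{\mathrm{fat}})$, clamped to
  $[0,1]$. The erosion excludes partial-volume boundary voxels, which are
  the dominant noise path for this trait.
* Posterior fat thickness samples the posterior ray from each head centre
  with trilinear interpolation and measures between the muscle–fat and
  fat–exterior threshold crossings at sub-voxel positions. On a 1-mm grid
  the layer quantisation bounds the error at about one voxel.
* The cortical compartment is every bone voxel with density ≥ 1.0 g/cm³
  *or* within 2 mm of the periosteal surface (ties at exactly 2 mm
  cortical); the region of interest runs from just below the head-centre
  plane to just below the trochanter landmark (5-mm offsets, passed
  explicitly for phantoms).
* A trait whose anatomy is truncated by the grid is flagged missing rather
  than aborting; the imputation stage then fills it from sex- and age-based
  regressions in the random sample.

One measurement definition is genuinely ambiguous in the source material:
the medius/minimus section sits either 1.5 head diameters (the tabulated
definition) or 1.0 diameter (the prose) above the head centres. The default
is 1.5 and `trait_config(offset_in_diameters = 1)` exposes the alternative;
the package does not guess intent beyond that.

Noise-free recovery tolerances on the default phantom (asserted in the
suite): hip width within 1 voxel, areas and volumes within 3%,
trabecular/cortical ratio within 2%, intramuscular fat within 0.5
percentage points, fat thickness within 1 mm. Under 10 HU of added Gaussian
noise all six traits move by less than 1%.

What the phantom does **not** emulate: realistic femur shapes, scanner
physics (beam hardening, reconstruction kernels, metal artefacts),
surrounding organs, or a soft-tissue body outline (the phantom is
bodies-in-air, so the outer fat surface plays the skin's role). Passing
phantom tests therefore validates the geometry and arithmetic of the
measurements, not their robustness to clinical image quality — the latter
is exactly the part of the original system (a trained segmentation network
plus technician review) that is out of scope here.

## The cohort simulator: study conditions as defaults

`cohort_spec()` encodes the study design the analysis assumes:

* A source population per sex (defaults 40 000 women, 20 000 men) aged
  65–90 (ages above 90 coded as 90, mirroring the privacy-driven coding of
  the source study), with a common age distribution across sexes
  (age-matching by construction).
* Traits from a Gaussian copula in which each trait loads on the age and
  strength latents so that its within-sex $R^2$ against age and strength
  hits configured targets, traits otherwise conditionally independent. The
  default targets are the sex-averaged per-sex values of the published
  trait table. The *pooled* published values are visibly inflated by
  between-sex mean differences (most strikingly for femoral neck volume:
  ~0.01 per sex but 0.15 pooled); the simulator reproduces that inflation
  naturally through its sex gaps rather than by targeting pooled values,
  which would distort the within-sex physiology.
* Outcomes from a logistic model of the same functional form the risk model
  fits, with coefficient signs fixed by the known risk directions and
  magnitudes as per-SD defaults (strength the strongest at −1.0; fat
  thickness and hip width the weakest at ±0.35, consistent with the
  published risk-factor profile). Per-sex intercepts are solved so the 5-yr
  population risks hit 5.8% (women) and 3.4% (men).
* Case-cohort sampling: every fracture case within 10 yr enters the sample,
  plus a random sample per sex sized to the case count — giving the ~1:1
  per-sex fracture:control ratio the calibration step exists to undo.
  Late (post-horizon) fractures, dropouts (10%), and treated patients (5%,
  ≥180 medication days) exercise the recoding rules.
* FRAX 10-yr hip risk as a log-normal monotone map of the standardised true
  logit plus noise. The log-scale parameters are chosen so the marginal
  distribution matches the published random-sample characteristics
  (medians 1.7%/1.1%, interquartile ranges 0.7–4.2 / 0.5–2.5, implying
  high-risk rates of ~34.6% and ~20.0%); the latent correlation (0.75) and
  the T-score analogue (mean −1.5/−0.7, SD 1.1/1.2, latent correlation 0.8
  with strength) were set once so the comparator tests discriminate at the
  published level (AUC ≈ 0.8). With these defaults the pooled
  development/validation AUCs of the fitted score land near 0.89/0.88.
* 28 synthetic sites; the development/validation split is a pure function
  of the site label (default: sites 1–12 develop, the rest validate).

Trait marginal means and SDs beyond the published strength and T-score
values are not identifiable from public sources; the defaults are
physiologically plausible round numbers, chosen once. The between-sex gaps
for muscle area, neck volume and hip width are moderate (0.5–1 SD): large
enough to reproduce the pooled-correlation inflation and the sex
differences in the trait profile, small enough that all six traits pass the
pooled selection screens at the development-set size — as they did in the
source study.

The generator returns ground truth (generating coefficients, per-patient
true logits and probabilities) alongside the table; the fitting path never
reads it. Two deliberate mismatches between generator and fitted model are
documented rather than hidden: the generator has per-sex intercepts while
the fitted model has one (the parameter-recovery test therefore uses a
sex-homogeneous population, where the two coincide), and trait values are
clamped to physiologic ranges, which perturbs the copula correlations by
less than the Monte-Carlo tolerance at the tested sizes.

## Selection, fitting, calibration, interpretation

`select_traits()` applies the three statistical screens — weak correlation
with age and strength in the random sample ($R^2 \le 0.25$), univariate
Wald $p < 10^{-4}$, and full-model Wald $p < 10^{-4}$ — and reports an
audit table; the two curation criteria (biomechanical plausibility,
reliable measurability) are recorded as such. `fit_logistic()` is a
standard maximum-likelihood fit (IRLS, relative deviance change
$< 10^{-10}$); perfect separation aborts with an actionable message.
`calibrate_sex_offsets()` solves each sex's offset by bisection on
$[-50, 50]$ logit units (interval $< 10^{-8}$); since both the target and
achieved rates are multiples of $1/n_{\mathrm{sex}}$ over the same
patients, the match is exact barring score ties, and $\le 1/n$ always.
Ties at the score threshold count as positive (score ≥ 75), matching the
stated inequality; T-scores are positive at ≤ −2.5.

Per-trait Z-scores — the deviation from the sex-specific age-predicted
mean in units of the age-regression residual SE — are fitted on
random-sample records only, excluding the age-90-coded and any record with
an imputed trait, and pooled across race/ethnicity. The raw signed Z is
returned with an `adverse` flag giving the risk-increasing direction, so a
clinical display can star deviations that raise risk.

## Evaluation statistics

AUC uses the Mann–Whitney rank formulation with midrank ties — identical
to the ROC area of a univariate logistic model, since the fitted
probability is monotone in a single predictor — with DeLong placement
variance for CIs. `delong_test()` implements the paired comparison from
the placement covariance directly; the suite cross-checks it against an
independent implementation (pROC), against an exhaustive pair-enumeration
oracle at $n \le 50$, against a 10 000-replicate bootstrap of the AUC
difference (variance within 15%), and for null p-value uniformity
(Kolmogorov–Smirnov at $\alpha = 0.01$ over 500 replicates).

Sensitivity/specificity CIs use the normal approximation to the binomial,
truncated to $[0, 100]$. The diagnostic odds ratio is
$(\mathrm{TP}/\mathrm{FN})/(\mathrm{FP}/\mathrm{TN})$ with a
Haldane–Anscombe 0.5 correction when a cell is empty; its CI is a
log-odds Wald interval. Published CI widths for sensitivity and
specificity in the source tables are implausibly narrow for the stated
sample sizes (likely a typesetting artefact); the package implements the
stated method and does not chase those intervals.

`recode_outcomes()` applies the horizon rules — treated patients excluded,
post-horizon fractures recoded to controls if in the random sample and
excluded otherwise, non-fracturing patients without follow-up to the
horizon dropped — and returns an exclusion ledger whose counts partition
the input, a property asserted at every pipeline stage.

## Effectiveness arithmetic

With $S$ the validation-set sensitivity, PopFR the population fracture
risk (untreated random-sample patients, dropouts excluded), TestPR the
baseline positive-test rate (all random-sample patients, dropouts
included), and $E = 0.53$ the assumed treatment efficacy (alendronate):

$$\mathrm{PPV} = S \times \mathrm{PopFR} / \mathrm{TestPR}, \qquad
\mathrm{preventable\ per\ 1000} = S \times \mathrm{PopFR} \times E \times 1000.$$

The identity $\mathrm{PPV} \times \mathrm{TestPR} = S \times
\mathrm{PopFR}$ holds on unrounded values on every report row; display
rounding is half-up (one decimal for percentages, integers for counts),
and all internal arithmetic is unrounded. The preventable-count semantics
assume every positive-testing patient is treated, and the report header
says so. Risk classes compare a test's PPV (rounded to one decimal)
against the PPVs at FRAX ≥ 3.0% (high) and ≥ 4.5% (very high) from the
same patient stratum, with ties attaining the class.

The shipped worked-example fixtures record, for every published
effectiveness cell, whether the printed value is exactly recoverable from
the printed (rounded) inputs. Twenty-four of 32 PPV cells differ by
0.1–0.2 and two preventable counts by 1, the footprint of the source
report's unrounded internal sensitivities; four of twelve DOR cells differ
by up to 0.4 for the same reason. The fixtures assert exactness where it
holds and the documented bound elsewhere — the discrepancies are recorded,
not "fixed".

## Problem sizes and numerical conventions

The test suite and acceptance script run at sizes chosen to make their
statistical assertions sharp but cheap: parameter-recovery and
AUC-recovery checks use 20 seeds at roughly 3000 patients per split;
copula calibration checks use 20 seeds at 5000 per sex; the phantom checks
use one full-resolution (1 mm, 240×170×170) phantom plus a compact 2-mm
variant for rule and robustness tests. Bisection, convergence and rounding
tolerances are stated next to the code that uses them. Known limitations:
the phantom's idealised geometry (above); the simulator's conditional-
independence copula, which cannot represent trait–trait dependence beyond
what age and strength induce; FRAX and T-scores simulated as monotone
noisy maps rather than mechanistic calculators; and no competing-risk
structure — the binary-horizon outcome with dropout recoding is the
design, inherited deliberately.
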