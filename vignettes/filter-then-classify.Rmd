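---
title: "Filter-then-classify evaluation of allergy predictors: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-then-classify evaluation of allergy predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoallergy)
```

## The problem

A birth cohort is followed to 18 months; each child ends up labelled
non-allergic, IgE-mediated allergic, or non-IgE-mediated allergic /
uncertain. Candidate predictors are of two kinds: net cytokine secretion of
stimulated mononuclear cells — 18 analytes × two stimulations (LPS, PHA) ×
two durations (24 h, 96 h) × four sampling timepoints (cord blood, 2, 6,
18 months), i.e. 288 continuous variables in pg/ml — and 8 clinical
variables of mixed type. The questions are descriptive (which variables
differ between outcome groups?) and predictive (how well can a classifier
trained on a subset of variables label a new child?). These are different
questions with different pitfalls, and the package keeps them separate.

## Preprocessing model

**Background subtraction.** Each cytokine condition is measured in a
stimulated and an unstimulated well; the analysis variable is their
difference. Negative net values are retained by default: they are genuine
measurement outcomes near the detection limit, and truncation would distort
group means. A `clamp` option exists for downstream users who require
non-negative concentrations.

**Inter-plate QC.** A positive control is carried on every plate. Per
cytokine, control values beyond 1.5×IQR fences are discarded and the
cytokine is kept only if max/min of the survivors is at most 5 (and the
minimum is positive, otherwise the ratio is undefined and the cytokine is
dropped with a warning). The fence rule is our choice — the criterion
"after removal of the outliers" admits several readings — so both the rule
and the threshold are arguments. Retention is scale-invariant, which the
test suite checks by rescaling control panels.

**Missingness.** Missed visits remove whole timepoint blocks (72 conditions
at once). Variables with 50% or less available data are removed before any
model fitting — imputing a mostly-missing variable manufactures
information. The boundary is strict: a variable observed in exactly half
the patients is removed, one observed in 51% is kept.

**Two-regime imputation.** Within a training split, a missing cell is
replaced by the mean (continuous) or mode (discrete; ties to the smallest
value, for determinism) of the observed values *of the same outcome class*.
Held-out data never see class labels: their missing cells get the *global*
training mean/mode. This asymmetry is deliberate — class-conditional
imputation of test data would leak the label being predicted. The
imputation statistics object carries both sets of statistics so the two
regimes cannot be mixed up, and mutation tests assert that perturbing
held-out rows changes neither the training statistics nor the imputed
values of other rows.

## Univariate stage

Tests are dispatched on variable type: unpaired two-sample t-test
(pooled variance; a Welch switch exists to quantify sensitivity) for
continuous, Mann–Whitney for ordinal (exact null when the combined sample
is ≤ 20, normal approximation with tie correction otherwise), chi-square
without continuity correction for binary/nominal, switching to Fisher's
exact test when any expected cell count is below 5. All p-values are
two-sided; missing values are excluded pairwise. The descriptive report
adjusts with the Benjamini–Hochberg step-up over *all* m variables of the
analysis (m = 296 in the standard layout), even if only a subset is
tabulated; the ranking used inside the resampling loop orders raw p-values
(the BH transform is monotone, so ranking on adjusted values would be
identical), with lexicographic tie-breaks and undefined tests last.

## Resampling protocol

`run_protocol()` is the package's central fitting function. Per repeat it
draws a stratified 90/10 split, ranks variables on the training rows only,
imputes (class-conditionally on train, globally on test), fits each
classifier on the s best-ranked variables, and scores the held-out BCR =
(sensitivity + specificity)/2. Stratification is the default because with
15 positives an unstratified 10% test set is frequently all-negative,
leaving the BCR undefined; an unstratified option redraws degenerate splits
and errors after 10·J redraws.

The mean BCR over J = 200 repeats is reported with the Nadeau-corrected
interval: the variance of the mean is inflated to
(1/J + n_test/n_train)·s² because training sets overlap heavily across
repeats; a naive t-interval would be far too narrow. The interval is
symmetric by construction and clipped to [0, 1].

**Random-number discipline.** The master seed draws one sub-seed per repeat
up front; splits, rankings and imputations are computed once per repeat and
shared across every classifier × signature size × feature set, so adding a
model to the grid never changes the splits. Stochastic learners are
re-seeded from the repeat sub-seed, and Random Forest training rows are
put into a canonical (content-based) order before fitting, so predictions
are invariant under permutations of the supplied training rows. Identical
configurations reproduce results bit-for-bit.

## Classifiers and the clinical kernel

Random Forest (500 trees, √p candidate variables per split) consumes the
imputed matrix directly. The SVM (C = 1) and 1-NN operate on a combined
kernel: cytokine features are standardized with training means/SDs and
compared by cosine similarity; clinical variables use the clinical kernel —
per variable, (r − |x−z|)/r on the training range r for continuous/ordinal
(clipped into [0, 1] for out-of-range test values; a degenerate r = 0
contributes 1), the equality indicator for binary/nominal — averaged
without weights. Active parts are averaged, keeping both on a [−1, 1] /
[0, 1] scale; the Gram matrix is passed to the SVM as a precomputed kernel
so the clinical kernel is honoured exactly. 1-NN predicts the label of the
training sample minimising the kernel-induced distance
√(k_xx + k_zz − 2k_xz), ties to the smallest training index. Ordinal
variables are treated as continuous on their observed training range in the
kernel — the rank-scaled alternative differs only when ordinal levels are
unevenly spaced, which none of the default clinical variables are.
Hyperparameters were not tuned (the protocol contains no nested tuning
loop); all are exposed as arguments.

## The synthetic generator

`generate_cohort()` emulates the study conditions: 86/30/15 children per
class, the 288-condition grid plus 8 clinical variables, and per-timepoint
block missingness with rate 0.435 — chosen so that roughly 74 of 131
patients are complete per condition. Net concentrations follow a shifted
lognormal, value = LN(µ, σ) − 5 pg/ml, with (µ, σ) solved so the arithmetic
mean and SD on the net scale match the configured group values; the shift
allows the small negative net values that background subtraction produces
while keeping the right-skew of real Luminex data. Conditions without a
configured effect share a baseline lognormal (log-mean 3, log-SD 1, i.e.
median ≈ 20 pg/ml with ~130% coefficient of variation). Effect conditions
use the published group-mean contrasts (lower cord-blood IL-15/IL-12p70,
6-month IL-1β and 18-month VEGF in the IgE-mediated group; lower cord-blood
TNF-α/IL-15/IL-17/FGF in allergic children pooled); one condition
(IL-15/PHA/96 h at birth) is constrained by both contrasts, and its three
class means are solved jointly (3.74 / 14.81 / 25.06 pg/ml). Group SDs are
not published; we use SD = 0.5 × mean (a 50% within-group CV, typical for
stimulated-cytokine panels after QC). The number of allergic first-degree
relatives is Poisson (0.88 non-allergic vs 1.37 allergic, the only printed
clinical effect); the seven binary clinical factors use printed frequencies
where available and plausible cohort frequencies otherwise.
`generate_raw_wells()` additionally emits paired stimulated/unstimulated
wells whose difference reproduces the net cohort exactly, to exercise the
background-subtraction path.

**What the generator does not model.** Inter-cytokine correlation (each
condition is drawn independently given the class), plate effects,
detection-limit censoring, and longitudinal within-child correlation. Tests
passing on synthetic cohorts therefore certify the *pipeline* — leakage
control, calibration, ranking and aggregation logic — not the biological
effect sizes of any real cohort.

**A calibration caveat worth knowing.** With only 15 IgE-mediated children
(~8 observed per condition after block missingness) and a heavy-tailed
baseline, the extreme tail of the t-test is anti-conservative: on no-effect
cohorts roughly a third of seeds show at least one BH-significant variable
for the IgE contrast, even though the bulk of the raw p-values stays
uniform. The 45-vs-86 allergic contrast calibrates cleanly (~95% of null
cohorts yield nothing significant). Real studies with a small rare class
face exactly this phenomenon; it is a property of running t-tests on skewed
concentrations with n ≈ 8, not of the implementation.

## Problem sizes used in checks

The test suite and the acceptance script run Monte-Carlo checks at sizes we
consider sufficient for stable yes/no conclusions: 100 (tests) or 60
(script) seeds for univariate signal recovery, 50 / 30 protocol seeds for
signature recovery, J = 200 repeats everywhere the protocol is scored, and
50 seeds for null calibration. Signature-recovery checks run on the
cord-blood conditions — the setting where the injected IgE signals are the
leading effects and the clinically interesting one (prediction at birth);
on the full grid the stronger injected 6- and 18-month effects top the
signatures instead, which is the expected behaviour of a correct ranking,
not a recovery failure. A seed whose cord-blood block falls below the 50%
availability rule cannot build a cord-blood model and is counted as a
recovery failure, conservatively.

## Known limitations

- The two label tasks treat the "uncertain" children as configured
  (`allergy_task(include_uncertain = )`); the right composition is a
  clinical judgement the package does not make.
- BCR confidence intervals are symmetric Nadeau intervals; asymmetric
  intervals (e.g. from clipping or bootstrap quantiles) are not provided.
- No nested hyperparameter tuning, no alternative resampling schemes
  (k-fold, LOOCV), and no formal test between classifiers beyond CI
  overlap reporting.
- The imputation is single (not multiple); its variance understatement is
  immaterial for ranking/classification but would matter for inference on
  imputed values.
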