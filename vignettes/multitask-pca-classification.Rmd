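---
title: "Multitask ROI PCA features for patient-control classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask ROI PCA features for patient-control classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpca)
```

## The analysis problem

Task fMRI studies of clinical populations often acquire several task
contrasts per participant — here a sleep-related picture contrast, a
sleep-related sound contrast, and a Stroop (incongruent minus congruent)
contrast — and ask whether the *joint* pattern of responses separates
patients from controls better than any single task does. mtpca implements
one such analysis end to end for a two-group design (psychophysiological
insomnia patients versus healthy controls, labelled 1 and 0): the
cross-task covariance structure of regional responses is summarized per
participant by PCA, the resulting component loadings are pooled across
participants as features, sparse logistic regression picks the
discriminative regions, and a kernel SVM under leave-one-out
cross-validation (LOOCV) quantifies how well each feature family separates
the groups.

## From contrast volumes to the ROI beta matrix

Regional summaries use an AAL-style parcellation of 90 cerebral regions.
For one region and one task contrast, the ROI value is the mean of the
voxels strictly greater than 0.1 times the within-ROI maximum
(`extract_roi_value()`). The relative threshold keeps only the voxels
carrying most of the positive task response, and makes the value
scale-equivariant: multiplying a contrast volume by c > 0 multiplies every
ROI value by c. Negative-going responses are deliberately excluded; when a
region has no positive voxel at all its value is 0 and a coverage flag is
set, so the matrix shape stays fixed for the decomposition instead of
introducing missing values.

Twelve regions whose atlas masks barely overlap typical acquisition
coverage (bilateral olfactory cortex, amygdala, superior parietal gyrus,
paracentral lobule, middle temporal pole, pallidum) are dropped by a fixed
exclusion list, leaving p = 78 retained ROIs (`filter_rois(mode =
"list")`). A data-driven alternative, `mode = "coverage"`, instead drops
any region flagged uncovered in any participant. Label and contrast volumes
must share a voxel grid; no resampling is attempted, as registration
belongs to upstream preprocessing.

The result per participant is a 78 × 3 nonnegative matrix X: rows are
ROIs, columns the task contrasts in the fixed order picture, sound,
Stroop.

## Per-participant PCA across tasks

Each column of X is centered by its own mean across the 78 ROIs, the
matrix is divided by √(n − 1) with n = 3, and the singular value
decomposition X̃ = U Σ Vᵀ is taken (`subject_pca()`). ROIs are treated as
observations and task contrasts as variables: this orientation is the only
one that yields 78-dimensional loading vectors (one weight per region) and
three informative components, and it matches the convention that the
components describe covariance *between regions* across tasks. The
explained-variance proportions are the squared singular values normalized
to sum to one; the task-side scores are V scaled by the singular values.
An all-constant matrix (zero variance after centering) is a hard error
rather than a silent zero component.

Eigenvector signs are mathematically indeterminate, which matters as soon
as loadings are pooled across participants. Two conventions are applied.
Within a participant, each component is oriented so its largest-magnitude
entry is positive (first occurrence breaks ties) — deterministic and
invariant to the input sign. Across participants
(`align_component_signs()`), the elementwise median of the
convention-oriented vectors serves as a reference direction and any vector
with negative inner product against it is flipped. Because the reference
is computed from sign-invariant inputs, the operation is idempotent and
never changes any loading magnitude. With no ground-truth orientation
available in real data this is a modelling choice, not a mathematical
necessity; cross-participant features are only meaningful relative to it.

`build_feature_matrix()` stacks one aligned component per participant into
a 78 × m feature table (m = 40 at the default study size);
`build_single_task_features()` builds the single-task baseline families
directly from the beta columns. `voxel_pca()` applies the same
decomposition with voxels as observations to group-mean contrast volumes,
for rendering signed component maps at voxel resolution.

## Feature selection: L1-penalized logistic regression

For one feature family the model is logistic regression of the group label
on the 78 features with an L1 penalty λ‖β‖₁ (fits via glmnet's coordinate
descent; convergence threshold 1e-10, path warm starts). Features are
internally standardized (population SDs) and coefficients reported on the
original scale — the default of the standard tooling, flagged here because
standardization is not otherwise determined by the model statement. The
penalty grid (`make_lambda_grid()`) holds 100 log-equispaced values
descending from λmax — the smallest penalty with an all-zero solution,
computable in closed form as max_j |⟨x_j, y − ȳ⟩|/m on standardized
features — down to 0.01·λmax.

λ is chosen by leave-one-out binomial deviance
(`select_lambda_loocv()`): each participant is held out once, the path is
refit on the other m − 1, and −2[y log p̂ + (1 − y) log(1 − p̂)] is summed
over held-out cases at each λ. Held-out probabilities are clipped at 1e-8
so the deviance stays finite; ties in total deviance break toward the
larger λ, i.e. the sparser model. Summing versus averaging the fold
deviances does not change the argmin, so the sum is implemented. The
selected features are those with nonzero coefficients at the chosen λ, in
descending order of coefficient magnitude; the selection can legitimately
be empty when the null model wins.

## Classification: soft-margin RBF SVM under LOOCV

Selected features feed a C-classification SVM with the radial kernel
exp(−γ‖x_i − x_j‖²). Cost C and kernel width γ are both searched over
log-equispaced grids on [0.1, 10], 20 values per parameter by default
(`svm_config()`); the grid range follows the study design, the resolution
is a package default since none is otherwise determined. For each pair,
LOOCV accuracy is computed from pooled held-out predictions; the
maximizing pair is returned with ties broken toward the smallest C, then
the smallest γ — maximum regularization. Features are centered and
unit-scaled once on the full sample before cross-validation; this shares
scale information across folds, consistent with the default pipeline
topology (next section), and makes libsvm's internal n-fold
cross-validation (each fold a single participant, hence a deterministic
partition) usable for the grid search. The pooled predictions at the best
pair are recomputed by an explicit fold loop and always agree with the
grid accuracy.

Metrics come from the single pooled confusion matrix with patients as the
positive class, not from per-fold averages: accuracy, recall TP/(TP+FN),
precision TP/(TP+FP), specificity TN/(TN+FP), and F2 =
5·P·R/(4P + R), the recall-weighted F score. All five are computed on
exact fractions; zero-denominator cases return 0 with a flag. Display
values are rounded to two decimals with base R `round()` on the double
quotient — the convention under which the package's reconstruction
utilities exactly invert published tables (see below).

### Pipeline topology and leakage

The default topology mirrors the published procedure: LASSO selection runs
once on the full sample, and the SVM LOOCV then operates on the selected
features. Because every training fold has seen the held-out participant
during selection, the resulting metrics are optimistically biased. The
package therefore also provides `nested_svm_loocv()` (and `nested = TRUE`
in `compare_feature_sets()`/`run_pipeline()`), which re-runs penalty
selection, feature selection and the (C, γ) search inside every fold. The
default remains the replicated topology; the nested variant exists because
the leakage materially inflates small-sample LOOCV metrics and honest
error estimates need it.

## Reconstructing confusion matrices from rounded metrics

With group sizes fixed (19 patients, 21 controls), a printed recall is
TP/19 rounded to two decimals and a printed specificity TN/21; both
denominators are small enough that the rounded values usually pin down TP
and TN uniquely. `reconstruct_confusion()` searches all (TP, TN) pairs and
returns the unique matrix or the full candidate list. This turns rounded
published metrics into exact integer targets: recomputing the five metrics
from the reconstructed counts reproduces a published table to the printed
precision, including the cases where the accuracy quotient sits on a
rounding boundary (27/40 and 29/40 display as 0.68 and 0.72 under the
double-rounding convention).

## The synthetic generator

No participant-level data accompany the published analysis, so the
generator (`synthetic_config()`, `generate_dataset()`) emulates the study
conditions and provides ground truth for every downstream stage:

* **Sizes.** 19 patients, 21 controls, 78 ROIs, 3 tasks.
* **Low-rank structure.** Each participant's matrix is
  U_s · diag(s) · Vᵀ + ε, with V a fixed orthonormal task-mixing matrix
  shared by all datasets and s the configured singular values, default
  proportional to √(0.70, 0.20, 0.10) so that the zero-noise
  explained-variance proportions are 70/20/10 percent — the regime the
  per-participant decompositions of the study data occupy.
* **Group difference.** The two groups share components 1 and 3; the
  patient group's component-2 loading pattern is perturbed at six effect
  ROIs (defaults: bilateral inferior frontal gyrus pars orbitalis, right
  calcarine, right lingual, left inferior occipital, left inferior
  temporal — the regions reported as discriminative) with magnitude
  `effect_size`, then re-orthonormalized. The default effect size (0.4
  against unit-norm patterns, i.e. roughly 0.16 per effect ROI against
  typical loadings of ~0.11) is deliberately large: the generator's role
  is parameter recovery and pipeline validation, not calibration to the
  study's unknown true effect.
* **Between-subject variability.** Loading patterns receive per-subject
  Gaussian jitter (SD 0.08) followed by re-orthonormalization — a
  stand-in, since no between-subject variance model for loadings is
  published; the study's explained-variance table shows substantial
  between-subject spread, so subjects must not be identical. Entry noise
  is i.i.d. Gaussian (SD 0.02), the simplest model consistent with the
  pipeline's assumptions.
* **Positivity.** Each matrix is shifted so its minimum entry is 0.05,
  mimicking positive-voxel averaging. Patterns (and jitter) are kept
  orthogonal to the all-ones vector, so the shift and the column centering
  cancel exactly and the zero-noise decomposition returns the configured
  patterns to machine precision.
* **Seeding.** One master seed; per-subject streams are derived
  deterministically, so equal seeds give bitwise-equal datasets.
* **Voxel mode.** `generate_volumes()` emits a toy label volume plus
  per-task voxel volumes whose supra-threshold positive-voxel means equal
  the requested ROI values, with planted sub-threshold and negative
  distractor voxels, and excluded atlas regions left without positive
  signal — a complete fixture for the extraction rule.

What the generator does **not** emulate: hemodynamic time series, task
design and GLM estimation, spatial smoothness beyond ROI-level structure,
realistic noise correlations between neighbouring regions, or the study's
actual (unknown) effect size. Passing the package's simulation studies
therefore demonstrates that the pipeline recovers structure of this
planted form at these sizes — not that real multitask fMRI data carry such
structure.

## Simulation studies and problem sizes

Three multi-seed studies accompany the package and are also what the
acceptance script recomputes:

* `selection_rate_study()` — 50 study-sized replicates; the fraction in
  which LASSO on the aligned component-2 loadings selects at least one
  planted effect ROI.
* `family_dominance_study()` — 25 replicates; the fraction in which the
  component-2 family's LOOCV accuracy is at least that of each single-task
  family, with one shared 20 × 20 (C, γ) grid.
* `variance_regime_study()` — one study-sized dataset; group-mean
  explained-variance percentages against the configured 70/20/10 shares.

These sizes (50, 25, 40 × 78 × 3) are the package's chosen simulation
scale; all are deterministic given their base seed.

## Numerical conventions, in one place

* PCA sign: largest-|entry|-positive per subject; median-reference
  alignment across subjects; singular-value ties broken by decomposition
  order.
* Threshold rule: strict inequality, voxels > 0.1·max; ties at exactly
  0.1·max excluded.
* LASSO: glmnet coordinate descent, threshold 1e-10, maxit 1e5;
  standardized features, original-scale coefficients; deviance clipping
  1e-8; λ ties toward sparsity.
* SVM: full-sample feature scaling; (C, γ) ties toward smallest C then
  smallest γ; libsvm defaults otherwise.
* Display rounding: base `round(x, 2)` on double quotients, chosen because
  it exactly reproduces published tables from integer counts.
* Degenerate inputs: zero-variance PCA input, empty ROI masks, single-class
  labels, and sub-4-participant SVM samples are errors, not warnings.

## Known limitations

* With three observations per decomposition (one per task), per-subject
  component estimates are high-variance; leading axes can be driven by
  single tasks with high leverage. More tasks per participant would
  stabilize them.
* The cross-participant sign-alignment convention is one of several
  defensible choices, and pooled-loading features depend on it.
* The default pipeline topology leaks selection information across LOOCV
  folds by design (to replicate the published procedure); use the nested
  variant for honest error estimates.
* Linear PCA only; nonlinear (kernel) component analysis is out of scope.
* The generator's effect placement and magnitudes are synthetic
  conventions; recovery rates on it do not transfer to real data.

## A worked example

```{r example, eval = FALSE}
run <- run_pipeline(
  synthetic_config(seed = 1),
  svm = svm_config(resolution = 20)
)
summary(run)
```

The run generates a 40-participant dataset, decomposes each participant's
78 × 3 matrix, aligns signs, assembles six feature families (PC1-PC3,
picture, sound, Stroop), selects features and classifies per family, and
prints the explained-variance table and the per-family metric table. All
reports (`manifest.json`, `metrics.json`, per-family feature tables and
deviance curves) can be written to a directory via `out_dir` and replayed
exactly with `run_from_manifest()`.
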