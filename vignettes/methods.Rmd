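---
title: "Predicting local failure of brain metastases after SRT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting local failure of brain metastases after SRT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

About one in five brain metastases treated with hypo-fractionated
stereotactic radiotherapy (SRT) progresses locally. An a-priori marker of
local failure (LF) versus local control (LC), available from the
treatment-planning MRI before any dose is delivered, would let clinicians
consider dose escalation or alternative management up front instead of
waiting months for serial follow-up imaging.

`BrainMetRadiomics` implements such a marker as a reusable pipeline:
3D radiomic features are extracted from the contrast-enhanced T1-weighted
(CE-T1w) and T2-FLAIR planning images of each lesion; a multi-phase
selection procedure distils them into a small biomarker; a k-nearest-
neighbour (k-NN) max-voting ensemble predicts the per-lesion outcome; and
Kaplan–Meier / log-rank analysis compares the survival of the patient
cohorts implied by the predictions. Because no patient images ship with
the package, a synthetic cohort generator reproduces the data *structure*
the analysis assumes, so every stage is testable end to end.

## Pipeline stages

### Pre-processing

Each lesion arrives as a CE-T1w volume (0.5 × 0.5 × 1.5 mm) and a
T2-FLAIR volume (0.5 × 0.5 × 5 mm), with tumour, edema and brain masks on
each grid. `preprocessLesion()`:

1. resamples both volumes and their masks to an isotropic grid
   (default 0.5 mm; trilinear for images, nearest-neighbour for masks so
   they stay binary). The output grid is anchored at the input origin
   with `ceil(n * spacing / target)` voxels per axis, which never crops
   tissue;
2. normalizes intensities to zero mean and unit variance over the brain
   mask (population standard deviation), then multiplies by an intensity
   scale factor (default 100);
3. builds two margin masks by Euclidean distance transform: the
   *tumour-margin* (shell within 5 mm of the tumour) and the
   *lesion-margin* (shell within 5 mm of tumour ∪ edema), both clipped to
   the brain and excluding their source region.

The intensity scale factor deserves a note. The method pairs unit-variance
normalization with a fixed gray-level bin width of 25, which would be
degenerate on unit-variance data (every ROI would fall into one or two
bins). Rescaling by 100 makes a ±2 SD intensity range span roughly 16
bins, a typical gray-level resolution for texture analysis. The factor is
configurable (`intensity_scale`).

### Gray-level quantization

`quantizeROI()` uses fixed-width bins with edges anchored at integer
multiples of the bin width ("equally spaced from zero"): the level of a
voxel with intensity $x$ is

$$\ell(x) = \lfloor x / w \rfloor - \lfloor \min_{ROI} / w \rfloor + 1,$$

so level 1 is the bin containing the ROI minimum. The anchoring makes
quantization invariant to shifting all intensities by exact multiples of
$w$, and the per-ROI minimum makes it invariant to *any* constant shift
of the ROI. Whether the minimum should be per-ROI or per-brain is not
fixed by the method description; per-ROI was chosen because texture
matrices are computed per ROI. A consequence worth knowing: gray-level
weighted features (e.g. high-gray-level emphasis) respond to the
within-ROI intensity *spread*, not to the ROI's absolute brightness.

### Feature panel

`extractLesionFeatures()` computes, per lesion:

* 18 first-order statistics × 4 regions (tumour, edema, tumour-margin,
  lesion-margin) × 2 images;
* 24 GLCM + 14 GLDM + 16 GLSZM + 5 NGTDM texture features for the same
  region × image grid;
* 14 morphology features once per region (tumour-family regions from the
  CE-T1w-grid masks, edema-family regions from the T2-FLAIR-grid masks),

for a total of 4 × 2 × 77 + 4 × 14 = **672** features with ids
`<image>|<region>|<family>|<name>`. The published description reports a
total of 800 for the same families and regions; that total cannot be
reconstructed from the listed components, so the package reports its own
deterministic count in the feature-table header and treats the
discrepancy as unresolvable.

Texture definitions follow the community-standard (IBSI-consistent)
formulas: GLCM at distance 1 summed symmetrically over the 13 unique 3D
directions; GLDM with dependence threshold α = 0 over the
26-neighbourhood, with the dependence count d ∈ [0, 26] stored exactly
and weighted as d + 1 in size-emphasis features (so small-dependence
emphases are defined at d = 0); GLSZM zones as maximal 26-connected
constant-level sets; NGTDM over the 26-neighbourhood, ignoring voxels
with no in-mask neighbour. All four matrix builders are verified
exactly, integer for integer, against brute-force enumeration oracles on
random 4×4×4 ROIs.

Morphology uses the eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$
of the physical voxel-centre covariance: elongation
$= \sqrt{\lambda_2/\lambda_1}$ (1 for a sphere, 0 for a line), flatness
$= \sqrt{\lambda_3/\lambda_1}$, axis lengths $4\sqrt{\lambda_i}$. Mesh
volume and surface area come from a closed iso-surface built by
tetrahedral-decomposition marching ("marching tetrahedra"): each cell is
split into six tetrahedra around its main diagonal and surface vertices
sit at edge midpoints. On binary data this produces the same vertex set
as midpoint marching cubes without the 256-case tables; enclosed volumes
agree with analytic spheres to about 1% at radius 10 voxels. Maximum 3D
and per-plane 2D diameters are pairwise distances over surface vertices
(deterministically strided down above 4000 vertices to bound the
quadratic scan). Masks with fewer than two voxels return defined values
(elongation 1) instead of failing, to keep batch extraction total.

### Feature selection

`selectFeatures()` chains three phases on the training patients only:

1. **Correlation reduction** — features are grouped into connected
   components of the graph with edges where pairwise Pearson $R^2 > 0.8$;
   each component keeps its best feature by direction-corrected
   univariate rank AUC (`max(AUC, 1-AUC)`, midrank ties), with
   lexicographic tie-break. Components rather than cliques make the
   grouping deterministic and order-independent. Constant features have
   undefined correlations and form singletons.
2. **mRMR ranking** — greedy minimal-redundancy-maximal-relevance with
   the difference (MID) criterion; mutual information is estimated after
   4-quantile discretization of continuous features. The top 100 ids form
   the candidate pool.
3. **Sequential forward selection** — candidates are added greedily by
   the cross-validated score below; selection stops at `max_features`
   (10) or at the first candidate whose improvement fails the acceptance
   rule.

The score of a feature set is the mean, over class-balanced undersampled
replicates, of a patient-level stratified 5-fold cross-validated k-NN
AUC: each replicate contains every minority-class (LF) lesion plus an
equal-size without-replacement draw from the majority class; within a
replicate, folds are assigned per patient (all lesions of a patient stay
together, stratified by the patient's any-LF outcome), the k-NN is fit on
the training folds with per-fold z-scoring, validation lesions are scored
by neighbour vote fraction, and per-fold AUCs are averaged. 501
replicates are the default; 51 is the documented desk-scale setting used
in the test suite.

**Stopping rule.** The rule is necessarily invented (the method
description reports a four-feature biomarker but no rule). A pure
"accept while the mean score improves by more than 1e-4" rule measurably
overfits: with dozens of candidate features and ~140 training lesions,
some noise features correlate with the training labels by chance, their
cross-validated improvement is real *in-sample*, and held-out AUC drops
by up to 0.1. The package therefore accepts a candidate only if its mean
improvement exceeds both `min_improvement` and one standard error of the
paired per-subset improvement (the same replicates score both feature
sets, so the improvement is a paired sample of size `n_subsets`). This is
the classic one-standard-error idea applied to forward selection; it
keeps chance features out without any tuned constant.

### Outcome prediction

`fitKnnEnsemble()` trains one k-NN model (k = 5, Euclidean) per balanced
replicate, each storing its own per-feature mean/sd for z-scoring.
`predictEnsemble()` lets every model vote with the majority label of its
five nearest training points and takes the fraction of models voting LF
as the continuous score; the final label is LF iff that fraction exceeds
0.5. Odd neighbour and model counts make every vote decisive. Neighbour
distance ties break by training-point index, which makes predictions
bit-reproducible. The ROC AUC of the ensemble uses the vote fraction as
the score (the voting classifier itself has no canonical continuous
output; this is the documented package choice).

### Survival comparison

Patients with at least one LF lesion form the LF cohort (any-LF rule),
applied once to the predicted labels and once to the ground-truth labels
of the independent test set. Kaplan–Meier curves and the two-sample
log-rank test are delegated to the `survival` package behind thin
wrappers (`kmCurve`, `logrankTest`) that fix the cohort semantics, the
median definition (smallest time with S(t) ≤ 0.5, reported as NA when
never reached) and the reporting format; hand-computed product-limit and
hypergeometric examples in the test suite pin the wrapping down.

## The synthetic cohort generator

`generateCohort()` emulates the structure of the study population:

* 120 patients by default, of whom ~68% carry a single treated lesion
  (mixture 0.68 / 0.25 / 0.07 for 1 / 2 / ≥3). This mixture is calibrated
  to the printed lesion totals (171 lesions in 120 patients; 141 in the
  100 training patients) rather than to the number-of-brain-metastases
  table, which counts all metastases, not the SRT target lesions; the NBM
  clinical covariate keeps the published marginals.
* per-lesion LF prevalence 63/171 ≈ 0.37, optionally tilted by previous
  WBRT through a centred log-odds bump (default 0.8) so clinical-model
  code paths carry signal without changing the marginal prevalence;
* clinical covariates drawn from the published marginal frequencies
  (histology, dose levels 22.5–35 Gy, location, prior treatments);
* geometry: an ellipsoidal tumour (axis ratios drawn per class:
  LC 0.65–0.95, LF 0.45–0.80, so LF lesions tend to be more elongated) plus an
  edema shell 3–8 mm thick, randomly rotated and placed inside a fixed
  ellipsoidal brain phantom of ~120 × 150 × 100 mm. Volumes are rendered
  on a subvolume around the lesion (the brain mask is the phantom clipped
  to it) — whole-head rendering would add only empty background;
* texture: each region is filled with a stationary correlated random
  field (white noise smoothed by a separable Gaussian kernel with the
  class's correlation length, rescaled to the class's mean and sd), plus
  additive white noise. Because quantization is anchored at the ROI
  minimum, the per-class *sd* (LC 25 / LF 45 in the tumour) is what
  separates the classes in gray-level texture; the mean shift affects
  first-order features only;
* survival: exponential event times with medians 26.2 (LC) / 13.5 (LF)
  months, drawn once per patient (the any-LF class governs the draw);
  independent uniform censoring with the horizon solved numerically so
  the overall censoring probability equals `censor_rate` (default 0.2);
* both modalities are rendered on their native anisotropic grids
  (0.5 × 0.5 × 1.5 mm and 0.5 × 0.5 × 5 mm).

All randomness forks from one root seed through named sub-streams
(cohort plan, per-lesion rendering keyed by patient × lesion index,
subsets, folds, split), so cohorts are byte-reproducible and a single
lesion can be regenerated without rebuilding the cohort.

What the generator does **not** emulate: anatomy (no skull, no tissue
classes), scanner effects (bias fields, multi-site variation), partial
volume at mask boundaries drawn by clinicians, spatially varying noise,
or any real correlation between clinical covariates and imaging beyond
the configured WBRT bump. Passing tests on this cohort therefore
demonstrate that the pipeline recovers *planted* effects of realistic
magnitude under the study's data structure — not that the published
patient-data effect sizes are reproduced. The published AUCs depend on
undeposited patient data and are out of reach by construction.

## Numerical choices and degenerate inputs

* Resampling clamps interpolation coordinates at the volume border
  (effectively edge padding); masks resample by nearest neighbour.
* `normalizeWithinBrain()` refuses brains with zero intensity variance.
* Margin construction requires an isotropic grid (resample first) and
  uses an exact separable Euclidean distance transform with a 1e-9 mm²
  slack on the squared-distance comparison.
* Empty regions flag their features as NA with a warning naming the
  lesion; the lesion is reported, never silently dropped.
* AUC uses midranks for ties throughout; selection tie-breaks are
  lexicographic on feature id; k-NN distance ties break by training
  index.
* A fold whose training or validation part is single-class is skipped; a
  replicate with no usable fold is dropped; all replicates unusable is an
  error.
* Test and acceptance runs use scaled-down problem sizes chosen a
  priori: 51 balanced replicates (the documented desk-scale setting),
  cohorts of 8–60 patients for image-based stages, 1 mm target spacing in
  unit tests (0.5 mm for the end-to-end determinism check), and held-out
  cohorts of 500 patients for generalization AUC so that the AUC standard
  error (~0.01) does not dominate the comparison.

## Known limitations

* The 800-feature panel of the original description is not
  reconstructable; the package's canonical panel has 672 features.
* Sensitivity/specificity conventions: the original Results paragraph and
  its Table 2 disagree (88/85 vs 85/88); the package reports the
  confusion matrix at full precision and leaves the convention to the
  reader (LF is the positive class throughout).
* Wrapper selection on ~140 lesions with dozens of candidates admits a
  chance-correlated feature in a minority of seeds even with the
  standard-error guard; held-out AUC then lands around 0.72–0.78 instead
  of ~0.86. This is a property of the method at that sample size, not of
  the implementation; the acceptance suite measures it honestly.
* The mRMR variant (MID, 4-quantile discretization), the stratification
  variables of the patient split (any-LF × lesion-count bucket), and the
  per-replicate re-stratification of CV folds are all under-determined
  by the method description; each documented choice is deterministic and
  seeded.
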