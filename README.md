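# BrainMetRadiomics

Per-lesion prediction of **local failure (LF) vs local control (LC)** in
brain metastases treated with hypo-fractionated stereotactic radiotherapy
(SRT), from pre-treatment MRI — implemented as a tested, reusable R
pipeline with a synthetic MRI cohort generator standing in for patient
data.

About 20% of brain metastases progress locally after stereotactic
radiotherapy. The package builds an a-priori imaging biomarker from the
treatment-planning contrast-enhanced T1-weighted (CE-T1w) and T2-FLAIR
volumes of each lesion and uses it to stratify patients *before*
treatment, months ahead of the radiological follow-up that normally
establishes the outcome.

## What the pipeline does

1. **Pre-processing** — resample both modalities to an isotropic 0.5 mm
   grid, normalize intensities to zero mean / unit variance within the
   brain, and build 5 mm morphological margin shells around the tumour
   and around the lesion (tumour + edema).
2. **Feature extraction** — 672 features per lesion: 14 morphology
   features per region, and 18 first-order + 59 texture features
   (GLCM, GLDM, GLSZM, NGTDM; IBSI-consistent formulas) for each of
   4 regions × 2 images. Gray levels use fixed-width bins
   (width 25) with edges anchored at zero:
   `level(x) = floor(x/w) − floor(min_ROI/w) + 1`.
3. **Feature selection** — Pearson *R*² > 0.8 redundancy pruning
   (connected components, best univariate rank AUC kept), greedy mRMR
   ranking (MID criterion) to a top-100 pool, then sequential forward
   selection scored by patient-level stratified 5-fold cross-validated
   AUC averaged over 501 class-balanced undersampled replicates of the
   training set.
4. **Outcome model** — one k-NN (k = 5, Euclidean, per-model z-scoring)
   per balanced replicate; the ensemble predicts LF when more than half
   of the 501 models vote LF. Odd counts make every vote decisive.
5. **Survival** — patients with any LF lesion form the LF cohort;
   Kaplan–Meier curves and the log-rank test compare the cohorts implied
   by the predictions with those given by the ground-truth labels.

For a lesion with ensemble vote fraction
`v = (1/M) Σ_m 1[model m votes LF]`, the predicted label is
`LF ⇔ v > 0.5` and `v` is the ROC score. Elongation, the morphology
feature most prominent in this setting, is `sqrt(λ₂/λ₁)` of the ROI
coordinate covariance eigenvalues (0 = line, 1 = sphere).

Because the underlying patient data are not publicly deposited, the
package ships a **synthetic cohort generator** (`generateCohort()`) that
emulates the study's data structure: per-patient lesion multiplicity,
LF prevalence 63/171, clinical covariate marginals, ellipsoidal
tumour + edema geometry with class-dependent elongation, correlated
random-field textures with class-dependent heterogeneity, native
anisotropic grids (0.5 × 0.5 × 1.5 mm and 0.5 × 0.5 × 5 mm), and
exponential survival with medians 26.2 (LC) / 13.5 (LF) months.

## Worked example

```r
library(BrainMetRadiomics)

params <- syntheticParams(n_patients = 24, seed = 42)
cohort <- generateCohort(params)
length(cohort$lesions)
#> [1] 31

cfg <- pipelineConfig(
  target_spacing = 1.0,                       # coarser grid for a quick demo
  selection = selectionConfig(n_subsets = 51, seed = 42),
  feature_set_mode = "radiomic",
  train_fraction = 0.75,
  seed = 42)

res <- runPipeline(cohort, cfg)

res$selection$selected
#> [1] "FLAIR|tumour|firstorder|90Percentile"
#> [2] "FLAIR|tumour-margin|GLDM|DependenceEntropy"
round(res$selection$scores, 3)
#> [1] 0.996 1.000

res$metrics
#> sensitivity 100.0%  specificity 100.0%  accuracy 100.0%  AUC 1.000

res$survival$label$logrank
#> log-rank chi-square 0.365, p = 0.5458
```

Reading the output: the 24-patient cohort yielded 31 lesions; selection
reduced the 672-feature panel to a two-feature biomarker whose
cross-validated AUC on balanced training replicates is shown per step;
the ensemble classified all 7 held-out test lesions correctly (the
planted class effects in the generator are deliberately strong, and small
test sets make round numbers common). The log-rank comparison on 6 test
patients is far from significant — survival analyses need the larger
cohorts used in the test suite, where exponential arms at the configured
medians separate at p < 0.05 with 40 patients per arm.

`runPipeline()` also writes (or returns hashes of) every artifact:
feature table CSV with a provenance header, selection audit JSON, the
serialized ensemble, per-lesion predictions, metrics and survival JSON.
Identical config + seed reproduce identical artifact hashes.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R simulate --out cohort/ --patients 24 --seed 42
Rscript inst/scripts/run_pipeline.R run-all --manifest cohort/ --out results/ --subsets 51
```

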