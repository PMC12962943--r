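---
title: "Texture radiomics for MSI-H/MMRd prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture radiomics for MSI-H/MMRd prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Microsatellite-instable (MSI-H) / mismatch-repair-deficient (MMRd) pancreatic
ductal adenocarcinoma responds differently to immunotherapy than
microsatellite-stable disease, but MSI testing is not routine for pancreatic
tumors. msirad implements a CT texture-radiomics pipeline that scores the
probability of MSI-H/MMRd status from a portal-venous-phase CT volume with
tumor and pancreas segmentations: 254 texture features per region, univariate
screening, minimum-redundancy maximum-relevance (mRMR) selection with forward
selection, four classifier back-ends, logistic fusion of the tumor-level and
pancreas-level probability scores, and evaluation under repeated stratified
3-fold cross-validation. Because clinical CT cohorts of this rare phenotype
are not publicly available, the package also ships a synthetic phantom-cohort
generator so that every stage — and the pipeline end-to-end — is testable.

# The feature registry

Features are computed per axial slice inside the region mask and averaged,
unweighted, over all eligible slices (at least 16 in-mask pixels; a slice
failing a particular feature's own precondition is skipped for that feature
only). Six families make up the 254-entry registry:

* **GLCM (52)** — gray-level co-occurrence matrices at distance 1 in the four
  pixel directions (0, 45, 90, 135 degrees), symmetric and normalized, each
  summarized by the classical 13 Haralick statistics. Features are
  direction-resolved (13 x 4): keeping the four directions as separate
  registry entries preserves the 254-feature inventory and the index
  positions the field reports (e.g. RLM11), at the cost of rotational redundancy that the
  redundancy-aware selector is designed to absorb.
* **HIST (14)** — first-order statistics of the raw in-mask intensities
  (mean, sd, skewness, kurtosis, median, min, max, range, 32-bin histogram
  energy and entropy, percentiles 10/25/75/90). These intentionally keep raw
  intensity units; all other families are computed after per-slice
  quantization or comparisons and are therefore invariant to constant
  intensity offsets.
* **RLM (44)** — run-length matrices over maximal in-mask collinear
  constant-level segments, 11 classical statistics x 4 directions.
* **FD (48)** — for 16 equally spaced in-mask intensity thresholds, the
  box-counting dimension of the thresholded set, the box-counting dimension
  of its 4-connected boundary, and lacunarity (coefficient of variation of
  box masses at box size 4). Box grids are anchored at the mask bounding box,
  making the estimates translation-invariant; dyadic box sizes run from 1 to
  half the region extent and the dimension is the least-squares slope of
  log2 N(s) against log2(1/s), clamped to [0, 2].
* **LBP (72)** — rotation-invariant uniform local binary patterns for
  (P = 8, R = 1), (16, 2), (24, 3): normalized code histograms (10 + 18 + 26
  bins) plus six histogram summaries per configuration. Neighbors are sampled
  with bilinear interpolation, the comparison rule is neighbor >= center (with
  a relative tolerance of 1e-9 so interpolation round-off cannot flip exact
  ties), and a pixel is eligible only when the full interpolation support of
  every neighbor lies inside the mask.
* **ACM (24)** — angle co-occurrence matrices of Sobel gradient orientations
  folded to [0, 180) and quantized into 8 bins, at offsets (0,1) and (1,0)
  and two gradient-magnitude thresholds (25th and 50th in-mask percentile;
  zero-gradient pixels, which have no orientation, are always excluded), each
  summarized by six co-occurrence statistics.

Quantization uses 32 equal-width bins between the per-slice in-mask minimum
and maximum, so matrix features are independent of the scanner's contrast
window; a constant region maps to a single level. The registry is exposed by
`feature_registry()` and validated on every feature-table read.

# Screening and selection

`wilcoxon_screen()` tests each feature against MSI status with a two-sided
rank-sum test (exact when both groups have at most 10 cases and no ties,
normal approximation with tie correction otherwise) at alpha = 0.05 without
multiple-testing correction. Screening is descriptive: the in-fold selection
path is mRMR followed by forward selection, and feeding the screen into
selection would leak label information across folds.

`mrmr_rank()` uses the greedy MID (difference) scheme on plug-in mutual
information with 4-level equal-frequency (rank-based) discretization — robust
at the ~63 training cases available inside a fold, and invariant to monotone
feature transforms. Ties break toward the earlier registry position, which
makes selection deterministic. `forward_select()` then walks the mRMR order
and keeps a feature when it improves the inner stratified 3-fold out-of-fold
AUC by more than 1e-3, up to a cap of 10 features; the first ranked feature
is always kept. The cap reflects the small positive class (19 cases): larger
subsets overfit before they help.

# Models and fusion

Four classifier back-ends (`train_risk_model()`) produce risk scores in
[0, 1], all with inverse-prevalence class weights for the 1:4 imbalance and
fixed, recorded hyperparameters (no tuning): ridge logistic regression
(lambda = 1/n), an RBF-kernel SVM (cost 1, gamma = 1/p on standardized
inputs) whose decision values are calibrated by a Platt logistic fit on the
training data, a 500-tree random forest with sqrt-p variables per split, and
XGBoost with 200 depth-3 rounds at learning rate 0.1. Platt scaling is fit
directly on the training decision values rather than through libsvm's
internal cross-validated fit, which is not reproducible from R's seed; direct
fitting keeps the whole pipeline a pure function of (data, seed).

The combined model (IntRad) is a two-input logistic regression on the
tumor-model and pancreas-model probability scores (`train_fusion()`). To keep
the combiner leak-free it is trained on channel scores produced by an inner
stratified 3-fold split of the training fold; the outer-fold-selected feature
subsets are reused inside the inner folds (selection is not re-run there —
the contract being protected is that no test-fold information reaches
training, which re-selection would not change).

# Cross-validation and reporting

`run_repeated_cv()` repeats stratified 3-fold cross-validation (class-wise
shuffled round-robin assignment; per-fold class counts differ by at most 1).
Within each fold, selection, training, and fusion see training data only; the
held-out fold is scored once. Per repetition, metrics are computed on the
pooled out-of-fold scores — with 19 positives split across 3 folds,
per-fold metrics would be too unstable. The Youden threshold is refit per
repetition on the same pooled scores it evaluates; the optimism this introduces is recorded in the report
metadata rather than corrected. Percentile (2.5/97.5) intervals across
repetitions serve as 95% intervals. The clinical setting calls for 100
repetitions; package tests and the acceptance script use 10, which stabilizes means to
within a few hundredths of AUC on the phantom cohorts while keeping a full
run desk-scale (roughly two minutes per cohort on one CPU at the default
95-case, 64 x 64 x 12 geometry).

`decision_curve()` computes net benefit NB(t) = TP/n − FP/n · t/(1 − t)
against treat-all and treat-none references, and `selection_frequency()`
reports how often each feature was forward-selected across repetition x fold
fits, with the "frequently selected" set at frequency > 70%.

# The phantom generator

`phantom_config()` / `generate_cohort()` build cohorts of axial-slice
volumes: a constant background (40), a pancreas ellipsoid at base intensity
100, a tumor ellipsoid strictly inside it at 80 (hypodense, as pancreatic
tumors typically are), and an additive per-slice stationary Gaussian random
field inside the pancreas — white noise convolved with a Gaussian kernel of
width `corr_length`, centered and rescaled to amplitude `sigma`. Class signal
is planted as heterogeneity differences (case sigma 30 vs control 10;
correlation length 2 vs 4 voxels), not mean shifts, because the
discriminative features in this application are texture features. The
defaults (19 cases vs 76 controls, 64 x 64 x 12 voxels at a nominal 2.5 mm
pseudo-spacing) mirror the clinical cohort design this package targets; no
reference intensity statistics exist for such cohorts, so the intensity and
noise levels are declared, configurable conventions chosen to give realistic
in-region contrast-to-noise rather than calibrated values. Setting `effect_regions = character(0)` yields
a null cohort in which the label carries no information — the negative
control for the whole pipeline.

What the phantoms do **not** emulate: CT physics (beam hardening, noise
correlation from reconstruction), HU calibration, anatomical shape variation,
segmentation error, and scanner/protocol heterogeneity. Passing tests on
phantoms therefore demonstrate that the pipeline recovers planted
texture-heterogeneity signal and is calibrated under the null — not that any
particular clinical effect size is attainable; clinical CT cohorts of this
rare phenotype are not publicly available, so clinical performance figures
are not testable targets at desk scale.

# Numerical conventions and degenerate inputs

* Entropies are base-2 with 0·log 0 := 0; sd/skewness/kurtosis of a constant
  region are 0; correlation of a zero-variance co-occurrence matrix is 0.
* A thresholded fractal set that is empty scores 0; an ACM
  threshold/offset combination with no valid pair scores 0; a GLCM offset
  with no valid pair or an LBP configuration with an empty eroded mask causes
  that slice to be skipped for those features.
* Youden candidate thresholds are midpoints between adjacent distinct
  scores; ties in J break toward the higher threshold (higher specificity);
  all-equal scores return that value with J = 0. Predicted positive means
  score >= threshold. PPV/NPV with a zero denominator are reported missing,
  not 0.
* Constant features screen to p = 1; degenerate (single-bin) variables have
  zero mutual information; all-tied mRMR objectives fall back to registry
  order.
* Inner folds that lose a class are re-derived from the next seed (at most 5
  retries). All seeds derive deterministically from the master seed and the
  (repetition, fold, region) indices, so every result object is a pure
  function of (data, config, seed).

# Known limitations

* Features are 2D slice-wise, averaged over axial slices; volumetric texture, filtered-image, and shape features are out
  of scope.
* Volumes are not resampled to uniform spacing before extraction; voxel
  spacing is carried as metadata only.
* Registry index names (FD31, RLM11, ...) are positional convention within
  this package's registry layout; other radiomics implementations number
  their inventories differently.
* The logistic back-end requires at least two columns internally
  (a zero dummy column is appended for single-feature fits; its coefficient
  is exactly zero and scores are unaffected).

# A worked run

```{r}
library(msirad)

cfg <- phantom_config(seed = 1)                 # 19 cases vs 76 controls
coh <- generate_cohort_cases(cfg)
tum <- extract_features(coh$cases, "tumor")
panc <- extract_features(coh$cases, "pancreas")

screen <- wilcoxon_screen(tum, coh$labels)
attr(screen, "n_significant")

cv <- run_repeated_cv(tum, panc, coh$labels, n_repetitions = 10, seed = 2)
report <- summarize_cv(cv)
report
tidy(report)

plot_roc(cv)
plot_decision_curve(cv)
plot_score_distribution(cv)
```
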