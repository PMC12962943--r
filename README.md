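# msirad

Texture radiomics for predicting microsatellite-instability / mismatch-repair
status (MSI-H/MMRd) in pancreatic ductal adenocarcinoma from contrast-enhanced
CT.

MSI-H/MMRd pancreatic tumors are rare (1–2%) but matter clinically: they
respond to immunotherapy, and MSI testing is not routine for pancreatic
cancer. This package implements a complete CT texture-radiomics pipeline for
scoring MSI-H/MMRd probability from a portal-venous-phase CT volume with
tumor and pancreas segmentations, for imaging scientists who want to apply,
audit, or extend the procedure:

* **254 texture features per region** — gray-level co-occurrence (Haralick),
  intensity histogram, run-length, fractal dimension (box counting,
  boundary dimension, lacunarity), rotation-invariant uniform local binary
  patterns, and angle (gradient-orientation) co-occurrence features, computed
  per axial slice inside the mask and averaged over slices.
* **Screening and selection** — per-feature Wilcoxon rank-sum screening;
  in-fold greedy mRMR ranking (MID scheme on binned mutual information)
  followed by forward selection against inner-CV AUC.
* **Models** — logistic regression (ridge), RBF SVM with Platt-calibrated
  scores, random forest, and XGBoost, all with inverse-prevalence class
  weights; risk scores in [0, 1].
* **Fusion** — the combined model (IntRad) is a logistic combiner of the
  tumor-model (TumRad) and pancreas-model (PancRad) probability scores,
  trained on leak-free inner out-of-fold channel scores.
* **Evaluation** — repeated stratified 3-fold cross-validation; AUC,
  Youden-index dichotomization with sensitivity/specificity/PPV/NPV,
  discrimination slope, percentile 95% intervals across repetitions,
  decision-curve analysis (net benefit `NB(t) = TP/n − FP/n · t/(1−t)`),
  and feature selection-frequency reporting (the >70% rule).
* **Synthetic phantoms** — a Gaussian-random-field phantom-cohort generator
  (19 MSI-H vs 76 controls by default, with class-conditional texture
  heterogeneity) so the entire pipeline is testable without patient data.

## A worked example

```r
library(msirad)

# A phantom cohort with the clinical 1:4 case:control design and
# heterogeneity planted in
# tumor and pancreas textures (case GRF sigma 30 vs control 10).
cfg  <- phantom_config(seed = 1)
coh  <- generate_cohort_cases(cfg)
tum  <- extract_features(coh$cases, "tumor")      # 95 x (case_id + 254)
panc <- extract_features(coh$cases, "pancreas")

attr(wilcoxon_screen(tum, coh$labels), "n_significant")
#> [1] 209

cv <- run_repeated_cv(tum, panc, coh$labels, n_repetitions = 10,
                      classifiers = "logistic", seed = 2)
dplyr::summarise(dplyr::group_by(tidy(cv), model), auc = mean(auc))
#> # A tibble: 3 × 2
#>   model     auc
#>   <chr>   <dbl>
#> 1 IntRad  1
#> 2 PancRad 1
#> 3 TumRad  0.999
```

With heterogeneity planted in both regions the planted signal is recovered
essentially perfectly (mean cross-validated AUC ≈ 1 for all three models),
and the selection-frequency report identifies a stable feature set; on a
null cohort (`phantom_config(effect_regions = character(0))`) the same
pipeline stays at chance (mean IntRad AUC ≈ 0.46 with a 95% interval
covering 0.5). Plot helpers `plot_roc()`, `plot_decision_curve()`, and
`plot_score_distribution()` (or `autoplot()`) visualize the result;
`summarize_cv()` produces the model × classifier performance report with
95% percentile intervals, and `tidy()`/`glance()` give broom-style access.

Cohorts can also be written to and read from disk (`generate_cohort()`,
`read_manifest()`, `load_case()`, `write_feature_table()`), using NIfTI
volumes/masks and CSV manifests/feature tables.

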