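# radsurv

Zone-wise radiomics versus clinical survival modelling for IDH-mutated
diffuse lower-grade glioma (dLGG), implemented as a fully tested R
pipeline over a synthetic imaging-survival cohort generator.

## The problem

Patients with IDH-mutated dLGG have long but very heterogeneous survival,
which makes the timing of postoperative oncological treatment a genuine
decision problem. Standard prognostic covariates are preoperative tumor
volume, extent of resection (biopsy / partial / complete) and molecular
subtype (astrocytoma / oligodendroglioma). Quantitative MRI features —
tumor shape, first-order intensity statistics, and gray-level run-length
texture (GLRLM), computed in the tumor and in peritumoral zones — may add
prognostic information. `radsurv` implements the full comparison:

* four volumetric zones from a segmentation by signed anisotropic
  Euclidean distance: tumor, −5..+5 mm boundary band, 0–10 mm and
  10–20 mm peritumoral bands (half-open, brain-clipped);
* 292 features per patient: 9 shape per zone, plus 16 first-order and 16
  GLRLM features per zone and sequence (T1c, FLAIR), on unfiltered images
  with fixed-bin-count discretization;
* a three-stage training-set selection cascade: variance screen
  (variance < 0.01 removed), Spearman redundancy pruning (|ρ| ≥ 0.95,
  removing the member with the higher mean |ρ|), LASSO-Cox with
  cross-validated penalty;
* Cox models: preoperative clinical (volume), full clinical (volume +
  resection + subtype), four zone-wise radiomics models, two combined
  models (clinical + selected radiomics, refit jointly), and a
  postoperative-volume sensitivity variant — with exact linear SHAP
  explanations;
* evaluation by Uno's IPCW concordance
  `Σ w_i · 1[risk_i > risk_j] / Σ w_i` with `w_i = 1/Ĝ(T_i⁻)²`
  (plus the τ = 5 y truncated variant and Harrell's c), a paired bootstrap
  (identical resample indices across models) summarized as median (IQR),
  and Wilcoxon signed-rank model comparisons;
* risk-group stratification at the log-rank-optimal threshold with a 33%
  minimum group size.

Because no patient MRI can be distributed, a first-class synthetic cohort
generator provides segmented two-sequence tumors (lobulated ellipsoids
with Voronoi-cell texture of controllable run-length heterogeneity),
imaging-consistent clinical covariates, and Weibull proportional-hazards
outcomes with known effect sizes — so every stage is testable against
ground truth and independent brute-force oracles.

## Worked example

```r
library(radsurv)

cfg    <- strong_signal_config(n_patients = 200, seed = 1)
cohort <- generate_cohort(cfg)          # images, masks, clinical, outcomes
res    <- run_study(cohort, B = 1000, seed = 1)

res$models[, c("model", "n_features", "uno_c", "uno_c_boot_median",
               "uno_c_boot_iqr", "uno_c_tau", "harrell_c")]
```

```
                 model n_features uno_c uno_c_boot_median uno_c_boot_iqr uno_c_tau harrell_c
1       preop_clinical          1 0.709             0.708         0.0609     0.737     0.712
2        full_clinical          3 0.711             0.708         0.0544     0.747     0.716
3      radiomics_tumor         14 0.732             0.736         0.0694     0.742     0.730
4   radiomics_band_pm5          6 0.725             0.729         0.0627     0.743     0.727
5   radiomics_ptz_0_10          4 0.724             0.724         0.0668     0.726     0.724
6  radiomics_ptz_10_20          6 0.710             0.712         0.0717     0.706     0.708
7       combined_preop         15 0.732             0.735         0.0648     0.745     0.732
8        combined_full         17 0.746             0.749         0.0593     0.769     0.748
9 full_clinical_postop          3 0.722             0.721         0.0581     0.756     0.726
```

Reading the table: each row is one survival model evaluated on the
untouched 30% test set (n = 60). The tumor zone is the best radiomics
zone (chosen on the training set), and adding its selected features to
the full clinical model raises the test Uno's c from 0.711 to 0.746 —
approaching the generating model's Monte-Carlo oracle ceiling:

```r
oracle_concordance(cfg, n = 6000, seed = 2)$uno
#> 0.810
res$stratification[c("threshold", "chisq", "p_value", "n_high", "n_low")]
#> threshold 0.137, chisq 99.7, p = 1.8e-23, n_high 73, n_low 127
```

The risk groups from the combined model separate survival strongly
(log-rank p ≈ 2e-23), and the paired bootstrap comparison confirms the
combined model outperforms the full clinical model (signed-rank
p < 1e-70 over 1000 paired resamples).

The numbered scripts under `analysis/` run the same study as a
reproducible workflow (`01_simulate_cohort.R` → `04_risk_groups.R`),
writing tables and figures under `results/`.

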