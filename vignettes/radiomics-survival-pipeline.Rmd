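---
title: "Zone-wise radiomics survival modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-wise radiomics survival modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radsurv)
```

## The scientific question

Adult diffuse lower-grade gliomas with an IDH mutation show very
heterogeneous survival, which complicates the timing of postoperative
oncological treatment. Clinical prognostic models typically use
preoperative tumor volume, extent of resection and molecular subtype
(astrocytoma vs. oligodendroglioma). Quantitative imaging features
(radiomics) computed from routine MRI — tumor shape, intensity statistics,
and gray-level run-length texture — may add prognostic information, both
inside the tumor and in the peritumoral zones where diffuse gliomas
infiltrate.

`radsurv` implements this comparison end to end as reusable, tested
components: zone extraction, feature computation, a feature-selection
cascade, Cox modelling, censoring-robust concordance evaluation with paired
bootstrap comparison, and risk-group stratification. Because no patient
imaging is distributed with the package, a synthetic cohort generator with
*known* ground truth stands in for the data; it is first-class, tested code
and defines the conditions under which every downstream claim is verified.

## The pipeline

1. **Zones.** From a tumor segmentation, a signed anisotropic Euclidean
   distance map $d(v)$ (mm, negative inside) defines four volumetric zones:
   the tumor itself, the boundary band $-5 \le d \le 5$, and the
   peritumoral bands $0 < d \le 10$ and $10 < d \le 20$, each clipped to
   the brain mask. The outside bands are half-open so they partition the
   0–20 mm shell with no double counting; the boundary band is closed on
   both sides. Distances are center-to-center voxel distances (no sub-voxel
   surface model): deterministic and exactly checkable against a
   brute-force all-pairs oracle, which the test suite does.
2. **Features.** Per zone: 9 shape features (voxel-count volume in ml,
   face-counted surface area, sphericity
   $\pi^{1/3}(6V)^{2/3}/A$, maximum 3D diameter, per-plane maximum 2D
   diameters, elongation, flatness); per zone and sequence: 16 first-order
   features and the 16-feature gray-level run-length (GLRLM) set averaged
   without weighting over the 13 unique 3D directions. Images are used
   unfiltered. Intensities are discretized to a fixed bin count (default
   32) over the ROI range, top bin inclusive. Diameters are computed over
   voxel centers — every convex-hull vertex is an extreme point of its grid
   line along each axis, so intersecting the per-axis extreme sets
   preserves the exact maximum while discarding the blob interior.
3. **Selection cascade** (training rows only, fixed order): (i) variance
   screen, removing features with variance strictly below 0.01; (ii)
   Spearman redundancy pruning: among pairs with $|\rho| \ge 0.95$, visited
   in descending $|\rho|$, the member with the higher mean $|\rho|$ against
   all other features is removed (lexicographically later name on ties),
   using one static correlation matrix; (iii) LASSO-Cox with the penalty
   chosen by 5-fold cross-validated partial-likelihood deviance on
   event-stratified, seeded folds.
4. **Models.** Two clinical Cox models (preoperative: tumor volume; full:
   volume + extent of resection + subtype), four zone-wise LASSO-Cox
   radiomics models, two combined models (clinical covariates plus the best
   radiomics zone's selected features, refit jointly by unpenalized Cox),
   and a sensitivity variant replacing extent of resection with
   postoperative volume. Extent of resection is coded as two indicators
   (partial, complete) against a biopsy reference; subtype as an
   astrocytoma indicator. Ties use the Efron correction.
5. **Evaluation.** Uno's IPCW concordance (primary), its $\tau = 5$ years
   truncation (short-term prognosis), and Harrell's c (for comparability).
   Pair weights are $1/\hat G(T_i^-)^2$ with $\hat G$ the reverse
   Kaplan-Meier of the censoring distribution on the evaluation set. A
   paired bootstrap (default $B = 1000$, identical resample indices for
   every model) yields c-index distributions summarized as median (IQR) and
   compared pairwise by Wilcoxon signed-rank tests.
6. **Stratification.** The combined full model's risk scores over the
   entire cohort are dichotomized at the threshold maximizing the log-rank
   chi-square, subject to a minimum group size of 33% of the cohort;
   candidates are midpoints between consecutive sorted unique scores,
   ties resolved toward the smaller threshold, high risk meaning strictly
   above the threshold.

## The synthetic cohort generator

The generator emulates the essential statistical structure of a surgical
lower-grade-glioma cohort rather than MRI physics:

* **Geometry.** Tumors are star-shaped perturbed ellipsoids: per-axis
  semi-axes drawn from 8–15 mm and the radius modulated by
  $1 + \lambda f(u)$, with $f$ a random low-order ($l = 2, 3$) real
  spherical-harmonic field normalized to unit SD and $\lambda = 0.3$ the
  lobulation amplitude. Star-shapedness (the factor is clamped at 0.25)
  keeps the region connected.
* **Texture.** Intratumoral intensity is piecewise constant over
  nearest-seed (Voronoi) cells of Poisson-sampled centers with
  characteristic size 4–12 mm, plus Gaussian noise. Cell size directly
  controls run lengths, so the GLRLM long-run features are monotone in it —
  the property the heterogeneity effect is built on, and a tested oracle.
* **Clinical covariates.** Preoperative volume is measured from the
  rendered segmentation; extent of resection is drawn with probabilities
  0.09/0.70/0.21 (biopsy/partial/complete), mirroring the roughly 8/71/20%
  split of a typical surgical series at this scale, with a consistent
  postoperative volume (0 after complete resection, unchanged after
  biopsy). Subtype is a fair coin and acts only through its hazard effect,
  which isolates clinical-versus-radiomics information for synergy checks.
* **Outcomes.** Event times follow a Weibull proportional-hazards model
  (shape 1.2, scale 12 years — median survival near 9 years, appropriate
  for this disease). The continuous hazard drivers are statistics of the
  tumor the images actually show — the analytic Feret diameter and volume
  of the exact perturbed shape each mask seed renders, and the realized
  mean Voronoi cell size of the rendered texture (the cell layout is drawn
  once and shared between the survival simulator and the renderer) — so
  the prognostic signal is, by construction, present in the imaging.
  Continuous drivers act per SD; indicators act as is. Default effect sizes
  are 0.5 (diameter), 0.5 (texture), 0.3 (log volume), 0.7 (astrocytoma),
  −0.3/−0.7 (partial/complete resection). Censoring combines an
  administrative horizon — calibrated by bisection so the realized event
  fraction hits its target, default 0.25 to mirror the ~75% censoring
  regime of such cohorts — with 10% uniform dropout.
* **Strong-signal preset.** `strong_signal_config()` raises the imaging
  effects (diameter 1.0, texture 0.8 per SD) and the event fraction to
  0.5. This is the cohort used for end-to-end synergy checks: with ~30
  test-set events the concordance of a 60-patient test set is estimated
  precisely enough to compare against the generating model's oracle
  ceiling. These values were fixed as the check's study conditions, not
  fitted to it.

What the generator does **not** emulate: MRI physics (bias fields, partial
volume, registration error), multi-site effects, nonproportional hazards,
imaging–subtype correlation, or informative censoring. Passing tests
therefore demonstrate the *correctness of the pipeline's computations and
inferential plumbing* under a known truth — not clinical performance on
real data.

## Numerical choices and conventions

* **Concordance ties.** Pairs tied in time count when exactly one member is
  an event (the event is taken to precede censoring at the same recorded
  time); event/event ties are unusable; risk ties count 1/2. With zero
  censoring all IPCW weights are 1 and Uno's estimator reduces to
  Harrell's exactly — asserted in the tests, as is exact agreement with an
  independent brute-force IPCW double loop and with
  `survival::concordance(timewt = "n/G2")`.
* **$\hat G$ evaluation.** The censoring survival is evaluated at the left
  limit $T_i^-$; an event subject was still at risk at earlier censoring
  times, so the weights stay finite.
* **Variance screen on raw values.** The screen is applied to
  pre-normalization values: after z-scoring every non-constant feature has
  unit variance and a 0.01 threshold would be vacuous. Reading it as a
  near-constancy screen on raw features is the only interpretation that
  gives the stage effect.
* **Test-set normalization.** The protocol z-scores training and test sets
  each with their own statistics; this is unusual (it lets the test set
  see its own distribution) but is followed as stated and exposed as a
  switch (`test_stats = "train"`) for the conventional choice. Because
  z-scoring is a monotone affine map, Spearman-based pruning is unaffected.
* **Best-zone choice for the combined models.** The radiomics zone entering
  the combined models is chosen by *training-set* concordance, keeping the
  test set untouched by any selection decision.
* **Degenerate inputs.** Constant ROIs discretize to level 1 and report
  zero variance/entropy with skewness/kurtosis 0 by convention; empty
  zones propagate as explicit missing feature values, never silent zeros;
  constant covariates and event-free data are errors; monotone-likelihood
  Cox fits are flagged, not silently returned.
* **Determinism.** Every random stage derives its own seed from one master
  seed; a study run is a pure function of (cohort, master seed), which the
  suite asserts byte-for-byte on the JSON results record.

## Problem sizes

The shipped analyses and checks use: a 200-patient rendered cohort on a
48³ grid at 2 mm spacing (the full study), 500–5000-patient tabular
cohorts for parameter-recovery checks, 6000 Monte-Carlo patients for the
oracle concordance ceiling, and $B = 1000$ bootstrap replicates. These
sizes were chosen so each quantity's Monte-Carlo error is small relative to
the tolerance it is checked against, while keeping a full run in the
minutes range on a single core.

## Known limitations

* Surface area by face counting overestimates curved surfaces (only
  sphericity consumes it); mesh-based shape is out of scope.
* The representative feature inventory (9 shape, 16 first-order, 16 GLRLM
  per zone/sequence) is a standard IBSI-style set; other texture families
  (GLCM, GLSZM, NGTDM) and filtered images are deliberately excluded.
* The generator's clinical realism is qualitative (event fraction, volume
  scale, category frequencies), not a fit to any cohort table.
* With very small test sets the bootstrap can skip event-free resamples;
  more than 10% skips is treated as an error rather than silently
  reweighted.
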