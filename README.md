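# habrad — habitat-subregion radiomics for nodal metastasis prediction

`habrad` implements a voxel-level **tumor habitat** analysis of
co-registered dual-phase (arterial/venous) CT for predicting lymph node
metastasis (LNM) in intrahepatic cholangiocarcinoma (ICC). It is aimed
at imaging researchers who want a fully scripted, testable version of
the habitat-radiomics workflow: instead of treating the tumor as one
homogeneous region, the joint (arterial, venous) intensity distribution
of all tumor voxels in a cohort is partitioned into K intensity classes
("habitats"), and a radiomic signature is built per habitat.

## Method

1. **Preprocessing.** Volumes are standardized to the abdominal display
   window (level/width 50/350 HU, clip bounds [−125, 225]) and resampled
   to 1×1×1 mm (trilinear for images, nearest-neighbour for masks).
2. **Habitat delineation.** All in-mask voxels of the cohort are pooled
   into an N×2 matrix of (arterial, venous) HU values and clustered with
   K-means (k-means++ starts, Lloyd iterations, best of 10 starts). The
   cluster count K ∈ [2, 10] is selected by the maximum of the
   Calinski–Harabasz index
   CH(K) = [B/(K−1)] / [W/(N−K)],
   with B and W the between- and within-cluster dispersions. Habitats
   are named 1..K by ascending venous-phase center, so Habitat1 is the
   hypodense, necrosis-like class.
3. **Radiomics.** From the venous phase, per region (whole tumor or one
   habitat): 10 shape features, and 19 first-order + 10 GLCM texture
   features on the original image and 12 filtered variants
   (Laplacian-of-Gaussian σ ∈ {1,3,5} mm, the 8 stationary Haar wavelet
   subbands, a square-root transform) — 387 features per region, with
   fixed 25 HU discretization anchored at the region minimum.
4. **Signature.** z-score normalization (train-fitted), a greedy
   Spearman redundancy filter (delete the most redundant feature while
   any pair has |ρ| > 0.9), then LASSO-logistic regression
   (−(1/n)·loglik + λ‖β‖₁, coordinate descent) with λ chosen by
   stratified 5-fold CV maximizing validation AUC. The radiomic score is
   the linear combination of the retained standardized features.
5. **Evaluation.** 100 repeated stratified 6:4 train/test splits; per
   split the whole-tumor (intra) model, one model per habitat, and a
   fused model from the joint LASSO over the Habitat1+Habitat5
   post-redundancy pools. AUC with DeLong confidence intervals and
   tests, Youden-threshold confusion metrics, Hosmer–Lemeshow
   calibration, decision-curve analysis, Kaplan–Meier/log-rank survival
   and Yates-corrected χ² contingency statistics.

Because no patient images are distributed with the method, the package
includes a **synthetic phantom generator** (`phantom_spec()`,
`generate_cohort()`) that plants a known habitat structure — concentric
intensity shells around a low-attenuation core, class-dependent habitat
composition and survival — so every stage can be validated against
ground truth.

## Worked example

```r
library(habrad)

spec <- phantom_spec(seed = 0L)        # 20 patients, 5 planted habitats
gen  <- generate_cohort(spec)
w    <- window_spec()                  # 50/350 HU abdominal window
pats <- lapply(gen$patients, function(p)
  list(arterial = window_clip(p$arterial, w),
       venous   = window_clip(p$venous, w),
       mask     = p$mask))

vox   <- pool_voxels(pats)             # 273,599 pooled voxels
model <- select_k(vox, 2:10, seed = 0)
model
#> <habitat_model> K=5, WCSS=5.473e+07
#>          arterial venous
#> habitat1     0.02   9.94
#> habitat2    45.00  55.00
#> habitat3    89.89 100.03
#> habitat4   135.01 145.01
#> habitat5   179.96 190.06
```

The CH index peaks at K = 5 (the planted habitat count), and the fitted
centers recover the planted (arterial, venous) means — e.g. habitat 1
at (0, 10) HU, the necrosis-like core — to within 0.1 HU. A full run,
including radiomics, modeling and reports, is one call:

```r
run_all(default_config(), "runs/demo")
```

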