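---
title: "Habitat-subregion radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-subregion radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

Intrahepatic cholangiocarcinoma metastasizes to regional lymph nodes in
roughly half of resected patients, and nodal status is a dominant
prognostic factor; yet many patients never undergo nodal dissection, so
a preoperative imaging predictor is clinically valuable. Whole-tumor
("intra") radiomics averages over a heterogeneous lesion. The habitat
approach instead assumes the tumor is a mixture of a small number of
micro-environmental compartments — necrosis, hypoperfused rim,
enhancing viable tissue — that are distinguishable by their joint
attenuation in two contrast phases. Formally, each in-mask voxel
contributes a point in (arterial HU, venous HU) space, the pooled cloud
over the cohort is modeled as K compact classes, and K-means with the
Calinski–Harabasz (CH) criterion

$$\mathrm{CH}(K) = \frac{B/(K-1)}{W/(N-K)},\qquad
B = \sum_k n_k \lVert c_k - \bar c\rVert^2,\quad
W = \sum_k \sum_{x \in k} \lVert x - c_k\rVert^2$$

selects the compartment count. Clustering is **pooled over the cohort**,
not per patient: a single set of centers makes "Habitat 3" mean the same
tissue class in every patient, which is what allows per-habitat
signatures to be compared and fused across patients. Per-patient
clustering would leave labels incomparable. The two channels share HU
units, so they enter unscaled.

Cluster ids from any K-means solver are arbitrary; we rename habitats by
ascending venous-phase center. This is deterministic, makes Habitat 1
the most hypodense (necrosis-like) class, and renders the pipeline
invariant to solver seed on well-separated data (tested).

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| window level/width | 50 / 350 | HU | abdominal display window; clip bounds [−125, 225] |
| resample spacing | 1×1×1 | mm | isotropic grid for scanner-independent features |
| K candidates | 2–10 | — | brackets plausible compartment counts with margin |
| k-means starts / tol / iters | 10 / 1e-4 / 300 | — | k-means++ starts, Lloyd refinement; determinism via fixed seed |
| discretization bin width | 25 | HU | fixed-width bins anchored at the region minimum |
| min. region size for texture | 64 | voxels | below this, texture is ill-defined; features reported missing |
| Spearman redundancy threshold | 0.9 | \|ρ\| | above this two features are considered duplicates |
| λ grid | 50 points, λ_max → 10⁻³ λ_max | — | λ_max = max\|X'(y−ȳ)\|/n zeroes all coefficients |
| CV folds | 5, stratified | — | λ chosen by mean validation AUC, no 1-SE rule |
| split ratio / repeats | 0.6 / 100 | — | repeated stratified 6:4 splits |
| DCA grid | 0.01–0.99 step 0.01 | p_t | full-range net-benefit curve |
| HL bins | 10 | — | deciles of predicted risk, df = bins − 2 |

# The phantom: what it emulates and what it does not

No patient images are available, so the synthetic generator defines the
study conditions under which the pipeline is validated:

* **Geometry.** An ellipsoidal tumor (equivalent radius 12–18 mm) on a
  1 mm grid; habitats are concentric shells around a low-attenuation
  core, with an angular perturbation of the shell boundaries so they
  are not perfect spheres. This mirrors the observation that the
  informative habitats ring the necrotic core, and makes planted volume
  fractions exact up to the perturbation.
* **Intensities.** Five habitat means at (0,10), (45,55), (90,100),
  (135,145), (180,190) HU with 10 HU within-habitat sd — adjacent
  classes separated by ≈ 64 HU ≥ 4×sd, the identifiability condition
  the spec of the generator enforces. These values are conventions
  chosen to span the abdominal window; real ICC habitat HU ranges are
  not published.
* **Class signal.** LNM+ patients shift 0.12 of total volume fraction
  toward habitats 1 and 5 (Dirichlet concentration 100 around the class
  means), so the class signal lives in the habitat composition and in
  habitat-wise features, not in any single voxel.
* **Survival.** Exponential with medians 17 (LNM−) and 9 (LNM+) months,
  administrative censoring at 54 months plus uniform dropout on
  (0, 60) months, giving ≈ 30% censoring.
* **Covariate.** A WBC-like dichotomized covariate with below-cutoff
  probability 17/51 (LNM−) vs 29/52 (LNM+).

The phantom does **not** simulate CT physics (beam hardening, partial
volume, correlated noise, anisotropic acquisition) or anatomy outside
the tumor. Passing tests therefore certify the *computational* pipeline
— recovery of planted structure, absence of leakage, calibration of the
inferential tools — not clinical performance on real images.

# Numerical choices and degenerate inputs

* **Resampling** anchors the output grid at the input origin with
  size ⌈extent/spacing⌉, trilinear for images and nearest-neighbour for
  masks; clipping precedes resampling (the order only matters at window
  boundaries, which is tested).
* **Discretization** is `floor((x − min_region)/25) + 1`. On strongly
  range-compressed filtered images (large-σ LoG, the square-root
  transform) a region can collapse to a single gray level; its GLCM
  features are then reported missing, logged, and later median-imputed
  or dropped by the normalization step. This is the honest consequence
  of a fixed-width rule rather than silently rescaling bins per filter.
* **Wavelet** subbands use a single-level stationary Haar transform
  with averaging normalization, so the all-lowpass band of a constant
  image is that constant and all detail bands vanish; filters use
  replicate padding at the boundary.
* **Kurtosis** is the non-excess (+3) convention; skewness and kurtosis
  of a constant region are 0 by convention; percentiles use R's default
  type-7 quantile.
* **Maximum 3D diameter** is computed over surface voxels only (the
  maximum is attained there), chunked to bound memory.
* **CH with W = 0** (coincident points per cluster) returns +Inf — a
  perfectly separated degenerate case.
* **Ties.** CH ties break toward smaller K; redundancy-filter ties
  toward larger mean |ρ|, then the lexicographically first name;
  CV-λ ties toward the larger λ; Youden-threshold ties toward the
  larger cutoff; score ≥ threshold counts as positive. All are fixed so
  reruns are bit-identical.
* **Null-model guard.** If cross-validation prefers the empty (all-zero)
  signature, λ selection is restricted to path points that retain at
  least one feature; a design where no λ retains any feature raises a
  "signal-free" error.
* **Hosmer–Lemeshow** bins are right-closed quantile deciles (boundary
  ties to the lower bin); bins with expected events < 1 merge into
  their predecessor; the statistic uses the grouped form
  (O−E)²/(E(1−p̄)) with df = bins − 2.
* **2×2 tables** use the Yates continuity correction (clamped at
  |O−E|), which is the form that reproduces the reference cohort's
  printed statistics; median survival is reported without a standard
  error because the SE convention for medians is not identifiable from
  the reference values.

# Open design decisions taken

* "When the correlation between a feature and others exceeds 0.9, keep
  one" is ambiguous; we implement the greedy most-redundant-first
  deletion with the tie-breaks above, which terminates with no
  surviving pair above the threshold (asserted on every run).
* "100 cross-validations" is read as 100 repeated random stratified 6:4
  splits; the reported model is the repeat whose test AUC is closest to
  the median (ties to the lower index).
* Fusion is a single joint LASSO over the union of the two habitats'
  post-redundancy pools (names prefixed by region), not a union of
  separately selected features — one selection step, with per-region
  counts of the retained features reported.
* Registration is out of scope: inputs must pass `check_alignment`;
  the original workflow registered semi-manually, which is not
  reproducible computation.
* The whole pipeline is driven by one seed; per-patient, per-fold and
  per-split seeds are derived arithmetically from it.

# Problem sizes used in validation

The shipped validation uses a 20-patient default phantom
(≈ 2.7×10⁵ pooled voxels) for the cluster-count recovery run; 14- and
12-patient phantoms for the end-to-end and reproducibility runs; 6³
fixtures with 100 seeds for the feature-definition oracles; n = 200
with 51 features for the LASSO recovery simulation; 500 null
replicates for log-rank calibration; and a 2,000-replicate stratified
bootstrap for the DeLong standard-error check. These sizes are the
package's choice of smallest scales at which each property is
informative.

# Known limitations

* Feature classes are first-order, shape and GLCM only (no
  GLRLM/GLSZM/GLDM/NGTDM); 2D per-slice extraction and arterial-phase
  features are out of scope (the signature uses the venous phase).
* Habitat regions may be spatially disconnected and are treated as one
  voxel set, including for shape features.
* No Cox regression, competing risks, or nomogram construction.
* The phantom's intensity geometry is a convention; conclusions about
  real-data performance require real cohorts.
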