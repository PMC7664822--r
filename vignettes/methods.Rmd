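---
title: "Methods: quantitative CT texture analysis for solid pulmonary nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative CT texture analysis for solid pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pulmonary hamartomas are benign, but when they lack their two pathognomonic
CT signs — macroscopic fat and popcorn calcification — they are easily
mistaken for lung adenocarcinoma on conventional reading, and many end up
resected unnecessarily. Non-calcified hamartomas (NCH) are, however,
histologically mixtures of fibrous connective tissue, cartilage and fat in
varying proportions, so their interior attenuation is locally *heterogeneous*;
adenocarcinomas are comparatively uniform soft tissue. nodtex implements a
quantitative-imaging pipeline that turns this histological intuition into a
classifier: a 94-feature attenuation/texture panel per lesion, screened by
Bonferroni-corrected group tests and fed to a small feedforward neural
network evaluated by repeated stratified cross-validation.

## Pipeline

For each lesion (a CT volume in Hounsfield units plus a binary 3D ROI mask):

1. **ROI list.** The mask is flattened to one record per voxel
   (`x`, `y`, `z`, HU), ordered by slice, row, column
   (`mask_to_voxel_list()`).
2. **Normalization.** Attenuation is rescaled to $[0,1]$ within
   $\mu \pm 3\sigma$ of the lesion's own distribution:
   $v \mapsto \mathrm{clip}\{(v - (\mu - 3\sigma))/(6\sigma),\,0,\,1\}$,
   suppressing scanner offset/gain differences. $\sigma$ is the sample
   standard deviation ($n-1$ denominator); a constant ROI maps to 0.5 so
   degenerate phantoms stay processable. Normalization is per lesion, not
   per scan: the features are per-lesion quantities and the correction is
   meant to act at that level.
3. **2D substrate.** Texture features use the axial slice with the largest
   ROI area (ties to the smallest index). The normalized values on that
   slice are decimated to 8 equal-width gray levels on $[0,1]$
   (`level` $= 1 + \lfloor 8v \rfloor$, with $v=1$ in level 8).
4. **Feature panel** (94 columns, frozen order, `feature_dictionary()`):
   - f1–f8, *3D attenuation*: mean raw HU ("mass"); the parameters of a
     logistic curve $f(x) = f_2/(1+e^{-(x-f_3)/f_4})$ fitted to the
     cumulative attenuation distribution; mean, SD, skewness and excess
     kurtosis of the normalized values.
   - f9–f88, *gray-level co-occurrence*: symmetric, mask-restricted
     8-level GLCMs at unit displacement on 0°, 45°, 90° and 135°, each
     summarized by 20 Haralick-family statistics (contrast, entropy,
     energy, cluster shade/prominence, information measures of
     correlation, …).
   - f89–f94, *local binary patterns*: rotation-invariant uniform codes
     (riu2, radius 1, 8 neighbors, $\geq$ comparison) on the normalized
     slice, summarized by four moments and two histogram statistics.
5. **Statistics.** Welch two-sided t-tests per feature at the
   Bonferroni-corrected thresholds $0.05/94 = 0.0005$ (full panel) and
   $0.05/20 = 0.0025$ (orientation-pooled GLCM features). Dice overlap
   (with the conventional $> 0.7$ excellent-agreement flag) summarizes
   inter-observer segmentation agreement.
6. **Classification.** A feedforward network — feature-set input, one
   hidden layer of 50 tanh units, two softmax outputs, cross-entropy loss —
   evaluated by stratified 10-fold cross-validation repeated over many
   cycles, fold assignment reseeded per cycle. Per cycle the pooled
   test-fold scores give a ROC curve; sensitivity/specificity/accuracy/
   PPV/NPV are taken at the Youden-optimal threshold, with NCH as the
   positive class. AUC distributions across feature sets are compared by
   one-way ANOVA with Bonferroni-adjusted pairwise tests.

## Conventions that had to be fixed

Several steps admit dialects; nodtex fixes one of each and records it in
the extraction metadata:

- **Sigmoid fit target.** The logistic is fitted to the empirical
  cumulative fraction of the sorted normalized values, using the midpoint
  plotting position $(i - \tfrac12)/n$. A right-continuous $i/n$ target
  biases the fit by half a step; the midpoint convention makes noiseless
  logistic-CDF inputs recover their parameters exactly, which is the
  package's self-consistency guarantee. For ROIs above 2000 voxels the
  curve is represented by 2000 evenly spaced order statistics — a
  deterministic thinning that preserves the curve. The optimizer is
  Levenberg–Marquardt (`minpack.lm`), initialized at
  $f_2 = 1$, $f_3 = \mathrm{median}$, $f_4 = \mathrm{sd}/2$, tolerance
  $10^{-8}$, 500 iterations; non-convergence returns the best iterate with
  a warning flag.
- **GLCM dialect.** Displacement distance 1 pixel (the universal default of
  the co-occurrence literature); both endpoints of a pair must be inside
  the mask; matrices are symmetrized and normalized; logarithms are base 2
  with $0\log 0 = 0$; sum variance is taken about the sum average;
  the "normalized inverse difference (moment)" variants divide $|i-j|$ by
  $N$ (respectively $(i-j)^2$ by $N^2$). Orientation vectors in (row, col)
  with rows increasing downward: 0° $(0,1)$, 45° $(-1,1)$, 90° $(-1,0)$,
  135° $(-1,-1)$. Note scikit-image measures its angles in the opposite
  vertical sense, so its $\pi/4$ corresponds to our 135°.
- **LBP variant.** riu2 is the canonical rotation-invariant form: uniform
  patterns (at most two circular 0/1 transitions) map to their set-bit
  count, all others to 9, a 10-symbol alphabet whose histogram entropy is
  bounded by $\log_2 10$. Codes are computed on the continuous normalized
  values, not the 8-level quantization, which exists only as the GLCM
  substrate. The "histogram mean value" feature is the mean height of the
  occupied normalized-histogram bins (equivalently $1/k$ for $k$ occupied
  bins); the occupied-bin form avoids a constant value on lesions that use
  the whole alphabet.
- **Moments.** Skewness and kurtosis are bias-uncorrected standardized
  moments, kurtosis as excess (uniform data $\to -1.2$); both defined 0
  at zero variance.
- **Positive class.** NCH is the positive group in every metric. (Sources
  describing this design disagree internally on the labeling; the
  statistical-analysis definition is the one implemented, and the choice
  only swaps sensitivity with specificity.)
- **ANOVA.** The AUC comparison is a plain one-way ANOVA across models;
  there is no covariate to adjust for.
- **Leakage control.** Min-max scaling of network inputs and the
  early-stopping validation split are estimated from training rows only,
  inside each fold. The column-wise min-max rescaling over the whole
  cohort (`normalize_feature_columns()`) exists only for visualization and
  export.

## The synthetic cohort

No patient data accompany this design, so `generate_cohort()` builds a
phantom cohort with the statistical structure the analysis assumes, and the
whole pipeline is validated end-to-end on it. Defaults (42 NCH + 49 ACA;
largest diameters $14.3 \pm 6.0$ vs $22.6 \pm 7.4$ mm truncated to
6–41 mm; no voxel at or above the 120 HU calcification bound) mirror the
cohort the design targets. Each lesion is an approximately ellipsoidal mask
(longest axis = the drawn diameter, minor axes shrunk by random factors in
$[0.7, 1]$) centred in a 48³ volume of 1 mm isotropic voxels over a
$-800 \pm 30$ HU parenchyma background.

Interior attenuation is built from two controllable ingredients:

- a **correlated Gaussian field** (white noise smoothed by FFT convolution
  with a Gaussian kernel, rescaled to unit variance), correlation length
  1 mm for NCH vs 4 mm for ACA, amplitude 55 HU (`texture_sd_hu`) for
  both — the ordering of correlation lengths *is* the heterogeneity
  contrast between the classes;
- for NCH only, a **random Voronoi partition** of the mask into 3–6
  blobs assigned component means cycling through 40 (soft tissue),
  −40 (fat-admixed) and 80 HU (cartilage-like), emulating the
  multi-component histology. The fat-like component sits at −40 rather
  than pure fat's ≈ −100 HU: at 1 mm voxels small fat pockets are
  partial-volume mixtures, and a milder component keeps the per-lesion
  $\sigma$ from swamping the fine texture after $\mu \pm 3\sigma$
  normalization (extreme component spreads compress the within-component
  texture into too few gray levels, which *reduces* co-occurrence entropy).

ACA interiors are a single 30 HU component plus the smooth field. A 10 HU
white-noise floor is added everywhere and masked voxels are clipped
strictly below 120 HU. With these defaults the orientation-pooled GLCM
contrast, entropy and dissimilarity are all higher in the NCH class — the
direction the histology argument predicts — and the GLCM-fed network
separates the classes with mean AUC well above 0.9 while label-permuted
data stays near 0.5.

What the phantom does *not* emulate: scanner reconstruction kernels, dose
and multi-scanner variability, anisotropic voxels, ground-glass or
cavitating lesions, lesion-boundary partial-volume fading, and anatomic
context (vessels, pleura). Passing end-to-end tests on the phantom
demonstrates that the pipeline measures and exploits intra-lesion
heterogeneity as designed — not that the specific accuracy figures
transfer to patient data.

Determinism: each lesion's seed is derived from the cohort seed and lesion
index by a fixed integer recurrence, so identical configurations reproduce
identical cohorts byte-for-byte, while lesions remain mutually independent.

## Problem sizes used in validation

The repeated-cross-validation experiments in the package's own checks use
10 folds × 20 cycles per feature set on the 91-lesion default cohort —
enough cycles for the cycle-to-cycle AUC spread (SD ≈ 0.01) to make the
summary stable, while keeping a full four-model comparison fast on a
single core. The evaluation API defaults to 100 cycles for users who want
the tighter summary.

## Known limitations

- The sigmoid-fit target (a cumulative attenuation curve) is one of
  several plausible readings of "sigmoid features from curve fitting"; it
  is a package convention, recorded in metadata, not an inference about
  other implementations.
- Only 2D texture at distance 1 on the maximum-area slice is implemented;
  no 3D or multi-distance co-occurrence, no multi-radius LBP.
- The network trainer is full-batch Adam with early stopping; it is
  deliberately small and deterministic rather than tuned for speed on
  large cohorts.
- Synthetic-cohort results quantify pipeline correctness and direction of
  effect; absolute classification figures on the phantom exceed what mixed
  clinical data would give.
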