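---
title: "Parametric response mapping and volumetric CNN classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric response mapping and volumetric CNN classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(prm3d)
```

## The problem

Chronic obstructive pulmonary disease (COPD) alters lung parenchyma in two
ways that paired CT can separate: emphysematous tissue destruction, visible
as abnormally low attenuation at full inspiration, and functional
small-airway disease (fSAD), visible only as air trapping — tissue that
looks normal at inspiration but fails to empty at expiration. Parametric
response mapping (PRM) registers the expiratory scan onto the inspiratory
grid and classifies each lung voxel jointly by its two attenuation values.
This package implements that voxel model, the registration-derived
mechanical measures, a nine-layer volumetric convolutional network that
classifies subjects as COPD versus non-COPD from any of the derived maps,
Grad-CAM saliency volumes for inspecting what the network uses, and a
synthetic phantom generator that makes the whole chain testable without
clinical data.

## The PRM voxel model

With the standard clinical thresholds of −950 HU on inspiration and
−856 HU on expiration (both inclusive), a lung voxel is

* **emphysema (code 64)** if it is at or below both cuts,
* **fSAD (code 32)** if it is above the inspiratory cut but at or below
  the expiratory cut,
* **normal (code 8)** otherwise.

The fourth quadrant (low inspiratory, high expiratory attenuation) is
physiologically incoherent under the air-trapping model and is folded into
the normal class; `classify_volume()` logs how many voxels fell there.
Summary fractions (`Emph%`, `fSAD%`, `Normal%`) are computed over mask
voxel counts, with `Normal%` taken as the complement so the three sum to
exactly 100. Because the phantom grids are uniform, count-weighting and
volume-weighting coincide; for real data with one shared grid they also
coincide, so the simpler convention is used.

Air volumes use the linear attenuation mixture between pure air (−1000 HU,
air fraction 1) and soft tissue (55 HU, fraction 0), clamped to [0, 1]:
total lung capacity integrates the inspiratory air fraction over the mask,
functional residual capacity the expiratory one.

## Deformation measures

A prior registration supplies a displacement field u on the expiration
grid with the convention x_insp = x_exp + u(x_exp) (the registration
algorithm itself is out of scope; phantoms supply ground-truth fields).
From F = I + ∇u, computed by central differences in physical millimetres
with second-order one-sided stencils at grid faces (so affine fields are
differentiated exactly everywhere), the package derives:

* **J = det F**, the local volume-change ratio (J > 1 is expansion toward
  inspiration);
* the **principal stretches** λ₁ ≥ λ₂ ≥ λ₃ > 0, square roots of the
  eigenvalues of FᵀF, via the closed-form symmetric 3×3 eigenvalue
  solution (vectorised; voxels with a non-positive-definite FᵀF are
  flagged `NA` rather than silently clamped);
* the **anisotropic deformation index**
  ADI = √(((λ₁−λ₂)/λ₂)² + ((λ₂−λ₃)/λ₃)²), zero for isotropic volume
  change;
* the **slab-rod index**
  SRI = (2/π)·atan2(λ₂(λ₁−λ₂), λ₃(λ₂−λ₃)) ∈ [0, 1], separating slab-like
  (λ₁ = λ₂, SRI 0) from rod-like (λ₂ = λ₃, SRI 1) deformation;
* the **air-volume change** ΔV_air = J·β_in(x+u(x)) − β_ex(x), with β the
  air fraction and the inspiratory term sampled by trilinear
  interpolation. The J-weighting makes the quantity a per-expiration-voxel
  volume balance; an unweighted difference would ignore that the
  corresponding inspiratory tissue occupies J times the volume. Out-of-grid
  correspondences clamp to the nearest edge and are counted.

Per-subject scalars are voxel-medians over the mask, which are robust to
lesion outliers; whether the original cohort tables used means or medians
of voxel values is not stated anywhere we could verify, and the median is
the package's choice.

## The phantom generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is checked.

Each subject is an ellipsoidal "lung" (semi-axes 0.75/0.85/0.9 of the
half-extent of a 64³ grid at 4 mm isotropic spacing, ~79k mask voxels)
inside a +40 HU soft-tissue background. Attenuation models, all Gaussian
per voxel with an additional global 5 HU scanner noise:

| tissue | IN (HU) | EX (HU) |
|---|---|---|
| normal parenchyma | −870 (30) | −780 (25) |
| emphysema lesion | −975 (10) | −920 (15) |
| fSAD lesion | −900 (15) | −900 (15) |

These place each class on the correct side of the −950/−856 cuts while
keeping a real misclassification tail (about 1.3% of emphysema voxels
drift above −950 at IN; about 0.15% of normal voxels drift below −856 at
EX). The normal-parenchyma EX spread was set to 25 HU: much wider and the
normal→fSAD leak alone would plant more than half a percentage point of
spurious fSAD in a disease-free lung, which would defeat zero-burden
closure checks.

**Burden calibration.** Planted burdens are drawn from truncated normals
calibrated to the published group statistics (COPD: Emph% 8.5 (7.5),
fSAD% 23.7 (13.6), J 1.5 (0.3); non-COPD: 1.7 (2.5), 11.2 (13.4),
1.7 (0.4)). Naively clamping or rejecting draws at zero would inflate the
means (a N(1.7, 2.5) truncated at 0 has mean ≈ 2.3), so
`calibrate_truncnorm()` solves for underlying (μ, σ) such that the
*post-truncation* mean equals the target exactly and the sd is as close as
attainable. A [0, ∞)-truncated normal cannot exceed a coefficient of
variation of ~1, so for non-COPD Emph% and fSAD% the realised sds cap at
≈ 1.7 and ≈ 10.5 while the means are matched exactly — cohort-mean
recovery is the calibration contract; the sd shortfall is a documented
limitation.

**Tail compensation.** Because the attenuation tails leak a predictable
fraction of voxels between classes, planting exactly the drawn coverage
would bias PRM-measured burdens. The generator computes the 3×3
misclassification matrix analytically from the Gaussian models and solves
a 2×2 linear system so that the *expected measured* Emph%/fSAD% equal the
planted truth; planted voxel counts are then hit exactly (blobs are
trimmed farthest-first). Lesions are spheres with N(3, 1)-voxel radii
(floored at 1.2), placed with a configurable upper-lung bias — 2:1 for
COPD subjects by default, mirroring the apical predominance the saliency
analysis looks for.

**Displacement fields.** u is the sum of (i) a global anisotropic
expansion c·S₀ with S₀ ∝ diag(1, 1.05, 1.15) normalised to det 1 — most
expansion along the craniocaudal axis, as in breathing; (ii) a random
perturbation, white noise Gaussian-smoothed at a 20 mm correlation length
(synthesised at half resolution, where it is fully band-limited, then
upsampled) and scaled to contribute ~0.03 sd to J; and (iii) radial
Gaussian contractions at lesion sites scaled so local expansion is pulled
roughly halfway toward 1, emulating air trapping. The scalar c is tuned by
a secant iteration on the analytically assembled det(cS₀ + ∇u_rest) so the
voxel-median J over the mask matches the subject's drawn target to < 1e-3;
the gradient of the non-affine part is computed once, making the tuning
cheap and exact for the affine component.

**What the phantom does not emulate:** airway trees, lobe fissures and
vasculature; reconstruction-kernel texture; registration error (fields are
exact by construction); inter-scanner attenuation shifts; the correlation
structure between Emph%, fSAD% and J within a subject (draws are
independent apart from the joint burden cap). Passing recovery tests
therefore demonstrates that the *pipeline measures what was planted*, not
that it would achieve any particular accuracy on hospital data.

## Network input preparation

Every input kind is resampled to 32³ by trilinear interpolation on the
voxel-centred lattice and mapped into [0, 1] by a fixed affine window:
attenuation [−1024, 0] HU; J [0.5, 3]; ADI [0, 2]; ΔV_air [−0.5, 1.5];
SRI is already native [0, 1]. PRM code maps are interpolated like any
scalar grid — class borders blend, accepting interpolation mixing in
exchange for treating every input kind identically — and divided by 64,
which makes intensity monotone in severity (normal 0.125 < fSAD 0.5 <
emphysema 1). Fixed windows rather than per-volume min-max are deliberate:
per-volume scaling would erase the between-group density differences that
carry the signal. The IN+EX kind stacks two channels; all others are
single-channel.

## The classifier

The network is 3 × [3×3×3 convolution (32/64/128 filters, same-padding) →
batch normalisation → ReLU → 2×2×2 max-pool], taking 32³ → 16³ → 8³ → 4³,
followed by fully connected layers of 128, 128 and 2 units with a softmax
output — 1,343,490 trainable parameters for one input channel. Weights
start from N(0, 0.1); optimisation is Adam at learning rate 1e-4 on
softmax cross-entropy. Layer order within a block (conv → BN → ReLU →
pool) and same-padding are package choices where the source architecture
left them open. Batch normalisation uses batch statistics during training
and running statistics (momentum 0.9) at inference; since a channel bias
preceding batch normalisation is cancelled by the mean subtraction, conv
biases are carried as parameters but receive no gradient.

The reference training schedule is 2500 iterations (optimiser steps) on
batches of 50. The package's desk-scale default, used in all of its own
experiments, is 300 iterations on batches of 8 — sized for a single
commodity CPU core; batch norm statistics remain ample because each
channel sees ~260k voxel samples per batch, and on the phantom cohorts the
training curves are flat well before 400 iterations. The full schedule
remains one `train_config()` call away.

Implementation: single-precision im2col + BLAS `sgemm` with the whole
mini-batch fused into one multiply per layer; all large buffers persist
across iterations. Weight initialisation and batch order are drawn from
R's RNG, so one integer seed reproduces a training run bit-identically on
the same BLAS.

Cross-validation is stratified five-fold: within each class subjects are
shuffled and dealt round-robin, with the deal rotated between classes so
fold sizes differ by at most one subject globally and per class. Each
subject is tested exactly once; pooled test-fold predictions are the
primary report (per-fold metric tables are also returned, since pooling
versus averaging is a reporting choice that can move a metric by ~0.1
percentage points).

## Grad-CAM

Saliency is taken at the third convolution block's post-activation feature
volume at 8³ resolution — before its pool, trading the conventional
last-pooled layer for double the spatial resolution, which matters this
close to the 32³ input. Gradients of the chosen class logit are globally
average-pooled into channel weights; the ReLU of the weighted channel sum
is upsampled trilinearly to 32³ and max-normalised per volume (max 1
unless identically zero). `export_overlay()` writes the heatmap volume
plus axial/sagittal/coronal mid-plane PNGs (plane index ⌊shape/2⌋,
0-based) alpha-blended over the grayscale background.

## Numerical and degenerate-input choices

* Threshold comparisons are inclusive (≤) on both PRM cuts; decision
  thresholds on probabilities count ties as positive.
* ROC curves sweep the unique scores; AUC is trapezoidal and equals the
  Mann–Whitney concordance probability with ties counted half (verified
  against brute-force pair counting).
* Metrics with zero denominators report 0 with a warning rather than NaN.
* Voxels whose FᵀF is numerically non-positive-definite yield NA stretches
  and are excluded from medians; they are counted and logged.
* Degenerate inputs error early: empty masks, mismatched geometries,
  non-finite attenuations, fields with the wrong component count,
  inverted thresholds.

## Problem sizes used in the package's own checks

Cohort-recovery checks use 500 subjects per group on the 64³ grid;
classifier properties use a 300-subject calibrated cohort under five-fold
cross-validation at the desk-scale schedule; saliency localisation uses a
100-subject cohort whose COPD lesions are restricted to the upper lung
third. These sizes give two-standard-error tolerances of roughly ±0.7
(COPD Emph%), ±0.15 (non-COPD Emph%), ±1 percentage point (fSAD%) and
±0.03 (J) on cohort means, and a binomial se of ~0.02 on pooled accuracy.

## Known limitations

* The published real-data results (89.3% accuracy, AUC 0.937 on 596
  hospital subjects) concern private clinical CT; phantom-cohort
  accuracies are properties of the generator's separability, not
  reproductions of those numbers.
* The non-COPD burden sds are structurally capped below the published
  values (truncated-normal CV bound), making the control group slightly
  more homogeneous than reported.
* PRM resampling to 32³ blends class codes at boundaries; any network
  input built from a label map inherits this.
* ADI/SRI follow the principal-stretch formulas given above; other
  definitions exist in the registration literature, and comparisons
  across software should check the formula, not just the name.
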